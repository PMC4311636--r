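# Real-time processing pipeline.
#
# Long-running commands are modeled as step-wise tasks: each step does a
# bounded unit of work (one directory poll, one volume, one <=50 ms delay
# slice) so the protocol server can interleave pipeline work with answering
# status and feedback queries. Synchronous entry points simply drive a task
# to completion.

#' Wait for a volume file to arrive
#'
#' Blocks until `<input_dir>/<prefix><index>.nii` exists and its size is
#' stable across two polls at least 50 ms apart (write-completion
#' heuristic), or the timeout elapses.
#'
#' @param input_dir Watched directory.
#' @param index 1-based volume index.
#' @param params `studyParams` supplying the naming convention.
#' @param timeout Seconds to wait before failing.
#' @return The file path.
#' @export
awaitVolume <- function(input_dir, index, params, timeout = params$poll_timeout_s) {
  st <- new.env(parent = emptyenv())
  deadline <- Sys.time() + timeout
  path <- file.path(input_dir, volumeFileName(params, index))
  repeat {
    p <- pollVolumeOnce(path, st)
    if (!is.null(p)) return(p)
    if (Sys.time() > deadline) {
      stop(sprintf("TIMEOUT waiting for volume %d (%s)", index, path))
    }
    Sys.sleep(0.02)
  }
}

# One non-blocking arrival check. Returns the path when the file exists with
# a positive size unchanged since a previous poll >= 50 ms ago, else NULL.
pollVolumeOnce <- function(path, state) {
  if (!file.exists(path)) {
    state$size <- NULL
    return(NULL)
  }
  sz <- file.info(path)$size
  now <- as.numeric(Sys.time())
  if (!is.null(state$size) && state$size == sz && sz > 0 &&
      now - state$time >= 0.05) {
    return(path)
  }
  if (is.null(state$size) || state$size != sz) {
    state$size <- sz
    state$time <- now
  }
  NULL
}

## ---- task plumbing ----

newTask <- function(session, command, stepFn, onFail = NULL) {
  t <- new.env(parent = emptyenv())
  t$session <- session
  t$command <- command
  t$stepFn <- stepFn
  t$onFail <- onFail
  t$done <- FALSE
  t
}

# Advance a task by one bounded step; returns TRUE when the task is finished
# (DONE or FAILED). Errors mark the command FAILED with the error message as
# the reason; a task's onFail handler (e.g. the Finalization hook) still runs.
taskStep <- function(t) {
  if (t$done) return(TRUE)
  res <- tryCatch(t$stepFn(), error = function(e) e)
  if (inherits(res, "error")) {
    t$done <- TRUE
    if (!is.null(t$onFail)) try(t$onFail(), silent = TRUE)
    t$session$failReason <- conditionMessage(res)
    try(setCommandStatus(t$session, t$command, "FAILED"), silent = TRUE)
    return(TRUE)
  }
  if (isTRUE(res)) {
    t$done <- TRUE
    setCommandStatus(t$session, t$command, "DONE")
  }
  t$done
}

runTask <- function(t) {
  while (!taskStep(t)) NULL
  queryStatus(t$session$id, t$command)
}

# Cooperative delay: sleeps the configured artificial delay in <= 50 ms
# slices across successive task steps, so queries stay responsive however
# long a handler is slowed down.
delaySlice <- function(env) {
  if (env$delayLeft <= 0) return(FALSE)
  s <- min(0.05, env$delayLeft)
  Sys.sleep(s)
  env$delayLeft <- env$delayLeft - s
  TRUE
}

## ---- PREPROC ----

makePreprocTask <- function(session) {
  p <- session$params
  if (is.null(p)) stop("NO_CONFIG")
  if (is.null(session$pluginBinding)) stop("NO_PLUGIN")
  setCommandStatus(session, "PREPROC", "RUNNING")
  # idempotent restart: wipe all per-run pipeline state
  session$processed <- list()
  session$feedback <- list()
  session$motion <- list()
  session$hookTrace <- character()
  session$pluginState <- new.env(parent = emptyenv())
  session$reference <- NULL
  session$masks <- NULL
  session$refinedMasks <- NULL
  session$glm <- NULL
  session$failReason <- NULL
  for (cmd in setdiff(longCommands(), "PREPROC")) {
    assign(cmd, "IDLE", envir = session$status)
  }
  env <- new.env(parent = emptyenv())
  env$phase <- "delay"
  env$delayLeft <- p$debug_delay_s
  env$poll <- new.env(parent = emptyenv())
  env$deadline <- Sys.time() + p$poll_timeout_s

  stepFn <- function() {
    if (env$phase == "delay") {
      if (delaySlice(env)) return(FALSE)
      env$phase <- "reference"
      return(FALSE)
    }
    if (env$phase == "reference") {
      if (nzchar(p$reference_volume)) {
        if (!file.exists(p$reference_volume)) {
          stop("reference volume not found: ", p$reference_volume)
        }
        env$refPath <- p$reference_volume
      } else {
        path <- pollVolumeOnce(file.path(p$input_dir, volumeFileName(p, 1L)), env$poll)
        if (is.null(path)) {
          if (Sys.time() > env$deadline) stop("TIMEOUT waiting for the reference volume")
          Sys.sleep(0.02)
          return(FALSE)
        }
        env$refPath <- path
      }
      env$phase <- "finish"
      return(FALSE)
    }
    # finish: load reference and masks, validate grids, init the plug-in
    ref <- readVolume(env$refPath)
    session$reference <- as.array(ref)
    session$voxelDims <- voxelDims(ref)
    masks <- lapply(p$roi_mask_paths, function(mp) {
      if (!file.exists(mp)) stop("mask not found: ", mp)
      readMask(mp)
    })
    for (mk in masks) {
      if (!identical(dim(mk$mask), dim(session$reference))) {
        stop("SHAPE_MISMATCH: mask ", mk$name, " is not on the functional grid")
      }
    }
    session$masks <- masks
    callHook(session, "initialization")
    TRUE
  }
  newTask(session, "PREPROC", stepFn)
}

#' Run initial preprocessing for a session
#'
#' Loads (or awaits) the reference volume, validates the ROI masks against
#' the functional grid, resets the per-run pipeline state, and calls the
#' plug-in Initialization hook. Running it again restarts the pipeline from
#' scratch. Synchronous; the protocol server runs the same work as a
#' non-blocking task for `NBPREPROC`.
#'
#' @param session A session environment (see [createSession()], [getSession()]).
#' @return Final status, `"DONE"` or `"FAILED"`.
#' @export
runPreproc <- function(session) {
  runTask(makePreprocTask(session))
}

## ---- volume processing run ----

makeProcessTask <- function(session, compute_feedback) {
  p <- session$params
  if (is.null(p)) stop("NO_CONFIG")
  if (is.null(session$pluginBinding)) stop("NO_PLUGIN")
  command <- if (compute_feedback) "FEEDBACK" else "PIPELINE"
  if (queryStatus(session$id, "PREPROC") != "DONE") stop("PREPROC has not completed")
  if (compute_feedback && is.null(session$pluginBinding$resolved$test)) {
    stop("NO_PLUGIN: bound plug-in has no test hook")
  }
  setCommandStatus(session, command, "RUNNING")
  env <- new.env(parent = emptyenv())
  env$idx <- 1L
  env$phase <- "delay"
  env$delayLeft <- p$debug_delay_s
  env$poll <- new.env(parent = emptyenv())
  env$deadline <- Sys.time() + p$poll_timeout_s

  finalize <- function() callHook(session, "finalization")

  stepFn <- function() {
    if (env$idx > p$n_volumes) {
      finalize()
      return(TRUE)
    }
    if (env$phase == "delay") {
      if (delaySlice(env)) return(FALSE)
      env$phase <- "await"
      env$poll <- new.env(parent = emptyenv())
      env$deadline <- Sys.time() + p$poll_timeout_s
      return(FALSE)
    }
    if (env$phase == "await") {
      path <- pollVolumeOnce(file.path(p$input_dir, volumeFileName(p, env$idx)),
                             env$poll)
      if (is.null(path)) {
        if (Sys.time() > env$deadline) {
          stop(sprintf("TIMEOUT at volume %d", env$idx))
        }
        Sys.sleep(0.02)
        return(FALSE)
      }
      env$path <- path
      env$phase <- "process"
      return(FALSE)
    }
    # process one volume: Volume hook, motion correction, smoothing,
    # PostProc hook, then (optionally) the Test hook
    idx <- env$idx
    callHook(session, "volume", idx, env$path)
    vol <- readVolume(env$path)
    if (!identical(dim(vol)[1:3], dim(session$reference))) {
      stop(sprintf("SHAPE_MISMATCH at volume %d", idx))
    }
    vd <- session$voxelDims
    if (p$motion_correction && !identical(as.array(vol), session$reference)) {
      mp <- estimateMotion(vol, session$reference, vd)
      vol <- applyRigid(vol, mp, vd)
    } else {
      mp <- motionParams()
      vol <- as.array(vol)
    }
    storeMotion(session$id, idx, mp)
    if (p$smoothing_fwhm_mm > 0) {
      vol <- smoothGaussian(vol, p$smoothing_fwhm_mm, vd)
    }
    session$processed[[idx]] <- vol
    callHook(session, "postproc", idx, vol)
    if (compute_feedback) {
      res <- callHook(session, "test", idx, vol)
      if (isNotReady(res)) {
        # store completeness: a defined pair for every index; the value is NA
        # until the quantity (e.g. the first baseline block) is defined
        storeFeedback(session$id, idx, conditionIndexAt(p, idx), NA_real_)
      } else {
        storeFeedback(session$id, idx, res$class_label, res$feedback_value)
      }
    }
    env$idx <- idx + 1L
    env$phase <- if (p$debug_delay_s > 0) "delay" else "await"
    env$delayLeft <- p$debug_delay_s
    env$poll <- new.env(parent = emptyenv())
    env$deadline <- Sys.time() + p$poll_timeout_s
    FALSE
  }
  newTask(session, command, stepFn, onFail = finalize)
}

#' Process an acquisition run
#'
#' For each volume index in `1..n_volumes`: wait for the file to arrive, call
#' the plug-in Volume hook, estimate and apply rigid-body motion correction
#' against the run reference, apply Gaussian smoothing, store the motion
#' parameters, call the PostProc hook, and -- when `compute_feedback` is
#' `TRUE` (the `FEEDBACK` command) -- call the Test hook and store the
#' (class, feedback value) pair. The Finalization hook runs on completion and
#' also on failure. With `compute_feedback = FALSE` this is the `PIPELINE`
#' command: motion is stored, the feedback store stays empty.
#'
#' @param session A session environment with `PREPROC` completed.
#' @param compute_feedback Compute and store feedback per volume?
#' @return Final status, `"DONE"` or `"FAILED"`.
#' @export
runPipeline <- function(session, compute_feedback = TRUE) {
  runTask(makeProcessTask(session, compute_feedback))
}

## ---- GLM / feature selection / train commands ----

requireProcessed <- function(session) {
  p <- session$params
  if (is.null(p)) stop("NO_CONFIG")
  if (length(session$processed) < p$n_volumes ||
      any(vapply(seq_len(p$n_volumes), function(i) is.null(session$processed[[i]]), TRUE))) {
    stop("no completed run in this session (run PIPELINE/FEEDBACK first)")
  }
  invisible(p)
}

glmWork <- function(session) {
  p <- requireProcessed(session)
  dims <- dim(session$reference)
  Y <- vapply(session$processed[seq_len(p$n_volumes)], as.numeric,
              numeric(prod(dims)))
  fit <- glmFit(t(Y), p)
  session$glm <- list(fit = fit, tmap = array(fit$t, dims))
  invisible(NULL)
}

featureSelectionWork <- function(session, p_fraction = NULL) {
  p <- session$params
  if (is.null(p)) stop("NO_CONFIG")
  if (is.null(session$glm)) stop("GLM has not been computed in this session")
  if (length(session$masks) == 0L) stop("no ROI masks configured")
  if (is.null(p_fraction)) p_fraction <- p$feature_fraction_p
  session$refinedMasks <- lapply(session$masks, function(mk) {
    featureSelect(session$glm$tmap, mk, p_fraction)
  })
  invisible(NULL)
}

#' GLM, feature selection, and plug-in training commands
#'
#' `runGlm` fits the task-vs-baseline GLM to every voxel series of the
#' completed run and stores the t map in the session. `runFeatureSelection`
#' keeps the top fraction of in-mask voxels by that t map as refined ROIs for
#' subsequent feedback. `runTrain` invokes the bound plug-in's Train hook
#' (e.g. `buildROIs`, `trainSVM`); plug-ins without one skip silently.
#'
#' @param session A session environment.
#' @param p_fraction Fraction of voxels to keep (default from the study
#'   configuration).
#' @return Final status, `"DONE"` or `"FAILED"`.
#' @export
runGlm <- function(session) {
  runTask(makeGlmTask(session))
}

#' @rdname runGlm
#' @export
runFeatureSelection <- function(session, p_fraction = NULL) {
  runTask(makeFeatureSelectionTask(session, p_fraction))
}

#' @rdname runGlm
#' @export
runTrain <- function(session) {
  runTask(makeTrainTask(session))
}

makeGlmTask <- function(session) {
  requireProcessed(session)
  setCommandStatus(session, "GLM", "RUNNING")
  newTask(session, "GLM", function() { glmWork(session); TRUE })
}

makeFeatureSelectionTask <- function(session, p_fraction = NULL) {
  if (is.null(session$glm)) stop("GLM has not been computed in this session")
  setCommandStatus(session, "FEATURESELECTION", "RUNNING")
  newTask(session, "FEATURESELECTION",
          function() { featureSelectionWork(session, p_fraction); TRUE })
}

makeTrainTask <- function(session) {
  if (is.null(session$pluginBinding)) stop("NO_PLUGIN")
  setCommandStatus(session, "TRAIN", "RUNNING")
  newTask(session, "TRAIN", function() { callHook(session, "train"); TRUE })
}
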
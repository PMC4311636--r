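# Plug-in contract and the four shipped plug-ins.
#
# A plug-in exposes up to six hooks called at fixed time points of the
# pipeline: train, test, initialization, finalization, volume, postproc.
# Hooks absent from a binding are skipped silently. Hooks communicate with
# the engine only through the session workspace; per-session scratch state
# lives in session$pluginState, so concurrent sessions never share plug-in
# memory.

.pluginRegistry <- new.env(parent = emptyenv())

hookSlots <- function() {
  c("train", "test", "initialization", "finalization", "volume", "postproc")
}

#' Register a plug-in library
#'
#' Adds a named plug-in to the registry. `functions` maps exported function
#' names to callables; `default_hooks` assigns a function name (or `"-"` for
#' absent) to each of the six hook slots in the fixed order `train, test,
#' initialization, finalization, volume, postproc`. Third-party plug-ins use
#' the same contract as the four shipped ones.
#'
#' @param name Plug-in name (e.g. `"libROI"`).
#' @param functions Named list of functions.
#' @param default_hooks Named character vector over the six hook slots.
#' @export
registerPluginLibrary <- function(name, functions, default_hooks) {
  stopifnot(is.list(functions), all(nzchar(names(functions))))
  hooks <- rep("-", 6)
  names(hooks) <- hookSlots()
  for (slot in names(default_hooks)) {
    stopifnot(slot %in% hookSlots())
    hooks[[slot]] <- default_hooks[[slot]]
  }
  bad <- setdiff(setdiff(hooks, "-"), names(functions))
  if (length(bad)) stop("default hooks name unknown functions: ", paste(bad, collapse = ", "))
  assign(name, list(name = name, functions = functions, hooks = hooks),
         envir = .pluginRegistry)
  invisible(name)
}

#' Names of registered plug-ins
#' @return Character vector (the distribution ships `libROI`, `libMotor`,
#'   `libConnectivity`, `libBrainDecoding`).
#' @export
pluginNames <- function() ls(envir = .pluginRegistry)

#' Hook function names of a plug-in
#'
#' The six hook-function names in the fixed order `train, test,
#' initialization, finalization, volume, postproc`, with `"-"` marking hooks
#' the plug-in does not implement. This is the argument layout of the
#' `PLUGIN` protocol command.
#'
#' @param name Plug-in name.
#' @return Named character vector of length 6.
#' @export
pluginHookNames <- function(name) {
  if (!exists(name, envir = .pluginRegistry, inherits = FALSE)) {
    stop("unknown plug-in: ", name)
  }
  get(name, envir = .pluginRegistry)$hooks
}

#' Bind a plug-in to hook functions
#'
#' Resolves the named hook functions in the plug-in's registry entry and
#' returns a validated binding the engine calls hooks through. There is no
#' direct communication between frontends and plug-ins: the binding is the
#' only route.
#'
#' @param name Plug-in name.
#' @param hooks Character vector of 6 function names (`"-"` = absent) in the
#'   order of [pluginHookNames()]; defaults to the plug-in's own defaults.
#' @return A `pluginBinding` object.
#' @export
pluginBinding <- function(name, hooks = pluginHookNames(name)) {
  if (!exists(name, envir = .pluginRegistry, inherits = FALSE)) {
    stop("unknown plug-in: ", name)
  }
  lib <- get(name, envir = .pluginRegistry)
  stopifnot(length(hooks) == 6L)
  hooks <- as.character(hooks)
  names(hooks) <- hookSlots()
  resolved <- list()
  for (slot in hookSlots()) {
    fn <- hooks[[slot]]
    if (fn == "-") next
    if (!fn %in% names(lib$functions)) {
      stop(sprintf("plug-in %s has no function '%s'", name, fn))
    }
    resolved[[slot]] <- lib$functions[[fn]]
  }
  structure(list(name = name, hooks = hooks, resolved = resolved),
            class = "pluginBinding")
}

#' @export
print.pluginBinding <- function(x, ...) {
  cat(sprintf("plug-in %s: %s\n", x$name,
              paste(sprintf("%s=%s", names(x$hooks), x$hooks), collapse = " ")))
  invisible(x)
}

hookTraceLabel <- c(train = "Train", test = "Test", initialization = "Init",
                    finalization = "Final", volume = "Volume", postproc = "PostProc")

# Invoke a hook through the session's binding; absent hooks are skipped
# silently. Records the invocation in session$hookTrace.
callHook <- function(session, slot, ...) {
  b <- session$pluginBinding
  if (is.null(b)) return(invisible(NULL))
  fn <- b$resolved[[slot]]
  if (is.null(fn)) return(invisible(NULL))
  session$hookTrace <- c(session$hookTrace, hookTraceLabel[[slot]])
  fn(session, ...)
}

# Masks the feedback plug-ins operate on: localizer-refined masks when
# feature selection / buildROIs has run, else the configured ROI masks.
activeMasks <- function(session) {
  if (!is.null(session$refinedMasks)) session$refinedMasks else session$masks
}

## ---- ROI percent-signal-change machinery (libROI, libMotor) ----

#' Percent signal change relative to a baseline block
#'
#' The ROI feedback value: `(m_curr - m) / m` where `m` is the mean of the
#' per-volume ROI means over the `B` volumes of the previous baseline block.
#' The value is a fraction (no factor 100), exactly as the defining ratio is
#' written; frontends scale for display.
#'
#' @param current_mean ROI mean of the current volume.
#' @param baseline_means Per-volume ROI means of the completed baseline block.
#' @return Fractional signal change.
#' @export
roiPercentSignalChange <- function(current_mean, baseline_means) {
  stopifnot(length(baseline_means) >= 1)
  m <- mean(baseline_means)
  if (abs(m) < .Machine$double.eps) stop("DIVISION_BY_ZERO_BASELINE")
  (current_mean - m) / m
}

roiInit <- function(session, n_masks) {
  st <- session$pluginState
  masks <- activeMasks(session)
  if (length(masks) < n_masks) {
    stop(sprintf("plug-in needs %d ROI mask(s), found %d", n_masks, length(masks)))
  }
  st$nMasks <- n_masks
  st$baselineMeans <- NULL # per-mask mean over the previous baseline block
  st$B <- 0L
  st$acc <- list() # per-volume ROI means of the in-progress baseline block
  invisible(NULL)
}

# Shared Test hook: accumulates baseline-block ROI means, updates the rolling
# baseline when a baseline block completes (before computing that volume's
# feedback), then emits Eq-style fractional signal change per mask.
roiProcess <- function(session, index, volume) {
  st <- session$pluginState
  p <- session$params
  masks <- activeMasks(session)[seq_len(st$nMasks)]
  means <- vapply(masks, function(m) roiMean(volume, m), 0)
  cond <- conditionAt(p, index)
  if (cond == p$baseline_condition) {
    st$acc[[length(st$acc) + 1L]] <- means
    blk <- blockAt(p, index)
    if (index == blk$end) {
      accMat <- do.call(rbind, st$acc)
      st$baselineMeans <- colMeans(accMat)
      st$B <- nrow(accMat)
      st$acc <- list()
    }
  }
  if (is.null(st$baselineMeans)) return(notReady())
  vals <- vapply(seq_along(means), function(i) {
    m <- st$baselineMeans[[i]]
    if (abs(m) < .Machine$double.eps) stop("DIVISION_BY_ZERO_BASELINE")
    (means[[i]] - m) / m
  }, 0)
  structure(list(class_label = conditionIndexAt(p, index),
                 feedback_value = as.numeric(vals)),
            class = "feedbackResult")
}

roiFinal <- function(session) {
  st <- session$pluginState
  rm(list = ls(st), envir = st)
  invisible(NULL)
}

## ---- sliding-window connectivity (libConnectivity) ----

#' Sliding-window Pearson correlation
#'
#' Pearson correlation between two ROI-mean series over exactly the last `L`
#' entries. The window must be full: shorter input is an error (the engine
#' plug-in returns a not-ready marker instead of a partial-window value).
#'
#' @param x,y Numeric series of equal length `>= L`.
#' @param L Sliding-window size (number of most recent scans).
#' @return Correlation in `[-1, 1]`.
#' @export
slidingWindowCorrelation <- function(x, y, L) {
  stopifnot(length(x) == length(y), L >= 2)
  if (length(x) < L) stop("window not full: have ", length(x), ", need ", L)
  xi <- utils::tail(x, L)
  yi <- utils::tail(y, L)
  if (stats::sd(xi) < .Machine$double.eps || stats::sd(yi) < .Machine$double.eps) {
    stop("ZERO_VARIANCE in sliding window")
  }
  stats::cor(xi, yi)
}

#' Refine a pair of ROIs from a localizer run
#'
#' Fits the GLM to the voxel series of each supplied mask and keeps, per
#' mask, the top fraction `p` of voxels by the task-contrast t statistic
#' (see [featureSelect()]). The two refined voxel populations are the ROIs
#' used by the connectivity feedback.
#'
#' @param localizer List of 3-D arrays (the preprocessed localizer volumes,
#'   in acquisition order).
#' @param masks List of two `roiMask` objects.
#' @param p Fraction of voxels to keep, in (0, 1].
#' @param params `studyParams` describing the localizer design.
#' @return List of two refined `roiMask` objects.
#' @export
connBuildRois <- function(localizer, masks, p, params) {
  stopifnot(length(masks) == 2L, length(localizer) == params$n_volumes)
  lapply(masks, function(mk) {
    idx <- which(mk$mask)
    Y <- vapply(localizer, function(v) as.numeric(v)[idx], numeric(length(idx)))
    fit <- glmFit(t(Y), params)
    stat <- array(-Inf, dim(mk$mask))
    stat[idx] <- fit$t
    featureSelect(stat, mk, p)
  })
}

connInit <- function(session) {
  st <- session$pluginState
  if (length(activeMasks(session)) < 2L) stop("libConnectivity needs two ROI masks")
  st$L <- session$params$sliding_window_L
  st$win1 <- numeric()
  st$win2 <- numeric()
  invisible(NULL)
}

connTrain <- function(session) {
  p <- session$params
  if (length(session$processed) < p$n_volumes) {
    stop("buildROIs needs a completed localizer run in this session")
  }
  session$refinedMasks <- connBuildRois(session$processed,
                                        session$masks[1:2],
                                        p$feature_fraction_p, p)
  invisible(NULL)
}

connFeedback <- function(session, index, volume) {
  st <- session$pluginState
  masks <- activeMasks(session)
  st$win1 <- c(st$win1, roiMean(volume, masks[[1]]))
  st$win2 <- c(st$win2, roiMean(volume, masks[[2]]))
  if (length(st$win1) > st$L) { # keep only the last L scans
    st$win1 <- utils::tail(st$win1, st$L)
    st$win2 <- utils::tail(st$win2, st$L)
  }
  if (length(st$win1) < st$L) return(notReady())
  rho <- slidingWindowCorrelation(st$win1, st$win2, st$L)
  structure(list(class_label = conditionIndexAt(session$params, index),
                 feedback_value = rho),
            class = "feedbackResult")
}

connFinal <- function(session) roiFinal(session)

## ---- SVM brain decoding (libBrainDecoding) ----

decodingClasses <- function(params) {
  conds <- unique(vapply(params$design, `[[`, "", "condition"))
  task <- setdiff(conds, params$baseline_condition)
  if (length(task) < 2L) stop("SVM decoding needs two non-baseline conditions")
  task[1:2]
}

svmInitHook <- function(session) {
  st <- session$pluginState
  st$model <- NULL
  mp <- session$params$svm_model_path
  if (nzchar(mp) && file.exists(mp)) st$model <- loadTrainedSvm(mp)
  invisible(NULL)
}

svmTrainHook <- function(session) {
  p <- session$params
  if (length(session$processed) < p$n_volumes) {
    stop("trainSVM needs a completed training run in this session")
  }
  classes <- decodingClasses(p)
  conds <- vapply(seq_len(p$n_volumes), function(i) conditionAt(p, i), "")
  keep <- which(conds %in% classes)
  masks <- activeMasks(session)
  featureIdx <- if (length(masks)) which(masks[[1]]$mask)
                else seq_along(as.numeric(session$processed[[1]]))
  X <- t(vapply(keep, function(i) as.numeric(session$processed[[i]])[featureIdx],
                numeric(length(featureIdx))))
  model <- svmTrain(X, factor(conds[keep], levels = classes),
                    feature_idx = featureIdx)
  st <- session$pluginState
  st$model <- model
  if (dir.exists(p$workspace_dir)) {
    saveTrainedSvm(model, file.path(p$workspace_dir, "svm_model.json"))
  }
  invisible(NULL)
}

svmTestHook <- function(session, index, volume) {
  st <- session$pluginState
  if (is.null(st$model)) return(notReady())
  res <- svmTest(as.numeric(volume), st$model)
  conds <- unique(vapply(session$params$design, `[[`, "", "condition"))
  lbl <- match(res$class_name, conds)
  res$class_label <- if (is.na(lbl)) res$class_label else lbl
  res
}

svmFinalHook <- function(session) roiFinal(session)

## ---- registry population ----

registerShippedPlugins <- function() {
  registerPluginLibrary(
    "libROI",
    functions = list(
      initializeROIProcessing = function(session) roiInit(session, 1L),
      processROI = roiProcess,
      finalizeROIProcessing = roiFinal
    ),
    default_hooks = c(test = "processROI",
                      initialization = "initializeROIProcessing",
                      finalization = "finalizeROIProcessing")
  )
  registerPluginLibrary(
    "libMotor",
    functions = list(
      initializeMotorProcessing = function(session) roiInit(session, 2L),
      processMotorROI = roiProcess,
      finalizeMotorProcessing = roiFinal
    ),
    default_hooks = c(test = "processMotorROI",
                      initialization = "initializeMotorProcessing",
                      finalization = "finalizeMotorProcessing")
  )
  registerPluginLibrary(
    "libConnectivity",
    functions = list(
      initializeFunctionalConnectivity = connInit,
      buildROIs = connTrain,
      calculateFeedback = connFeedback,
      finalizeFunctionalConnectivity = connFinal
    ),
    default_hooks = c(train = "buildROIs",
                      test = "calculateFeedback",
                      initialization = "initializeFunctionalConnectivity",
                      finalization = "finalizeFunctionalConnectivity")
  )
  registerPluginLibrary(
    "libBrainDecoding",
    functions = list(
      initSVM = svmInitHook,
      trainSVM = svmTrainHook,
      testSVM = svmTestHook,
      finalSVM = svmFinalHook
    ),
    default_hooks = c(train = "trainSVM", test = "testSVM",
                      initialization = "initSVM", finalization = "finalSVM")
  )
}

.onLoad <- function(libname, pkgname) {
  registerShippedPlugins()
}
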
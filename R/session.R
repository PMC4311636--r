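# Session registry. A session is an isolated in-memory workspace holding one
# experiment's configuration, command statuses, per-volume feedback and motion
# stores, and opaque plug-in state. Two protocol connections bound to the same
# id share these stores (one driving the pipeline, one answering queries).

.sessions <- new.env(parent = emptyenv())

# Long-running commands whose completion the frontend polls for.
longCommands <- function() {
  c("PREPROC", "PIPELINE", "FEEDBACK", "GLM", "FEATURESELECTION", "TRAIN")
}

#' Create a session workspace
#'
#' Registers a fresh, isolated session with all command statuses `IDLE` and
#' empty feedback/motion stores. The configuration may be attached later (the
#' `READCONFIG` path) or supplied here.
#'
#' @param params Optional `studyParams`; `NULL` for a not-yet-configured
#'   session.
#' @return The session id, a short random alphanumeric token.
#' @export
createSession <- function(params = NULL) {
  repeat {
    id <- paste(sample(c(letters, LETTERS, 0:9), 12, replace = TRUE), collapse = "")
    if (!exists(id, envir = .sessions, inherits = FALSE)) break
  }
  s <- new.env(parent = emptyenv())
  s$id <- id
  s$params <- params
  s$status <- new.env(parent = emptyenv())
  for (cmd in longCommands()) assign(cmd, "IDLE", envir = s$status)
  s$feedback <- list()
  s$motion <- list()
  s$pluginBinding <- NULL
  s$pluginState <- new.env(parent = emptyenv())
  s$processed <- list()
  s$masks <- NULL
  s$refinedMasks <- NULL
  s$reference <- NULL
  s$glm <- NULL
  s$hookTrace <- character()
  s$failReason <- NULL
  s$created <- Sys.time()
  assign(id, s, envir = .sessions)
  id
}

#' Look up a live session
#'
#' @param id Session token returned by [createSession()].
#' @return The session environment.
#' @export
getSession <- function(id) {
  if (!is.character(id) || length(id) != 1L ||
      !exists(id, envir = .sessions, inherits = FALSE)) {
    stop(sprintf("unknown session '%s'", paste(id, collapse = " ")))
  }
  get(id, envir = .sessions, inherits = FALSE)
}

#' @rdname getSession
#' @export
sessionExists <- function(id) {
  is.character(id) && length(id) == 1L &&
    exists(id, envir = .sessions, inherits = FALSE)
}

#' List live session ids
#' @return Character vector of tokens.
#' @export
sessionIds <- function() ls(envir = .sessions)

#' End a session
#'
#' Removes the session from the registry; subsequent queries against its id
#' raise an unknown-session error. No state is persisted.
#'
#' @param id Session token.
#' @export
endSession <- function(id) {
  s <- getSession(id)
  rm(list = id, envir = .sessions)
  invisible(s$id)
}

# Status transitions: IDLE -> RUNNING -> (DONE | FAILED). A finished command
# may be restarted (terminal -> RUNNING), which resets the pipeline state;
# within one run the polled sequence is monotone.
setCommandStatus <- function(session, command, status) {
  if (!command %in% longCommands()) stop("not a long-running command: ", command)
  cur <- get(command, envir = session$status)
  ok <- switch(status,
    RUNNING = cur %in% c("IDLE", "DONE", "FAILED"),
    DONE = cur == "RUNNING",
    FAILED = cur == "RUNNING",
    IDLE = TRUE,
    FALSE
  )
  if (!ok) stop(sprintf("illegal status transition %s -> %s for %s", cur, status, command))
  assign(command, status, envir = session$status)
  invisible(status)
}

#' Query the status of a long-running command
#'
#' Never blocks; within one run of a command, repeated polling observes a
#' prefix of `IDLE* RUNNING* (DONE|FAILED)*`.
#'
#' @param id Session token.
#' @param command One of `PREPROC`, `PIPELINE`, `FEEDBACK`, `GLM`,
#'   `FEATURESELECTION`, `TRAIN`.
#' @return Status string.
#' @export
queryStatus <- function(id, command) {
  s <- getSession(id)
  if (!command %in% longCommands()) stop("not a long-running command: ", command)
  get(command, envir = s$status)
}

#' Not-ready marker
#'
#' Returned by non-blocking queries (and by feedback hooks) when the requested
#' value has not been computed yet.
#' @return An object of class `notReady`.
#' @export
notReady <- function() structure(list(), class = "notReady")

#' @rdname notReady
#' @param x Object to test.
#' @export
isNotReady <- function(x) inherits(x, "notReady")

checkVolumeIndex <- function(session, index) {
  index <- suppressWarnings(as.integer(index))
  n <- if (!is.null(session$params)) session$params$n_volumes else NA_integer_
  if (is.na(index) || index < 1L || (!is.na(n) && index > n)) {
    stop(sprintf("volume index out of range: %s", index))
  }
  index
}

#' Store and query per-volume feedback
#'
#' `storeFeedback` records the (class label, feedback value) pair produced for
#' one volume; `queryFeedback` retrieves it without blocking, returning
#' [notReady()] if the pipeline has not yet stored that index.
#'
#' @param id Session token.
#' @param index 1-based volume index.
#' @param class_label Integer condition/class label.
#' @param feedback_value Numeric feedback (length 1, or 2 for the dual-ROI
#'   motor plug-in).
#' @return `queryFeedback`: a `feedbackResult` (list with `class_label`,
#'   `feedback_value`) or a `notReady` marker.
#' @export
storeFeedback <- function(id, index, class_label, feedback_value) {
  s <- getSession(id)
  index <- checkVolumeIndex(s, index)
  s$feedback[[as.character(index)]] <- structure(
    list(class_label = as.integer(class_label), feedback_value = as.numeric(feedback_value)),
    class = "feedbackResult"
  )
  invisible(index)
}

#' @rdname storeFeedback
#' @export
queryFeedback <- function(id, index) {
  s <- getSession(id)
  index <- checkVolumeIndex(s, index)
  res <- s$feedback[[as.character(index)]]
  if (is.null(res)) notReady() else res
}

#' Store and query per-volume motion parameters
#'
#' Motion parameters are the 6 rigid-body parameters estimated against the run
#' reference (translations in mm, rotations in degrees) plus the
#' root-mean-square intensity difference at the optimum.
#'
#' @param id Session token.
#' @param index 1-based volume index.
#' @param mp A `motionParams` object (see [motionParams()]).
#' @return `queryMotion`: a `motionParams` object or a `notReady` marker.
#' @export
storeMotion <- function(id, index, mp) {
  s <- getSession(id)
  index <- checkVolumeIndex(s, index)
  stopifnot(inherits(mp, "motionParams"))
  s$motion[[as.character(index)]] <- mp
  invisible(index)
}

#' @rdname storeMotion
#' @export
queryMotion <- function(id, index) {
  s <- getSession(id)
  index <- checkVolumeIndex(s, index)
  res <- s$motion[[as.character(index)]]
  if (is.null(res)) notReady() else res
}

#' Rigid-body motion parameters
#'
#' @param tx,ty,tz Translations, mm.
#' @param rx,ry,rz Rotations about the grid centroid, degrees.
#' @param rms Root-mean-square intensity difference to the reference; 0 for
#'   the reference volume itself.
#' @param degenerate Flag set when estimation saw a constant volume and fell
#'   back to the identity transform.
#' @return A `motionParams` object.
#' @export
motionParams <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0,
                         rms = 0, degenerate = FALSE) {
  stopifnot(rms >= 0)
  structure(list(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz,
                 rms = rms, degenerate = isTRUE(degenerate)),
            class = "motionParams")
}

#' @export
print.motionParams <- function(x, ...) {
  cat(sprintf("rigid: t=(%.3f, %.3f, %.3f) mm r=(%.3f, %.3f, %.3f) deg rms=%.4g\n",
              x$tx, x$ty, x$tz, x$rx, x$ry, x$rz, x$rms))
  invisible(x)
}

#' Export motion parameters as tab-separated text
#'
#' One row per stored volume: index, tx, ty, tz, rx, ry, rz, rms.
#'
#' @param id Session token.
#' @param path Output file path.
#' @export
writeMotionTable <- function(id, path) {
  s <- getSession(id)
  idx <- sort(as.integer(names(s$motion)))
  rows <- vapply(idx, function(i) {
    m <- s$motion[[as.character(i)]]
    paste(c(i, m$tx, m$ty, m$tz, m$rx, m$ry, m$rz, m$rms), collapse = "\t")
  }, "")
  writeLines(c(paste(c("index", "tx", "ty", "tz", "rx", "ry", "rz", "rms"),
                     collapse = "\t"), rows), path)
  invisible(path)
}
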
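# TCP/IP protocol server.
#
# Single cooperative event loop: it accepts connections, answers queries
# immediately, and advances long-running commands one bounded step at a time
# between socket polls. That gives the contract the protocol promises --
# non-blocking commands reply as soon as the work is scheduled, and status /
# feedback queries (including from a second connection bound to the same
# session) respond while a handler is busy -- without OS threads. Blocking
# commands hold their connection's reply back until the task finishes;
# blocking TEST/GRAPHPARS queries are parked as waiters and answered as soon
# as the requested volume is stored (or their timeout passes).

#' Serve the engine protocol
#'
#' Listens on `port` and executes the command protocol until `max_runtime_s`
#' elapses (or forever). Multiple concurrent connections are accepted; any
#' number of sessions may be live, and two connections bound to the same
#' session share its stores (one driving the pipeline, one answering
#' queries).
#'
#' @param port TCP port to listen on.
#' @param config_path Optional study configuration applied by default to
#'   sessions that never receive `READCONFIG`.
#' @param ready_file Optional path: once listening, the server writes
#'   `"<pid> <port>"` there (used by [launchEngine()]).
#' @param max_runtime_s Stop serving after this many seconds.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return Invisibly, the number of requests served.
#' @export
engineServe <- function(port, config_path = NULL, ready_file = NULL,
                        max_runtime_s = Inf, log_level = "info") {
  defaultParams <- NULL
  if (!is.null(config_path)) {
    defaultParams <- parseStudyParams(readLines(config_path, warn = FALSE))
  }
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  st <- new.env(parent = emptyenv())
  st$conns <- list()
  st$tasks <- list()
  st$waiters <- list()
  st$defaultParams <- defaultParams
  st$log_level <- log_level
  st$served <- 0L
  if (!is.null(ready_file)) {
    writeLines(paste(Sys.getpid(), port), ready_file)
  }
  logMsg(st, "info", "listening on port ", port)
  endTime <- Sys.time() + max_runtime_s

  repeat {
    if (Sys.time() > endTime) break
    # accept any pending connections
    while (isTRUE(tryCatch(socketSelect(list(srv), timeout = 0),
                           error = function(e) FALSE))) {
      con <- socketAccept(srv, blocking = TRUE, open = "r+")
      c_state <- new.env(parent = emptyenv())
      c_state$con <- con
      c_state$sessionId <- NULL
      st$conns <- c(st$conns, list(c_state))
      logMsg(st, "debug", "connection accepted")
    }
    busy <- length(st$tasks) > 0 || length(st$waiters) > 0
    if (length(st$conns)) {
      ready <- tryCatch(
        socketSelect(lapply(st$conns, function(x) x$con),
                     timeout = if (busy) 0 else 0.05),
        error = function(e) rep(FALSE, length(st$conns)))
      drop <- logical(length(st$conns))
      for (i in which(ready)) {
        drop[i] <- !handleRequest(st, st$conns[[i]])
      }
      if (any(drop)) {
        for (i in which(drop)) try(close(st$conns[[i]]$con), silent = TRUE)
        st$conns <- st$conns[!drop]
      }
    } else if (!busy) {
      Sys.sleep(0.05)
    }
    # advance long-running work, one step per task per loop pass
    if (length(st$tasks)) {
      finished <- logical(length(st$tasks))
      for (i in seq_along(st$tasks)) {
        t <- st$tasks[[i]]
        finished[i] <- taskStep(t)
        if (finished[i] && !is.null(t$conn)) {
          status <- tryCatch(queryStatus(t$session$id, t$command),
                             error = function(e) "FAILED")
          if (status == "DONE") {
            sendResponse(t$conn$con, "OK", "DONE")
          } else {
            sendResponse(t$conn$con, paste(
              "ERROR", errorReason(t$session$failReason %||% "command failed")))
          }
        }
        if (finished[i]) {
          logMsg(st, "info", t$command, " [", t$session$id, "] -> ",
                 tryCatch(queryStatus(t$session$id, t$command),
                          error = function(e) "?"))
        }
      }
      st$tasks <- st$tasks[!finished]
    }
    # answer parked blocking queries whose value has arrived
    if (length(st$waiters)) {
      doneW <- logical(length(st$waiters))
      for (i in seq_along(st$waiters)) {
        w <- st$waiters[[i]]
        res <- tryCatch(w$check(), error = function(e) e)
        if (inherits(res, "error")) {
          sendResponse(w$conn$con, paste("ERROR", errorReason(conditionMessage(res))))
          doneW[i] <- TRUE
        } else if (!is.null(res)) {
          sendResponse(w$conn$con, "OK", res)
          doneW[i] <- TRUE
        } else if (Sys.time() > w$deadline) {
          sendResponse(w$conn$con, "ERROR TIMEOUT")
          doneW[i] <- TRUE
        }
      }
      st$waiters <- st$waiters[!doneW]
    }
  }
  for (x in st$conns) try(close(x$con), silent = TRUE)
  invisible(st$served)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logMsg <- function(st, level, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[st$log_level %||% "info"]] < levels[[level]]) return(invisible())
  cat(format(Sys.time(), "%H:%M:%OS3 "), ..., "\n", sep = "", file = stderr())
}

# Read one request line from a connection and dispatch it. Returns FALSE if
# the peer closed the connection.
handleRequest <- function(st, c_state) {
  line <- tryCatch(readLines(c_state$con, n = 1), error = function(e) character())
  if (length(line) == 0L) return(FALSE)
  st$served <- st$served + 1L
  msg <- tryCatch(parseCommand(line), error = function(e) e)
  if (inherits(msg, "error")) {
    reason <- sub("^ERROR ", "", gsub("[\r\n]+", " ", conditionMessage(msg)))
    logMsg(st, "info", "request '", line, "' -> ERROR ", reason)
    sendResponse(c_state$con, paste("ERROR", reason))
    return(TRUE)
  }
  logMsg(st, "debug", "request [", c_state$sessionId %||% "-", "] ", line)
  out <- tryCatch(dispatch(st, c_state, msg), error = function(e) e)
  if (inherits(out, "error")) {
    reason <- errorReason(conditionMessage(out))
    logMsg(st, "info", msg$verb, " -> ERROR ", reason)
    sendResponse(c_state$con, paste("ERROR", reason))
  }
  TRUE
}

# Resolve the session a command applies to: an explicit token argument wins,
# else the session bound to this connection, else (supporting the blocking
# single-connection flow that never sends NEWSESSION) a default session is
# created and bound.
resolveSession <- function(st, c_state, args, create = TRUE) {
  if (length(args) >= 1L && sessionExists(args[1])) {
    return(list(session = getSession(args[1]), args = args[-1]))
  }
  if (!is.null(c_state$sessionId)) {
    # bound id must still be live; a query after ENDSESSION is an error
    return(list(session = getSession(c_state$sessionId), args = args))
  }
  if (!create) stop("unknown session ''")
  id <- createSession(st$defaultParams)
  c_state$sessionId <- id
  list(session = getSession(id), args = args)
}

scheduleTask <- function(st, c_state, task, blocking) {
  st$tasks <- c(st$tasks, list(task))
  if (blocking) {
    task$conn <- c_state # reply deferred until the task finishes
  } else {
    sendResponse(c_state$con, "OK", "SCHEDULED")
  }
  invisible(NULL)
}

addWaiter <- function(st, c_state, check, timeout_s) {
  w <- new.env(parent = emptyenv())
  w$conn <- c_state
  w$check <- check
  w$deadline <- Sys.time() + timeout_s
  st$waiters <- c(st$waiters, list(w))
  invisible(NULL)
}

ensureConfig <- function(st, session) {
  if (is.null(session$params)) {
    if (is.null(st$defaultParams)) stop("NO_CONFIG")
    session$params <- st$defaultParams
  }
  invisible(session$params)
}

dispatch <- function(st, c_state, msg) {
  verb <- msg$verb
  if (verb == "NEWSESSION") {
    id <- createSession(st$defaultParams)
    c_state$sessionId <- id
    sendResponse(c_state$con, "OK", id)
    return(invisible())
  }
  if (verb == "SESSION") return(dispatchSessionQuery(st, c_state, msg))

  r <- resolveSession(st, c_state, msg$args)
  session <- r$session
  args <- r$args

  if (verb == "ENDSESSION") {
    endSession(session$id)
    if (identical(c_state$sessionId, session$id)) c_state$sessionId <- NULL
    sendResponse(c_state$con, "OK")
    return(invisible())
  }
  if (verb == "READCONFIG") {
    if (length(args) != 1L) stop("BAD_ARGS READCONFIG needs a byte count")
    nbytes <- suppressWarnings(as.integer(args[1]))
    if (is.na(nbytes) || nbytes <= 0L) stop("BAD_ARGS bad byte count")
    payload <- readChar(c_state$con, nbytes, useBytes = TRUE)
    session$params <- parseStudyParams(payload)
    sendResponse(c_state$con, "OK")
    return(invisible())
  }
  if (verb == "PLUGIN") {
    if (length(args) < 1L) stop("BAD_ARGS PLUGIN needs a plug-in name")
    binding <- if (length(args) >= 7L) pluginBinding(args[1], args[2:7])
               else pluginBinding(args[1])
    session$pluginBinding <- binding
    sendResponse(c_state$con, "OK")
    return(invisible())
  }
  if (verb %in% c("PREPROC", "NBPREPROC")) {
    ensureConfig(st, session)
    scheduleTask(st, c_state, makePreprocTask(session), blocking = verb == "PREPROC")
    return(invisible())
  }
  if (verb %in% c("PIPELINE", "NBPIPELINE", "FEEDBACK", "NBFEEDBACK")) {
    ensureConfig(st, session)
    task <- makeProcessTask(session, compute_feedback = verb %in% c("FEEDBACK", "NBFEEDBACK"))
    scheduleTask(st, c_state, task, blocking = verb %in% c("PIPELINE", "FEEDBACK"))
    return(invisible())
  }
  if (verb %in% c("GLM", "NBGLM")) {
    ensureConfig(st, session)
    scheduleTask(st, c_state, makeGlmTask(session), blocking = verb == "GLM")
    return(invisible())
  }
  if (verb %in% c("FEATURESELECTION", "NBFEATURESELECTION")) {
    ensureConfig(st, session)
    pfrac <- if (length(args) >= 1L) as.numeric(args[1]) else NULL
    scheduleTask(st, c_state, makeFeatureSelectionTask(session, pfrac),
                 blocking = verb == "FEATURESELECTION")
    return(invisible())
  }
  if (verb %in% c("TRAIN", "NBTRAIN")) {
    ensureConfig(st, session)
    scheduleTask(st, c_state, makeTrainTask(session), blocking = verb == "TRAIN")
    return(invisible())
  }
  if (verb == "TEST") {
    if (length(args) != 1L) stop("BAD_ARGS TEST needs a volume index")
    index <- checkVolumeIndex(session, args[1])
    timeout <- if (!is.null(session$params)) session$params$poll_timeout_s else 10
    sid <- session$id
    addWaiter(st, c_state, function() {
      res <- queryFeedback(sid, index)
      if (isNotReady(res)) NULL else formatFeedbackPayload(res)
    }, timeout)
    return(invisible())
  }
  if (verb == "GRAPHPARS") {
    if (length(args) != 1L) stop("BAD_ARGS GRAPHPARS needs a volume index")
    index <- checkVolumeIndex(session, args[1])
    timeout <- if (!is.null(session$params)) session$params$poll_timeout_s else 10
    sid <- session$id
    addWaiter(st, c_state, function() {
      res <- queryMotion(sid, index)
      if (isNotReady(res)) NULL else formatMotionPayload(res)
    }, timeout)
    return(invisible())
  }
  stop("UNKNOWN_COMMAND ", verb) # unreachable: parseCommand vets the verb
}

# SESSION/* queries: immediate, idempotent, never blocking.
dispatchSessionQuery <- function(st, c_state, msg) {
  r <- resolveSession(st, c_state, msg$args, create = FALSE)
  session <- r$session
  args <- r$args
  sub <- msg$subcommand
  if (sub %in% longCommands()) {
    status <- queryStatus(session$id, sub)
    payload <- status
    if (status == "FAILED" && !is.null(session$failReason)) {
      payload <- c(payload, gsub("[\r\n]+", " ", session$failReason))
    }
    sendResponse(c_state$con, "OK", payload)
    return(invisible())
  }
  if (sub == "TEST") {
    if (length(args) != 1L) stop("BAD_ARGS SESSION/TEST needs a volume index")
    res <- queryFeedback(session$id, args[1])
    if (isNotReady(res)) sendResponse(c_state$con, "NOT_READY")
    else sendResponse(c_state$con, "OK", formatFeedbackPayload(res))
    return(invisible())
  }
  if (sub == "GRAPHPARS") {
    if (length(args) != 1L) stop("BAD_ARGS SESSION/GRAPHPARS needs a volume index")
    res <- queryMotion(session$id, args[1])
    if (isNotReady(res)) sendResponse(c_state$con, "NOT_READY")
    else sendResponse(c_state$con, "OK", formatMotionPayload(res))
    return(invisible())
  }
  stop("BAD_ARGS unsupported SESSION subcommand ", sub)
}

#' Launch an engine server in a background R process
#'
#' Starts `Rscript -e 'nfengine::engineServe(...)'` on a free port and waits
#' until the server reports readiness. Used by the reference client examples,
#' the test-suite and the acceptance script.
#'
#' @param config_path Optional default study configuration for the server.
#' @param port Port to use; `NULL` picks random ports until one binds.
#' @param max_runtime_s Safety cap on the background server's lifetime.
#' @param wait_s How long to wait for readiness before giving up.
#' @param log_file File collecting the server's log output.
#' @return A handle list with `host`, `port`, `pid`, `log_file`; pass it to
#'   [stopEngine()].
#' @export
launchEngine <- function(config_path = NULL, port = NULL, max_runtime_s = 600,
                         wait_s = 20, log_file = tempfile("engine-log-")) {
  rscript <- file.path(R.home("bin"), "Rscript")
  tryPorts <- if (is.null(port)) sample(20000:60000, 5) else port
  for (p in tryPorts) {
    ready <- tempfile("engine-ready-")
    expr <- sprintf(
      "nfengine::engineServe(port=%d, config_path=%s, ready_file='%s', max_runtime_s=%d, log_level='info')",
      p,
      if (is.null(config_path)) "NULL" else sprintf("'%s'", config_path),
      ready, as.integer(max_runtime_s))
    system2(rscript, c("--vanilla", "-e", shQuote(expr)),
            stdout = log_file, stderr = log_file, wait = FALSE)
    deadline <- Sys.time() + wait_s
    while (Sys.time() < deadline && !file.exists(ready)) Sys.sleep(0.05)
    if (file.exists(ready)) {
      info <- scan(ready, what = integer(), n = 2, quiet = TRUE)
      return(list(host = "127.0.0.1", port = p, pid = info[1],
                  log_file = log_file, ready_file = ready))
    }
  }
  stop("engine failed to start; log tail:\n",
       paste(utils::tail(readLines(log_file, warn = FALSE), 5), collapse = "\n"))
}

#' @rdname launchEngine
#' @param handle Handle returned by [launchEngine()].
#' @export
stopEngine <- function(handle) {
  try(tools::pskill(handle$pid), silent = TRUE)
  unlink(handle$ready_file)
  invisible(NULL)
}
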
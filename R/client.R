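# Reference terminal frontend: drives the full protocol sequence against a
# running engine and renders feedback as a one-line text thermometer.

#' Low-level protocol access
#'
#' `engineConnect` opens a client connection to a running engine;
#' `engineRequest` performs one request/response round trip (framing the
#' optional payload and reading the reply through its blank-line
#' terminator). [runSession()] is built on these; they are exported for
#' frontend developers who drive the protocol directly.
#'
#' @param host,port Engine address.
#' @param timeout_s Socket timeout.
#' @param con Connection from `engineConnect`.
#' @param line Request line (no trailing newline).
#' @param payload Optional raw payload text (for `READCONFIG <n_bytes>`).
#' @return `engineRequest`: list with `status` (the status line), `ok`,
#'   `not_ready`, and `payload` (character vector of payload lines).
#' @export
engineConnect <- function(host, port, timeout_s = 10) {
  connectEngine(host, port, timeout_s)
}

#' @rdname engineConnect
#' @export
engineRequest <- function(con, line, payload = NULL) {
  sendCommand(con, line, payload)
}

connectEngine <- function(host, port, timeout_s = 10) {
  con <- tryCatch(
    suppressWarnings(socketConnection(host, port, blocking = TRUE, open = "r+",
                                      timeout = timeout_s)),
    error = function(e) stop("cannot connect to engine at ", host, ":", port,
                             " (", conditionMessage(e), ")"))
  con
}

# One request/response round trip over the wire.
sendCommand <- function(con, line, payload = NULL) {
  writeLines(line, con)
  if (!is.null(payload)) {
    writeChar(payload, con, eos = NULL)
  }
  flush(con)
  status <- readLines(con, n = 1)
  if (length(status) == 0L) stop("engine closed the connection")
  lines <- character()
  repeat {
    l <- readLines(con, n = 1)
    if (length(l) == 0L) stop("engine closed the connection mid-reply")
    if (l == "") break
    lines <- c(lines, l)
  }
  list(status = status, ok = identical(status, "OK"),
       not_ready = identical(status, "NOT_READY"), payload = lines)
}

stopOnError <- function(resp, context) {
  if (startsWith(resp$status, "ERROR")) {
    stop(sprintf("engine error during %s: %s", context, resp$status))
  }
  resp
}

#' Render a feedback value as a text thermometer
#'
#' Deterministic one-line gauge: `k` filled cells out of `width`, with
#' `k = clamp(round(value / scale * width), 0, width)`, the numeric value and
#' the class label printed beside the bar. This is the terminal counterpart
#' of the thermometer displays used by graphical frontends.
#'
#' @param value Feedback value (e.g. fractional signal change); `NA` renders
#'   an empty bar.
#' @param scale Value mapped to a full bar (> 0).
#' @param width Bar width in cells.
#' @param class_label Optional class label to print.
#' @return The gauge string, invisibly printable with `cat`.
#' @export
renderFeedback <- function(value, scale, width = 40, class_label = NULL) {
  stopifnot(scale > 0)
  k <- if (is.na(value)) 0L else max(0L, min(width, as.integer(round(value / scale * width))))
  sprintf("[%s%s] %s%s",
          strrep("#", k), strrep(" ", width - k),
          if (is.na(value)) "NA" else format(value, digits = 4),
          if (is.null(class_label)) "" else sprintf(" (class %s)", class_label))
}

pollBackoff <- function(s) min(1, s * 1.5)

#' Run a complete neurofeedback session as a frontend
#'
#' Drives the full protocol sequence against a running engine. In
#' non-blocking mode: `NEWSESSION`, `READCONFIG` (whole file over the wire),
#' `PLUGIN`, `NBPREPROC` + polling `SESSION/PREPROC`, `NBFEEDBACK`, then per
#' volume polling `SESSION/TEST` and `SESSION/GRAPHPARS` until each value is
#' available, and finally `ENDSESSION`. In blocking mode the client uses
#' `PREPROC`/`FEEDBACK`/`TEST` without polling (and without `NEWSESSION`,
#' which is only needed for asynchronous communication: the engine binds a
#' default session to the connection).
#'
#' @param host,port Engine address.
#' @param config_path Study configuration file to send via `READCONFIG`.
#' @param plugin Plug-in name (hook names are filled in from the registry).
#' @param mode `"nb"` (non-blocking, polled) or `"blocking"`.
#' @param poll_s Initial poll cadence, seconds (exponential backoff, 1 s
#'   cap).
#' @param timeout_s Abort if a polled value does not appear within this time.
#' @param render Optional callback `function(index, class_label, value)`
#'   invoked per volume (e.g. to print [renderFeedback()]); `NULL` disables
#'   display.
#' @param report_path Optional path for a tab-separated per-volume report.
#' @param end_session Send `ENDSESSION` when done? Set `FALSE` to leave the
#'   workspace live for further queries (e.g. by a quality-control frontend).
#' @return A `clientRunReport` list: `session_id`, `results` (one row per
#'   volume: index, class label, feedback value(s), motion rms),
#'   `timeline` (timestamped commands), `final_status`.
#' @export
runSession <- function(host, port, config_path, plugin = "libROI",
                       mode = c("nb", "blocking"), poll_s = 0.1,
                       timeout_s = 120, render = NULL, report_path = NULL,
                       end_session = TRUE) {
  mode <- match.arg(mode)
  cfgText <- paste(readLines(config_path, warn = FALSE), collapse = "\n")
  params <- parseStudyParams(cfgText)
  n <- params$n_volumes
  con <- connectEngine(host, port)
  on.exit(try(close(con), silent = TRUE), add = TRUE)

  timeline <- list()
  rec <- function(cmd, status) {
    timeline[[length(timeline) + 1L]] <<- list(
      time = as.numeric(Sys.time()), command = cmd, status = status)
  }
  ask <- function(line, payload = NULL, context = line) {
    resp <- sendCommand(con, line, payload)
    rec(context, resp$status)
    stopOnError(resp, context)
  }
  pollUntil <- function(mkLine, done, context) {
    s <- poll_s
    deadline <- Sys.time() + timeout_s
    repeat {
      resp <- sendCommand(con, mkLine())
      rec(context, resp$status)
      out <- done(resp)
      if (!is.null(out)) return(out)
      if (Sys.time() > deadline) stop("TIMEOUT polling ", context)
      Sys.sleep(s)
      s <- pollBackoff(s)
    }
  }

  sid <- NULL
  if (mode == "nb") {
    sid <- ask("NEWSESSION")$payload[1]
  }
  sidArg <- function() if (is.null(sid)) "" else paste0(" ", sid)
  ask(sprintf("READCONFIG %d", nchar(cfgText, type = "bytes")), payload = cfgText,
      context = "READCONFIG")
  hooks <- pluginHookNames(plugin)
  ask(paste(c("PLUGIN", plugin, hooks), collapse = " "), context = "PLUGIN")

  if (mode == "nb") {
    ask("NBPREPROC")
    status <- pollUntil(function() sprintf("SESSION/PREPROC %s", sid),
                        function(r) {
                          st <- r$payload[1]
                          if (st %in% c("DONE", "FAILED")) st else NULL
                        }, "SESSION/PREPROC")
    if (status != "DONE") stop("PREPROC failed on the engine")
    ask("NBFEEDBACK")
  } else {
    ask("PREPROC")
    ask("FEEDBACK")
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (mode == "nb") {
      fb <- pollUntil(function() sprintf("SESSION/TEST %s %d", sid, i),
                      function(r) if (r$ok) r$payload[1] else NULL,
                      sprintf("SESSION/TEST %d", i))
      mo <- pollUntil(function() sprintf("SESSION/GRAPHPARS %s %d", sid, i),
                      function(r) if (r$ok) r$payload[1] else NULL,
                      sprintf("SESSION/GRAPHPARS %d", i))
    } else {
      fb <- ask(sprintf("TEST %d", i))$payload[1]
      mo <- ask(sprintf("GRAPHPARS %d", i))$payload[1]
    }
    fbTok <- strsplit(fb, " ", fixed = TRUE)[[1]]
    moTok <- suppressWarnings(as.numeric(strsplit(mo, " ", fixed = TRUE)[[1]]))
    value <- suppressWarnings(as.numeric(fbTok[2]))
    rows[[i]] <- data.frame(
      index = i,
      class_label = as.integer(fbTok[1]),
      feedback_value = value,
      feedback_value2 = if (length(fbTok) >= 3)
        suppressWarnings(as.numeric(fbTok[3])) else NA_real_,
      rms = moTok[7]
    )
    if (!is.null(render)) render(i, as.integer(fbTok[1]), value)
  }

  finalStatus <- if (mode == "nb") {
    pollUntil(function() sprintf("SESSION/FEEDBACK %s", sid),
              function(r) {
                st <- r$payload[1]
                if (st %in% c("DONE", "FAILED")) st else NULL
              }, "SESSION/FEEDBACK")
  } else "DONE"
  if (end_session) ask("ENDSESSION", context = "ENDSESSION")

  report <- structure(list(
    session_id = sid,
    results = do.call(rbind, rows),
    timeline = do.call(rbind, lapply(timeline, as.data.frame)),
    final_status = finalStatus
  ), class = "clientRunReport")
  if (!is.null(report_path)) {
    utils::write.table(report$results, report_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  report
}

#' @export
print.clientRunReport <- function(x, ...) {
  cat(sprintf("client run %s: %d volumes, final status %s\n",
              x$session_id %||% "(default session)", nrow(x$results),
              x$final_status))
  invisible(x)
}
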
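# Wire protocol.
#
# Messages are newline-terminated UTF-8 lines of space-separated tokens.
# Multi-line payloads (READCONFIG) are framed as `READCONFIG <n_bytes>`
# followed by exactly n_bytes of configuration text. Every request receives
# exactly one reply: a status line (`OK`, `ERROR <reason>`, `NOT_READY`),
# zero or more payload lines, then a blank line terminator.

#' The engine command set
#'
#' All verbs the protocol accepts. `NB`-prefixed verbs share a handler with
#' their blocking twin but are dispatched non-blocking: the reply is sent as
#' soon as the work is scheduled and progress is observed through
#' `SESSION/...` queries.
#'
#' @return Character vector of verbs.
#' @export
engineCommandSet <- function() {
  c("NEWSESSION", "ENDSESSION", "SESSION", "READCONFIG", "PLUGIN",
    "PREPROC", "NBPREPROC", "PIPELINE", "NBPIPELINE",
    "FEEDBACK", "NBFEEDBACK", "GLM", "NBGLM",
    "FEATURESELECTION", "NBFEATURESELECTION",
    "TRAIN", "NBTRAIN", "TEST", "GRAPHPARS")
}

sessionSubcommands <- function() {
  c("GRAPHPARS", "TEST", "PREPROC", "FEEDBACK", "PIPELINE", "GLM",
    "FEATURESELECTION", "TRAIN")
}

#' Parse one protocol message
#'
#' Splits a request line into verb and arguments. Compound queries such as
#' `SESSION/GRAPHPARS` or `SESSION/TEST` parse to verb `SESSION` with the
#' subcommand as a separate field. `PLUG-IN` is accepted as an alias of
#' `PLUGIN`.
#'
#' @param line One newline-terminated message (without the newline).
#' @return A `commandMessage` list: `verb`, `subcommand` (or `NA`), `args`.
#' @export
parseCommand <- function(line) {
  toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  if (length(toks) == 0L || !nzchar(toks[1])) stop("ERROR BAD_ARGS empty command")
  verb <- toupper(toks[1])
  if (verb == "PLUG-IN") verb <- "PLUGIN"
  sub <- NA_character_
  if (grepl("/", verb, fixed = TRUE)) {
    parts <- strsplit(verb, "/", fixed = TRUE)[[1]]
    verb <- parts[1]
    sub <- parts[2]
  }
  if (!verb %in% engineCommandSet()) {
    stop("ERROR UNKNOWN_COMMAND ", verb)
  }
  if (verb == "SESSION") {
    if (is.na(sub) || !sub %in% sessionSubcommands()) {
      stop("ERROR BAD_ARGS SESSION requires a subcommand, e.g. SESSION/PREPROC")
    }
  } else if (!is.na(sub)) {
    stop("ERROR UNKNOWN_COMMAND ", paste0(verb, "/", sub))
  }
  structure(list(verb = verb, subcommand = sub, args = toks[-1]),
            class = "commandMessage")
}

# Reply helpers -------------------------------------------------------------

formatResponse <- function(status, payload = character()) {
  c(status, payload, "")
}

sendResponse <- function(con, status, payload = character()) {
  writeLines(formatResponse(status, payload), con)
  flush(con)
}

# Classify handler errors into wire reasons. Messages already carrying a
# protocol token (NO_CONFIG, TIMEOUT, ...) pass through; session lookup and
# index failures map to their tokens; anything else is reported verbatim on
# one line.
errorReason <- function(msg) {
  msg <- gsub("[\r\n]+", " ", msg)
  if (grepl("unknown session", msg)) return(paste("UNKNOWN_SESSION", msg))
  if (grepl("volume index out of range", msg)) return(paste("BAD_INDEX", msg))
  if (grepl("unknown plug-in|has no function", msg)) return(paste("BAD_PLUGIN", msg))
  msg
}

formatFeedbackPayload <- function(res) {
  vals <- vapply(res$feedback_value, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 17, scientific = TRUE)
  }, "")
  paste(c(res$class_label, vals), collapse = " ")
}

formatMotionPayload <- function(mp) {
  paste(vapply(c(mp$tx, mp$ty, mp$tz, mp$rx, mp$ry, mp$rz, mp$rms),
               function(v) format(v, digits = 17, scientific = TRUE), ""),
        collapse = " ")
}
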
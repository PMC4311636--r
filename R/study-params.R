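#' Parse a study configuration
#'
#' Reads the key--value study configuration dialect used by the engine and the
#' `READCONFIG` protocol command. One `key=value` pair per line; lines starting
#' with `#` and blank lines are ignored. The block design is given as repeated
#' `design=CONDITION:start-end` entries (1-based closed volume-index ranges)
#' and ROI masks as repeated `roi_mask=path` entries, both kept in file order.
#'
#' Mandatory keys are `input_dir`, `n_volumes` and at least one `design`
#' entry. All other keys take documented defaults (see
#' [defaultStudyParams()]). Design ranges must be disjoint and jointly cover
#' `1..n_volumes`.
#'
#' @param text Character scalar (possibly multi-line) or character vector of
#'   lines with the configuration content.
#' @return A validated `studyParams` object (a classed list).
#' @seealso [serializeStudyParams()] for the inverse operation.
#' @examples
#' p <- parseStudyParams(c(
#'   "input_dir=/tmp/in", "n_volumes=10",
#'   "design=BASELINE:1-5", "design=TASK:6-10"))
#' p$n_volumes
#' @export
parseStudyParams <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  raw <- list()
  design <- list()
  masks <- character()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) {
      stop(sprintf("study params: line %d is not a key=value pair: '%s'", i, ln))
    }
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    if (key == "design") {
      m <- regmatches(val, regexec("^([^:]+):([0-9]+)-([0-9]+)$", val))[[1]]
      if (length(m) != 4L) {
        stop(sprintf("study params: malformed design range at line %d: '%s'", i, val))
      }
      design[[length(design) + 1L]] <- list(
        condition = m[[2]],
        start = as.integer(m[[3]]),
        end = as.integer(m[[4]])
      )
    } else if (key == "roi_mask") {
      masks <- c(masks, val)
    } else {
      raw[[key]] <- val
    }
  }

  for (key in c("input_dir", "n_volumes")) {
    if (is.null(raw[[key]])) {
      stop(sprintf("study params: mandatory key '%s' is missing", key))
    }
  }
  if (length(design) == 0L) {
    stop("study params: mandatory key 'design' is missing (no design blocks)")
  }

  num <- function(key, default) {
    if (is.null(raw[[key]])) return(default)
    v <- suppressWarnings(as.numeric(raw[[key]]))
    if (is.na(v)) stop(sprintf("study params: key '%s' is not numeric: '%s'", key, raw[[key]]))
    v
  }
  chr <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]
  flag <- function(key, default) {
    if (is.null(raw[[key]])) return(default)
    tolower(raw[[key]]) %in% c("on", "true", "1", "yes")
  }

  nVolumes <- as.integer(num("n_volumes", NA))
  inputDir <- raw[["input_dir"]]

  params <- structure(list(
    input_dir = inputDir,
    workspace_dir = chr("workspace_dir", file.path(dirname(inputDir), "engine_workspace")),
    volume_prefix = chr("volume_prefix", "vol"),
    index_width = as.integer(num("index_width", 5)),
    n_volumes = nVolumes,
    tr_seconds = num("tr_seconds", 2),
    design = design,
    baseline_condition = chr("baseline_condition", design[[1]]$condition),
    roi_mask_paths = masks,
    reference_volume = chr("reference_volume", ""),
    sliding_window_L = as.integer(num("sliding_window_L", min(30L, nVolumes))),
    feature_fraction_p = num("feature_fraction_p", 1),
    smoothing_fwhm_mm = num("smoothing_fwhm_mm", 0),
    activation_threshold = num("activation_threshold", 0),
    poll_timeout_s = num("poll_timeout_s", 10),
    motion_correction = flag("motion_correction", TRUE),
    hrf = flag("hrf", TRUE),
    svm_model_path = chr("svm_model_path", ""),
    debug_delay_s = num("debug_delay_s", 0)
  ), class = "studyParams")
  validateStudyParams(params)
  params
}

#' Default study parameters
#'
#' Convenience constructor returning the `studyParams` defaults for a given
#' input directory, volume count and design, bypassing the text dialect.
#'
#' @param input_dir Directory watched for incoming volumes.
#' @param n_volumes Number of volumes in the acquisition run.
#' @param design List of blocks, each `list(condition=, start=, end=)`.
#' @param ... Further `studyParams` fields overriding the defaults.
#' @return A validated `studyParams` object.
#' @export
defaultStudyParams <- function(input_dir, n_volumes, design, ...) {
  txt <- c(
    paste0("input_dir=", input_dir),
    paste0("n_volumes=", n_volumes),
    vapply(design, function(b) sprintf("design=%s:%d-%d", b$condition, b$start, b$end), "")
  )
  p <- parseStudyParams(txt)
  dots <- list(...)
  for (k in names(dots)) p[[k]] <- dots[[k]]
  validateStudyParams(p)
  p
}

validateStudyParams <- function(p) {
  stopifnot(inherits(p, "studyParams"))
  if (is.na(p$n_volumes) || p$n_volumes < 1L) {
    stop("study params: n_volumes must be a positive integer")
  }
  if (p$tr_seconds <= 0) stop("study params: tr_seconds must be positive")
  if (p$poll_timeout_s <= 0) stop("study params: poll_timeout_s must be positive")
  if (p$smoothing_fwhm_mm < 0) stop("study params: smoothing_fwhm_mm must be >= 0")
  if (p$feature_fraction_p <= 0 || p$feature_fraction_p > 1) {
    stop("study params: feature_fraction_p must lie in (0, 1]")
  }
  if (p$sliding_window_L < 2L || p$sliding_window_L > p$n_volumes) {
    stop("study params: sliding_window_L must lie in [2, n_volumes]")
  }
  covered <- integer(0)
  for (b in p$design) {
    if (b$start < 1L || b$end > p$n_volumes || b$start > b$end) {
      stop(sprintf("study params: design block %s:%d-%d outside 1..%d",
                   b$condition, b$start, b$end, p$n_volumes))
    }
    idx <- seq.int(b$start, b$end)
    if (any(idx %in% covered)) {
      stop(sprintf("study params: design block %s:%d-%d overlaps another block",
                   b$condition, b$start, b$end))
    }
    covered <- c(covered, idx)
  }
  if (length(covered) != p$n_volumes) {
    stop("study params: design blocks must jointly cover 1..n_volumes")
  }
  if (!(p$baseline_condition %in% vapply(p$design, `[[`, "", "condition"))) {
    stop("study params: baseline_condition does not appear in the design")
  }
  invisible(p)
}

#' Serialize study parameters
#'
#' Writes a `studyParams` object back to the text dialect accepted by
#' [parseStudyParams()]; `parseStudyParams(serializeStudyParams(p))` equals
#' `p` field by field, which is what the `READCONFIG` command relies on.
#'
#' @param p A `studyParams` object.
#' @return A single character scalar of configuration text.
#' @export
serializeStudyParams <- function(p) {
  stopifnot(inherits(p, "studyParams"))
  fmtNum <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    paste0("input_dir=", p$input_dir),
    paste0("workspace_dir=", p$workspace_dir),
    paste0("volume_prefix=", p$volume_prefix),
    paste0("index_width=", p$index_width),
    paste0("n_volumes=", p$n_volumes),
    paste0("tr_seconds=", fmtNum(p$tr_seconds)),
    vapply(p$design, function(b) sprintf("design=%s:%d-%d", b$condition, b$start, b$end), ""),
    paste0("baseline_condition=", p$baseline_condition),
    if (length(p$roi_mask_paths)) paste0("roi_mask=", p$roi_mask_paths),
    if (nzchar(p$reference_volume)) paste0("reference_volume=", p$reference_volume),
    paste0("sliding_window_L=", p$sliding_window_L),
    paste0("feature_fraction_p=", fmtNum(p$feature_fraction_p)),
    paste0("smoothing_fwhm_mm=", fmtNum(p$smoothing_fwhm_mm)),
    paste0("activation_threshold=", fmtNum(p$activation_threshold)),
    paste0("poll_timeout_s=", fmtNum(p$poll_timeout_s)),
    paste0("motion_correction=", if (p$motion_correction) "on" else "off"),
    paste0("hrf=", if (p$hrf) "on" else "off"),
    if (nzchar(p$svm_model_path)) paste0("svm_model_path=", p$svm_model_path),
    paste0("debug_delay_s=", fmtNum(p$debug_delay_s))
  )
  paste(lines, collapse = "\n")
}

#' @export
print.studyParams <- function(x, ...) {
  cat("Study parameters\n")
  cat(sprintf("  input_dir: %s\n  n_volumes: %d (TR %gs)\n",
              x$input_dir, x$n_volumes, x$tr_seconds))
  cat(sprintf("  design: %s\n", paste(vapply(
    x$design, function(b) sprintf("%s:%d-%d", b$condition, b$start, b$end), ""
  ), collapse = " ")))
  cat(sprintf("  baseline: %s; masks: %d; window L=%d; fwhm %g mm\n",
              x$baseline_condition, length(x$roi_mask_paths),
              x$sliding_window_L, x$smoothing_fwhm_mm))
  invisible(x)
}

#' Condition labels along the run
#'
#' `conditionAt` gives the condition name of one volume; `conditionIndexAt`
#' gives its integer label (the order of first appearance of each condition in
#' the design), which is what plug-ins report as the class of a scan.
#' `blockAt` returns the design block (with start/end) containing the volume.
#'
#' @param p A `studyParams` object.
#' @param index 1-based volume index.
#' @return Condition name, integer label, or block list.
#' @export
conditionAt <- function(p, index) {
  blockAt(p, index)$condition
}

#' @rdname conditionAt
#' @export
conditionIndexAt <- function(p, index) {
  conds <- unique(vapply(p$design, `[[`, "", "condition"))
  match(conditionAt(p, index), conds)
}

#' @rdname conditionAt
#' @export
blockAt <- function(p, index) {
  index <- as.integer(index)
  if (is.na(index) || index < 1L || index > p$n_volumes) {
    stop(sprintf("volume index %s out of range 1..%d", index, p$n_volumes))
  }
  for (b in p$design) {
    if (index >= b$start && index <= b$end) return(b)
  }
  stop("internal: design does not cover index ", index) # unreachable post-validation
}

#' Expected volume file name
#'
#' File naming convention for incoming volumes:
#' `<prefix><index padded to index_width>.nii`, 1-based.
#'
#' @param p A `studyParams` object.
#' @param index 1-based volume index.
#' @return File name (no directory).
#' @export
volumeFileName <- function(p, index) {
  sprintf("%s%0*d.nii", p$volume_prefix, p$index_width, as.integer(index))
}
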
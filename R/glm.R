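# General linear model for localizer runs: per-voxel ordinary least squares
# on [condition boxcars convolved with a canonical double-gamma HRF,
# intercept, linear drift], with a t statistic for a task-vs-baseline
# contrast.

#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = g(t; 6, 1) - g(t; 16, 1) / 6` with `g` the gamma density: response
#' peaking near 5-6 s with an undershoot near 15-16 s and a 1/6 undershoot
#' ratio, normalized to unit peak.
#'
#' @param t Time points, seconds (>= 0).
#' @return HRF values at `t`.
#' @export
hrfDoubleGamma <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Build a GLM design matrix from a block design
#'
#' One regressor per non-baseline condition: the condition's boxcar
#' (optionally convolved with [hrfDoubleGamma()] sampled at TR), plus an
#' intercept and a centered linear drift term.
#'
#' @param params A `studyParams` object (fields `design`, `n_volumes`,
#'   `tr_seconds`, `baseline_condition`).
#' @param hrf Convolve boxcars with the canonical HRF?
#' @return Numeric matrix `n_volumes x (n_task_conditions + 2)` with named
#'   columns.
#' @export
buildDesignMatrix <- function(params, hrf = params$hrf) {
  n <- params$n_volumes
  conds <- unique(vapply(params$design, `[[`, "", "condition"))
  task <- setdiff(conds, params$baseline_condition)
  if (length(task) == 0L) stop("design has no non-baseline condition")
  h <- hrfDoubleGamma((seq_len(n) - 1) * params$tr_seconds)
  cols <- lapply(task, function(cn) {
    box <- numeric(n)
    for (b in params$design) {
      if (b$condition == cn) box[b$start:b$end] <- 1
    }
    if (hrf) {
      conv <- as.numeric(stats::convolve(box, rev(h), type = "open"))[seq_len(n)]
      conv
    } else box
  })
  X <- cbind(do.call(cbind, cols), 1, seq_len(n) / n - (n + 1) / (2 * n))
  colnames(X) <- c(task, "intercept", "drift")
  X
}

#' Fit the GLM to one or many voxel series
#'
#' Ordinary least squares per column of `series` on the design matrix of
#' [buildDesignMatrix()], with `t = c'beta / sqrt(sigma2 c'(X'X)^-1 c)` for
#' the task contrast. Residual variance uses `n - p` degrees of freedom.
#' Series with (numerically) zero residual variance get `t = 0`.
#'
#' @param series Numeric vector of length `n_volumes`, or matrix
#'   `n_volumes x n_voxels`.
#' @param params A `studyParams` object describing the design.
#' @param hrf Convolve boxcars with the canonical HRF?
#' @param contrast Name of the task condition to test against baseline;
#'   default the first non-baseline condition.
#' @return A `glmFit` object: `beta` (p x V), `t` (length V), `sigma2`
#'   (length V), `df`, the design matrix `X` and the contrast vector.
#' @export
glmFit <- function(series, params, hrf = params$hrf, contrast = NULL) {
  Y <- if (is.matrix(series)) series else matrix(series, ncol = 1)
  X <- buildDesignMatrix(params, hrf = hrf)
  if (nrow(Y) != nrow(X)) {
    stop(sprintf("series length %d does not match n_volumes %d", nrow(Y), nrow(X)))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
  if (is.null(contrast)) contrast <- colnames(X)[1]
  if (!contrast %in% colnames(X)) stop("unknown contrast column: ", contrast)
  cvec <- as.numeric(colnames(X) == contrast)

  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  n <- nrow(X); p <- ncol(X)
  sigma2 <- colSums(res^2) / (n - p)
  xtxInv <- chol2inv(qr.R(qrX))
  varfac <- as.numeric(t(cvec) %*% xtxInv %*% cvec)
  num <- as.numeric(t(cvec) %*% beta)
  se <- sqrt(sigma2 * varfac)
  tval <- ifelse(se > sqrt(.Machine$double.eps) * pmax(1, abs(num)), num / se, 0)
  structure(list(beta = beta, t = tval, sigma2 = sigma2, df = n - p,
                 X = X, contrast = contrast, cvec = cvec),
            class = "glmFit")
}

#' @export
print.glmFit <- function(x, ...) {
  cat(sprintf("GLM fit: %d series, %d regressors (%s), df=%d, contrast=%s\n",
              length(x$t), ncol(x$X), paste(colnames(x$X), collapse = ", "),
              x$df, x$contrast))
  invisible(x)
}

#' Select the top fraction of voxels by a statistic
#'
#' Returns the `ceiling(p * N)` in-mask voxels with the highest statistic
#' values (`N` = in-mask voxel count). Every selected voxel's statistic is >=
#' every excluded in-mask voxel's; ties at the threshold are broken by lowest
#' linear voxel index, making the selection deterministic.
#'
#' @param stat Numeric array (or vector) of statistic values on the grid.
#' @param mask A `roiMask` or logical array: the candidate voxels.
#' @param p Fraction in (0, 1].
#' @return A `roiMask` restricted to the selected voxels.
#' @export
featureSelect <- function(stat, mask, p) {
  stopifnot(p > 0, p <= 1)
  isRoi <- inherits(mask, "roiMask")
  m <- if (isRoi) mask$mask else as.array(mask)
  stat <- as.array(stat)
  if (!identical(dim(stat), dim(m)) && !(is.null(dim(stat)) && length(stat) == length(m))) {
    stop("stat and mask shapes differ")
  }
  idx <- which(m)
  if (length(idx) == 0L) stop("empty mask")
  k <- ceiling(p * length(idx))
  keep <- idx[order(-as.numeric(stat)[idx], idx)][seq_len(k)]
  sel <- array(FALSE, dim(m))
  sel[keep] <- TRUE
  roiMask(sel,
          name = paste0(if (isRoi) mask$name else "mask", "_top"),
          voxel_dims_mm = if (isRoi) mask$voxel_dims_mm else c(1, 1, 1))
}
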
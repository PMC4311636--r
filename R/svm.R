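# Linear two-class maximum-margin brain decoding. Training delegates the
# quadratic program to libSVM (via e1071); the engine owns the per-feature
# z-scaling, extraction of the hyperplane (w, b), sign canonicalization, the
# projection x'w + b used as feedback, and model serialization.

#' Train a linear two-class SVM decoder
#'
#' Voxel vectors are z-scaled per feature with statistics fitted on the
#' training set, then a linear maximum-margin classifier is trained. The
#' hyperplane is returned in the scaled feature space as weights `w` and
#' offset `b`; the decision boundary is `x'w + b = 0` and a positive
#' projection corresponds to the first factor level of `labels`. When `cost`
#' is `NULL` a hard margin is attempted first (large penalty); if the data
#' are not linearly separable the model is refit as a soft margin with
#' `cost = 1`.
#'
#' @param X Numeric matrix, one row per training volume (features =
#'   concatenated voxels).
#' @param labels Two-class labels (factor or coercible); >= 2 samples per
#'   class.
#' @param cost Soft-margin penalty, or `NULL` for the hard-then-soft default.
#' @param tolerance Optimizer termination tolerance.
#' @param feature_idx Optional linear voxel indices the rows of `X` were
#'   extracted from; stored so [svmTest()] can subset whole volumes.
#' @return A `trainedSVM` object with fields `w`, `b`, `center`, `scale`,
#'   `levels`, `feature_idx`.
#' @export
svmTrain <- function(X, labels, cost = NULL, tolerance = 1e-8,
                     feature_idx = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in training data")
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("exactly 2 distinct labels required, got ", nlevels(y))
  if (any(table(y) < 2L)) stop("need at least 2 volumes per class")
  if (nrow(X) != length(y)) stop("label count does not match rows of X")

  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < .Machine$double.eps] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")

  fitOne <- function(C) {
    fit <- e1071::svm(Xs, y, kernel = "linear", scale = FALSE, cost = C,
                      tolerance = tolerance)
    w <- drop(crossprod(fit$coefs, fit$SV))
    b <- -fit$rho
    # canonicalize: positive projection <-> first level
    f <- drop(Xs %*% w) + b
    if (mean(f[y == levels(y)[1]]) < mean(f[y == levels(y)[2]])) {
      w <- -w; b <- -b; f <- -f
    }
    list(w = w, b = b, f = f, C = C)
  }
  if (is.null(cost)) {
    hard <- fitOne(1e6)
    sep <- all(ifelse(hard$f > 0, levels(y)[1], levels(y)[2]) == as.character(y))
    fit <- if (sep) hard else fitOne(1)
  } else {
    fit <- fitOne(cost)
  }
  structure(list(
    w = as.numeric(fit$w), b = fit$b, center = as.numeric(center),
    scale = as.numeric(scale), levels = levels(y), cost = fit$C,
    feature_idx = if (is.null(feature_idx)) NULL else as.integer(feature_idx),
    version = 1L
  ), class = "trainedSVM")
}

#' Project an observation on the SVM discriminating hyperplane
#'
#' Applies the stored feature mask and z-scaling, then returns the signed
#' projection `x'w + b`. The boundary between the two conditions is the value
#' zero: the predicted class label is 1 (first training level) for a positive
#' projection, 2 otherwise. The raw projection is returned as the feedback
#' value; `normalize = TRUE` divides by `||w||`, turning it into a geometric
#' distance to the hyperplane.
#'
#' @param x Numeric vector: a whole volume (subset by the stored
#'   `feature_idx`) or an already-extracted feature vector.
#' @param model A `trainedSVM`.
#' @param normalize Divide the projection by `||w||`?
#' @return A `feedbackResult` list: `class_label` (1 or 2), `feedback_value`
#'   (the projection), and `class_name`.
#' @export
svmTest <- function(x, model, normalize = FALSE) {
  stopifnot(inherits(model, "trainedSVM"))
  x <- as.numeric(x)
  if (!is.null(model$feature_idx) && length(x) != length(model$w)) {
    if (max(model$feature_idx) > length(x)) {
      stop("volume does not match the training grid")
    }
    x <- x[model$feature_idx]
  }
  if (length(x) != length(model$w)) {
    stop(sprintf("feature length %d does not match model dimension %d",
                 length(x), length(model$w)))
  }
  xs <- (x - model$center) / model$scale
  f <- sum(xs * model$w) + model$b
  if (normalize) f <- f / sqrt(sum(model$w^2))
  cls <- if (f > 0) 1L else 2L
  structure(list(class_label = cls, feedback_value = f,
                 class_name = model$levels[cls]),
            class = "feedbackResult")
}

#' @export
print.trainedSVM <- function(x, ...) {
  cat(sprintf("trainedSVM: %d features, |w|=%.4g, b=%.4g, classes %s/%s (cost %g)\n",
              length(x$w), sqrt(sum(x$w^2)), x$b, x$levels[1], x$levels[2], x$cost))
  invisible(x)
}

#' Serialize a trained SVM decoder
#'
#' Versioned JSON with the hyperplane, scaling and feature mask, so a model
#' trained in one session can be reused for decoding in later testing
#' sessions.
#'
#' @param model A `trainedSVM`.
#' @param path Output/input file path.
#' @return `loadTrainedSvm`: the restored `trainedSVM`.
#' @export
saveTrainedSvm <- function(model, path) {
  stopifnot(inherits(model, "trainedSVM"))
  obj <- unclass(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname saveTrainedSvm
#' @export
loadTrainedSvm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$version) || obj$version != 1L) {
    stop("unsupported trainedSVM file version")
  }
  structure(list(
    w = as.numeric(obj$w), b = as.numeric(obj$b),
    center = as.numeric(obj$center), scale = as.numeric(obj$scale),
    levels = as.character(obj$levels), cost = as.numeric(obj$cost),
    feature_idx = if (length(obj$feature_idx)) as.integer(obj$feature_idx) else NULL,
    version = 1L
  ), class = "trainedSVM")
}
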
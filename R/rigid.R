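# Rigid-body (6 DOF) volume registration with trilinear resampling.
#
# Conventions (documented and tested): grid indices are 0-based internally
# with voxel centers at integer coordinates; rotations are in degrees about
# the grid centroid, applied as Rz %*% Ry %*% Rx; translations are in mm and
# converted per-axis to voxel units. A parameter set p maps an output voxel
# coordinate v to the input-space sample point q = R (v - c) + c + t_vox, so
# applyRigid(vol, p)[v] = vol[q] by trilinear interpolation (0 out of field).

rotationMatrix <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; g <- rz * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Affine form of a rigid parameter set
#'
#' Returns the matrix `A` and offset `b` such that an output voxel coordinate
#' `v` (0-based) is sampled from input-space point `A v + b` (voxel units).
#'
#' @param params Numeric of length 6: `tx, ty, tz` (mm), `rx, ry, rz`
#'   (degrees), or a `motionParams` object.
#' @param voxel_dims_mm Voxel sizes, mm.
#' @param grid_shape Integer length-3 grid dimensions.
#' @return List with `A` (3x3 rotation) and `b` (length-3 offset, voxels).
#' @export
rigidTransform <- function(params, voxel_dims_mm, grid_shape) {
  p <- asRigidVector(params)
  R <- rotationMatrix(p[4], p[5], p[6])
  ctr <- (grid_shape - 1) / 2
  tvox <- p[1:3] / voxel_dims_mm
  list(A = R, b = as.numeric(ctr + tvox - R %*% ctr))
}

asRigidVector <- function(params) {
  if (inherits(params, "motionParams")) {
    params <- c(params$tx, params$ty, params$tz, params$rx, params$ry, params$rz)
  }
  p <- as.numeric(params)
  stopifnot(length(p) == 6L, all(is.finite(p)))
  p
}

# Trilinear sampling of `data` at 0-based coordinates (N x 3 matrix).
# Returns NA where the sample point falls outside the grid.
sampleTrilinear <- function(data, coords) {
  dm <- dim(data)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  valid <- x >= 0 & x <= dm[1] - 1 & y >= 0 & y <= dm[2] - 1 &
    z >= 0 & z <= dm[3] - 1
  out <- rep(NA_real_, nrow(coords))
  if (!any(valid)) return(out)
  x <- x[valid]; y <- y[valid]; z <- z[valid]
  i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  i1 <- pmin(i0 + 1, dm[1] - 1); j1 <- pmin(j0 + 1, dm[2] - 1)
  k1 <- pmin(k0 + 1, dm[3] - 1)
  nx <- dm[1]; nxy <- dm[1] * dm[2]
  lin <- function(i, j, k) 1 + i + nx * j + nxy * k
  d <- as.numeric(data)
  v <-
    d[lin(i0, j0, k0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    d[lin(i1, j0, k0)] * fx * (1 - fy) * (1 - fz) +
    d[lin(i0, j1, k0)] * (1 - fx) * fy * (1 - fz) +
    d[lin(i1, j1, k0)] * fx * fy * (1 - fz) +
    d[lin(i0, j0, k1)] * (1 - fx) * (1 - fy) * fz +
    d[lin(i1, j0, k1)] * fx * (1 - fy) * fz +
    d[lin(i0, j1, k1)] * (1 - fx) * fy * fz +
    d[lin(i1, j1, k1)] * fx * fy * fz
  out[valid] <- v
  out
}

gridCoords <- function(grid_shape) {
  as.matrix(expand.grid(
    x = seq_len(grid_shape[1]) - 1,
    y = seq_len(grid_shape[2]) - 1,
    z = seq_len(grid_shape[3]) - 1
  ))
}

#' Apply a rigid-body transform to a volume
#'
#' Trilinear resampling on the original grid; voxels whose sample point falls
#' outside the field of view are set to 0.
#'
#' @param volume 3-D numeric array (or `niftiImage`).
#' @param params Rigid parameters (see [rigidTransform()]).
#' @param voxel_dims_mm Voxel sizes, mm (taken from the image if available).
#' @return 3-D array of the same shape.
#' @export
applyRigid <- function(volume, params, voxel_dims_mm = voxelDims(volume)) {
  dm <- dim(volume)[1:3]
  tr <- rigidTransform(params, voxel_dims_mm, dm)
  P <- gridCoords(dm)
  q <- P %*% t(tr$A) + matrix(tr$b, nrow(P), 3, byrow = TRUE)
  v <- sampleTrilinear(as.array(volume), q)
  v[is.na(v)] <- 0
  array(v, dm)
}

#' Estimate rigid-body motion against a reference
#'
#' Finds the 6-parameter rigid transform `p` minimizing the mean squared
#' intensity difference between `applyRigid(volume, p)` and `reference`, by
#' derivative-free Nelder-Mead descent from the zero transform: a coarse stage
#' on a stride-2 subsample of the comparison region, then refinement at full
#' resolution. The objective is evaluated over the central region of the grid
#' (a `margin`-voxel border is excluded) so the cost surface is smooth under
#' small transforms. Deterministic given its inputs.
#'
#' @param volume,reference 3-D arrays on the same grid.
#' @param voxel_dims_mm Voxel sizes, mm.
#' @param margin Border (voxels) excluded from the objective.
#' @param maxit_coarse,maxit_fine Nelder-Mead iteration caps for the two
#'   stages.
#' @return A [motionParams()] object; `rms` is the root-mean-square intensity
#'   difference at the optimum. A constant (degenerate) input volume yields
#'   the identity transform with `degenerate = TRUE` and a warning.
#' @export
estimateMotion <- function(volume, reference, voxel_dims_mm = voxelDims(reference),
                           margin = 4, maxit_coarse = 300, maxit_fine = 200) {
  vol <- as.array(volume); ref <- as.array(reference)
  dm <- dim(ref)[1:3]
  stopifnot(identical(dim(vol)[1:3], dm))
  if (stats::sd(vol) < 1e-12 * max(1, abs(mean(vol)))) {
    warning("degenerate (constant) volume; returning identity transform")
    return(motionParams(rms = sqrt(mean((vol - ref)^2)), degenerate = TRUE))
  }
  ctrIdx <- function(n, m) seq.int(min(m, floor((n - 1) / 2)) + 1L,
                                   n - min(m, floor((n - 1) / 2)))
  ix <- ctrIdx(dm[1], margin); iy <- ctrIdx(dm[2], margin); iz <- ctrIdx(dm[3], margin)
  region <- function(stride) {
    g <- expand.grid(x = ix[seq(1, length(ix), by = stride)] - 1,
                     y = iy[seq(1, length(iy), by = stride)] - 1,
                     z = iz[seq(1, length(iz), by = stride)] - 1)
    P <- as.matrix(g)
    tgt <- ref[cbind(P[, 1] + 1, P[, 2] + 1, P[, 3] + 1)]
    list(P = P, tgt = tgt)
  }
  objective <- function(reg) {
    force(reg)
    function(p) {
      tr <- rigidTransform(p, voxel_dims_mm, dm)
      q <- reg$P %*% t(tr$A) + matrix(tr$b, nrow(reg$P), 3, byrow = TRUE)
      v <- sampleTrilinear(vol, q)
      ok <- !is.na(v)
      if (sum(ok) < length(v) / 2) return(1e12)
      mean((v[ok] - reg$tgt[ok])^2)
    }
  }
  coarse <- region(2L)
  fit1 <- stats::optim(rep(0, 6), objective(coarse), method = "Nelder-Mead",
                       control = list(maxit = maxit_coarse, reltol = 1e-10))
  fine <- region(1L)
  fObj <- objective(fine)
  fit2 <- stats::optim(fit1$par, fObj, method = "Nelder-Mead",
                       control = list(maxit = maxit_fine, reltol = 1e-12))
  p <- fit2$par
  motionParams(p[1], p[2], p[3], p[4], p[5], p[6], rms = sqrt(fObj(p)))
}

#' Recovery error between a true and an estimated transform
#'
#' When a volume is produced by `applyRigid(ref, true)` and the correction is
#' estimated with [estimateMotion()], a perfect estimate satisfies
#' `A_true(A_est(x)) = x`. This helper composes the two sample maps and
#' reports how far the composition is from the identity: residual translation
#' magnitude (voxels) and residual rotation angle (degrees).
#'
#' @param true_params,est_params Rigid parameter sets.
#' @param grid_shape Grid dimensions.
#' @param voxel_dims_mm Voxel sizes, mm.
#' @return List with `translation_vox` and `rotation_deg`.
#' @export
motionRecoveryError <- function(true_params, est_params, grid_shape,
                                voxel_dims_mm = c(1, 1, 1)) {
  Tt <- rigidTransform(true_params, voxel_dims_mm, grid_shape)
  Te <- rigidTransform(est_params, voxel_dims_mm, grid_shape)
  # composition of sample maps: v -> A_t (A_e v + b_e) + b_t
  R <- Tt$A %*% Te$A
  b <- as.numeric(Tt$A %*% Te$b + Tt$b)
  ctr <- (grid_shape - 1) / 2
  resid <- as.numeric(R %*% ctr + b - ctr) # translation at the centroid
  ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  list(translation_vox = sqrt(sum(resid^2)), rotation_deg = ang)
}
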
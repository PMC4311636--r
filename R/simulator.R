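# Synthetic scanner-session generator. Produces a complete, self-contained
# session on disk -- study configuration, ROI masks, ground-truth manifest
# and a stream of single-volume NIfTI files with known activation,
# inter-ROI correlation, class structure and motion -- so every engine path
# is testable without scanner data.

#' Simulator configuration
#'
#' Defines a synthetic block-design acquisition. Defaults describe a small
#' but realistic session: a 32 x 32 x 16 grid of 3 mm isotropic voxels,
#' baseline intensity 1000, i.i.d. Gaussian voxel noise of 1% of baseline,
#' and two spherical ROIs. The per-voxel signal is
#' `base(x) * (1 + psc_r a_r(t) + drift (t-1)) + latent + noise`, where
#' `base` is a static smooth texture around the baseline intensity, `a_r(t)`
#' the condition boxcar of ROI `r` (optionally HRF-convolved) and the latent
#' term couples the two ROI means to a target correlation.
#'
#' @param grid_shape Grid dimensions.
#' @param voxel_dims_mm Voxel sizes, mm.
#' @param n_volumes Number of volumes.
#' @param tr_seconds Repetition time, s.
#' @param design List of blocks `list(condition=, start=, end=)`; default
#'   alternating BASELINE/TASK blocks of 15 volumes.
#' @param roi_specs List of `list(name=, center=, radius=)` spheres (voxel
#'   units, 1-based centers).
#' @param baseline_intensity Mean tissue intensity.
#' @param psc Named list: for each ROI name, a named numeric vector of
#'   fractional signal change per condition (e.g. `list(roi1 = c(TASK =
#'   0.02))`).
#' @param noise_sd Voxel noise standard deviation, as a fraction of the
#'   baseline intensity.
#' @param drift_slope Linear drift per volume, fractional.
#' @param latent_rho Target correlation between the two ROI mean series (0
#'   disables the latent term).
#' @param latent_amp Amplitude (fraction of baseline) of the shared latent
#'   fluctuation.
#' @param texture_amp Amplitude (fraction of baseline) of the static smooth
#'   spatial texture; gives volumes the contrast needed for registration.
#' @param texture_fwhm_mm Smoothness of the texture.
#' @param motion_schedule Optional list of per-volume rigid parameter sets
#'   applied to the volumes.
#' @param hrf Convolve activation boxcars with the canonical HRF?
#' @param motion_correction Should the engine run motion correction on this
#'   session (written into the study configuration)?
#' @param smoothing_fwhm_mm Engine-side smoothing written into the study
#'   configuration.
#' @param sliding_window_L,feature_fraction_p,poll_timeout_s Further study
#'   configuration fields.
#' @param seed RNG seed; sessions are reproducible given the seed.
#' @return A `simConfig` object.
#' @export
simConfig <- function(grid_shape = c(32, 32, 16), voxel_dims_mm = c(3, 3, 3),
                      n_volumes = 60, tr_seconds = 2, design = NULL,
                      roi_specs = list(
                        list(name = "roi1", center = c(10, 16, 8), radius = 3),
                        list(name = "roi2", center = c(23, 16, 8), radius = 3)),
                      baseline_intensity = 1000,
                      psc = list(roi1 = c(TASK = 0.02)),
                      noise_sd = 0.01, drift_slope = 0,
                      latent_rho = 0, latent_amp = 0.01,
                      texture_amp = 0.1, texture_fwhm_mm = 9,
                      motion_schedule = NULL, hrf = FALSE,
                      motion_correction = FALSE, smoothing_fwhm_mm = 0,
                      sliding_window_L = NULL, feature_fraction_p = 1,
                      poll_timeout_s = 30, seed = 1) {
  if (is.null(design)) {
    design <- list()
    start <- 1L
    cond <- c("BASELINE", "TASK")
    k <- 0L
    while (start <= n_volumes) {
      end <- min(start + 14L, n_volumes)
      design[[length(design) + 1L]] <- list(condition = cond[k %% 2L + 1L],
                                            start = start, end = end)
      start <- end + 1L
      k <- k + 1L
    }
  }
  if (is.null(sliding_window_L)) sliding_window_L <- min(30L, n_volumes)
  cfg <- structure(as.list(environment()), class = "simConfig")
  for (rs in cfg$roi_specs) {
    # the sphere's voxel set is in-grid by construction; the center must be
    stopifnot(all(rs$center >= 1), all(rs$center <= grid_shape))
  }
  stopifnot(all(unlist(cfg$psc) >= 0), latent_rho >= 0, latent_rho < 1)
  cfg
}

sphereMask <- function(grid_shape, center, radius) {
  g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  array(d2 <= radius^2, grid_shape)
}

# Condition activation profile per ROI: sum of the ROI's psc amplitudes over
# its active conditions' boxcars, optionally HRF-convolved (unit peak).
activationProfiles <- function(cfg) {
  n <- cfg$n_volumes
  conds <- unique(vapply(cfg$design, `[[`, "", "condition"))
  box <- sapply(conds, function(cn) {
    b <- numeric(n)
    for (blk in cfg$design) if (blk$condition == cn) b[blk$start:blk$end] <- 1
    b
  })
  if (cfg$hrf) {
    h <- hrfDoubleGamma((seq_len(n) - 1) * cfg$tr_seconds)
    box <- apply(box, 2, function(b)
      as.numeric(stats::convolve(b, rev(h), type = "open"))[seq_len(n)])
  }
  prof <- matrix(0, n, length(cfg$roi_specs))
  colnames(prof) <- vapply(cfg$roi_specs, `[[`, "", "name")
  for (rn in names(cfg$psc)) {
    amp <- cfg$psc[[rn]]
    for (cn in names(amp)) {
      if (!cn %in% conds) stop("psc names unknown condition: ", cn)
      prof[, rn] <- prof[, rn] + amp[[cn]] * box[, cn]
    }
  }
  prof
}

#' Generate a synthetic scanner session
#'
#' Writes, under `out_dir`: `study_params.txt`, ROI mask NIfTIs
#' (`masks/`), the volume files (`staging/`, moved into the watched
#' `input/` directory by [streamVolumes()]), an (initially empty) engine
#' workspace, and a tab-separated ground-truth manifest. Deterministic for a
#' given `cfg$seed`.
#'
#' @param cfg A [simConfig()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a `groundTruth` list: per-volume condition labels, the
#'   true per-ROI activation profile, the target inter-ROI correlation, the
#'   motion schedule, the active-voxel masks, and the paths written.
#' @export
generateSession <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(cfg$seed)
  dirs <- list(staging = file.path(out_dir, "staging"),
               input = file.path(out_dir, "input"),
               masks = file.path(out_dir, "masks"),
               workspace = file.path(out_dir, "workspace"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)

  gs <- cfg$grid_shape
  masks <- lapply(cfg$roi_specs, function(rs) sphereMask(gs, rs$center, rs$radius))
  names(masks) <- vapply(cfg$roi_specs, `[[`, "", "name")
  overlap <- Reduce(`+`, masks)
  if (any(overlap > 1)) {
    activeIn <- names(cfg$psc)
    if (sum(vapply(names(masks), function(nm) nm %in% activeIn, TRUE)) > 1) {
      stop("overlapping ROIs with conflicting activation")
    }
  }
  maskPaths <- character(length(masks))
  for (i in seq_along(masks)) {
    maskPaths[i] <- file.path(dirs$masks, paste0(names(masks)[i], ".nii"))
    writeVolume(masks[[i]] * 1.0, maskPaths[i], cfg$voxel_dims_mm)
  }

  base <- array(cfg$baseline_intensity, gs)
  if (cfg$texture_amp > 0) {
    tex <- smoothGaussian(array(stats::rnorm(prod(gs)), gs),
                          cfg$texture_fwhm_mm, cfg$voxel_dims_mm)
    tex <- tex / stats::sd(tex)
    base <- base * (1 + cfg$texture_amp * tex)
  }

  prof <- activationProfiles(cfg)
  n <- cfg$n_volumes
  latent <- NULL
  if (cfg$latent_rho > 0 && length(masks) >= 2) {
    z <- stats::rnorm(n)
    eps <- matrix(stats::rnorm(2 * n), n, 2)
    latent <- cfg$latent_amp *
      (sqrt(cfg$latent_rho) * cbind(z, z) + sqrt(1 - cfg$latent_rho) * eps)
  }

  for (t in seq_len(n)) {
    mult <- array(1 + cfg$drift_slope * (t - 1), gs)
    for (r in seq_along(masks)) {
      mult[masks[[r]]] <- mult[masks[[r]]] + prof[t, r]
    }
    vol <- base * mult
    if (!is.null(latent)) {
      for (r in 1:2) {
        vol[masks[[r]]] <- vol[masks[[r]]] + cfg$baseline_intensity * latent[t, r]
      }
    }
    if (cfg$noise_sd > 0) {
      vol <- vol + cfg$baseline_intensity * cfg$noise_sd * stats::rnorm(prod(gs))
    }
    if (!is.null(cfg$motion_schedule)) {
      vol <- applyRigid(vol, cfg$motion_schedule[[t]], cfg$voxel_dims_mm)
    }
    fname <- sprintf("vol%05d.nii", t)
    writeVolume(vol, file.path(dirs$staging, fname), cfg$voxel_dims_mm)
  }

  paramsText <- c(
    paste0("input_dir=", dirs$input),
    paste0("workspace_dir=", dirs$workspace),
    "volume_prefix=vol", "index_width=5",
    paste0("n_volumes=", n),
    paste0("tr_seconds=", cfg$tr_seconds),
    vapply(cfg$design, function(b) sprintf("design=%s:%d-%d", b$condition, b$start, b$end), ""),
    "baseline_condition=BASELINE",
    paste0("roi_mask=", maskPaths),
    paste0("sliding_window_L=", cfg$sliding_window_L),
    paste0("feature_fraction_p=", cfg$feature_fraction_p),
    paste0("smoothing_fwhm_mm=", cfg$smoothing_fwhm_mm),
    paste0("poll_timeout_s=", cfg$poll_timeout_s),
    paste0("motion_correction=", if (cfg$motion_correction) "on" else "off"),
    paste0("hrf=", if (cfg$hrf) "on" else "off")
  )
  paramsPath <- file.path(out_dir, "study_params.txt")
  writeLines(paramsText, paramsPath)

  labels <- vapply(seq_len(n), function(i) {
    for (b in cfg$design) if (i >= b$start && i <= b$end) return(b$condition)
    NA_character_
  }, "")
  manifest <- data.frame(index = seq_len(n), condition = labels)
  for (r in seq_along(masks)) manifest[[paste0("psc_", names(masks)[r])]] <- prof[, r]
  utils::write.table(manifest, file.path(out_dir, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  invisible(structure(list(
    labels = labels, activation = prof, latent_rho = cfg$latent_rho,
    motion_schedule = cfg$motion_schedule, masks = masks,
    config = cfg, params_path = paramsPath, dirs = dirs,
    mask_paths = maskPaths
  ), class = "groundTruth"))
}

#' Stream generated volumes into the watched input directory
#'
#' Copies the staged volume files into the session's input directory one by
#' one, `interval_s` apart, each via write-to-temporary-then-rename so a
#' partially written file is never visible to the engine's directory
#' watcher.
#'
#' @param session_dir Directory written by [generateSession()].
#' @param interval_s Seconds between consecutive volumes (0 = all at once).
#' @return Invisibly, the number of volumes streamed.
#' @export
streamVolumes <- function(session_dir, interval_s = 0) {
  staging <- file.path(session_dir, "staging")
  input <- file.path(session_dir, "input")
  files <- sort(list.files(staging, pattern = "\\.nii$"))
  for (i in seq_along(files)) {
    if (i > 1 && interval_s > 0) Sys.sleep(interval_s)
    src <- file.path(staging, files[i])
    tmp <- file.path(input, paste0(".tmp_", files[i]))
    file.copy(src, tmp, overwrite = TRUE)
    file.rename(tmp, file.path(input, files[i]))
  }
  invisible(length(files))
}

#' Labeled volumes for decoder training
#'
#' Generates `n_per_class` volumes per class for a two-class brain decoding
#' problem: class `k` activates the `k`-th ROI of `cfg$roi_specs` at
#' amplitude `psc_amplitude` on top of the shared textured baseline and
#' voxel noise. The per-active-voxel SNR is `psc_amplitude / noise_sd`; the
#' classes are Bayes-separable for the default SNR of 3.
#'
#' @param cfg A [simConfig()] with at least two (disjoint) ROI specs.
#' @param n_per_class Training volumes per class.
#' @param psc_amplitude Fractional activation of the class ROI.
#' @param classes Class names (two).
#' @return List with `X` (volumes as rows, concatenated voxels), `volumes`
#'   (list of 3-D arrays), `labels` (factor), `masks`, and the grid info.
#' @export
makeLabeledPatterns <- function(cfg, n_per_class = 50, psc_amplitude = 0.03,
                                classes = c("classA", "classB")) {
  stopifnot(inherits(cfg, "simConfig"), length(cfg$roi_specs) >= 2,
            length(classes) == 2)
  set.seed(cfg$seed)
  gs <- cfg$grid_shape
  masks <- lapply(cfg$roi_specs[1:2], function(rs) sphereMask(gs, rs$center, rs$radius))
  if (any(masks[[1]] & masks[[2]])) stop("class ROIs must be disjoint")
  base <- array(cfg$baseline_intensity, gs)
  if (cfg$texture_amp > 0) {
    tex <- smoothGaussian(array(stats::rnorm(prod(gs)), gs),
                          cfg$texture_fwhm_mm, cfg$voxel_dims_mm)
    base <- base * (1 + cfg$texture_amp * tex / stats::sd(tex))
  }
  n <- 2L * n_per_class
  labels <- factor(rep(classes, each = n_per_class), levels = classes)
  vols <- vector("list", n)
  X <- matrix(0, n, prod(gs))
  for (i in seq_len(n)) {
    k <- as.integer(labels[i])
    mult <- array(1, gs)
    mult[masks[[k]]] <- 1 + psc_amplitude
    vol <- base * mult
    if (cfg$noise_sd > 0) {
      vol <- vol + cfg$baseline_intensity * cfg$noise_sd * stats::rnorm(prod(gs))
    }
    vols[[i]] <- vol
    X[i, ] <- as.numeric(vol)
  }
  list(X = X, volumes = vols, labels = labels, masks = masks,
       grid_shape = gs, voxel_dims_mm = cfg$voxel_dims_mm)
}
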
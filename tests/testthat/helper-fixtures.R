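# Shared fixtures, built in code at test time.

# A smooth, textured volume suitable for registration experiments.
smoothTestVolume <- function(grid_shape = c(32, 32, 16), voxel_dims = c(3, 3, 3),
                             fwhm_mm = 9, seed = 11) {
  set.seed(seed)
  v <- smoothGaussian(array(rnorm(prod(grid_shape)), grid_shape),
                      fwhm_mm, voxel_dims)
  1000 + 100 * v / sd(v)
}

# Random valid study parameters (for round-trip property tests).
randomStudyParams <- function() {
  n <- sample(4:40, 1)
  nBlocks <- sample(1:4, 1)
  cuts <- sort(sample(seq_len(n - 1), min(nBlocks - 1, n - 1)))
  bounds <- unique(c(0, cuts, n))
  conds <- c("BASELINE", "TASK", "REST", "MOTOR")
  design <- lapply(seq_len(length(bounds) - 1), function(i) {
    list(condition = sample(conds[seq_len(min(i + 1, 4))], 1),
         start = bounds[i] + 1L, end = bounds[i + 1L])
  })
  design[[1]]$condition <- "BASELINE"
  defaultStudyParams(
    input_dir = file.path(tempdir(), "in"), n_volumes = n, design = design,
    tr_seconds = round(runif(1, 0.5, 4), 3),
    sliding_window_L = sample(2:n, 1),
    feature_fraction_p = round(runif(1, 0.05, 1), 4),
    smoothing_fwhm_mm = round(runif(1, 0, 8), 3),
    poll_timeout_s = round(runif(1, 1, 30), 2)
  )
}

# A tiny configured in-memory session (no disk, no server) with masks set,
# for driving plug-in hooks directly.
makeHookSession <- function(params, masks, plugin, hooks = pluginHookNames(plugin)) {
  sid <- createSession(params)
  s <- getSession(sid)
  s$masks <- masks
  s$pluginBinding <- pluginBinding(plugin, hooks)
  nfengine:::callHook(s, "initialization")
  s
}

# Brute-force, array-level recomputation of the ROI feedback rule: for each
# volume, the baseline is the most recent baseline block whose end <= index;
# all ROI means are recomputed from the raw arrays. Returns NA where no
# baseline block has completed yet.
bruteForceRoiFeedback <- function(params, volumes, mask) {
  m <- if (inherits(mask, "roiMask")) mask$mask else mask
  n <- params$n_volumes
  means <- vapply(volumes, function(v) mean(as.array(v)[m]), 0)
  isBase <- vapply(seq_len(n), function(i)
    conditionAt(params, i) == params$baseline_condition, TRUE)
  vapply(seq_len(n), function(i) {
    ends <- Filter(function(b) b$condition == params$baseline_condition &&
                     b$end <= i, params$design)
    if (length(ends) == 0) return(NA_real_)
    blk <- ends[[length(ends)]]
    base <- mean(means[blk$start:blk$end])
    (means[i] - base) / base
  }, 0)
}

# Drive a plug-in's test hook over an in-memory volume list, as the pipeline
# would, returning the per-volume feedback values (NA when not ready).
runTestHook <- function(s, volumes) {
  vapply(seq_along(volumes), function(i) {
    res <- nfengine:::callHook(s, "test", i, volumes[[i]])
    if (isNotReady(res)) NA_real_ else res$feedback_value[1]
  }, 0)
}

# Textbook Pearson correlation, written out as the defining sums.
textbookPearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Raw wire access for protocol tests.
wireConnect <- function(h) nfengine:::connectEngine(h$host, h$port)
wireSend <- function(con, line, payload = NULL) nfengine:::sendCommand(con, line, payload)

# Background volume streamer (separate R process).
launchStreamer <- function(session_dir, interval_s) {
  rscript <- file.path(R.home("bin"), "Rscript")
  expr <- sprintf("nfengine::streamVolumes('%s', %g)", session_dir, interval_s)
  system2(rscript, c("--vanilla", "-e", shQuote(expr)),
          stdout = FALSE, stderr = FALSE, wait = FALSE)
}

engineAvailable <- function() TRUE
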
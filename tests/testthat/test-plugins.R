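tinyParams <- function(design, ...) {
  n <- max(vapply(design, `[[`, 0L, "end"))
  defaultStudyParams(input_dir = "/tmp/in", n_volumes = n, design = design, ...)
}

randomTinyRun <- function(seed) {
  set.seed(seed)
  nBlocks <- sample(2:5, 1)
  lens <- sample(2:5, nBlocks, replace = TRUE)
  conds <- ifelse(seq_len(nBlocks) %% 2 == 1, "BASELINE", "TASK")
  starts <- cumsum(c(1L, lens[-nBlocks]))
  design <- lapply(seq_len(nBlocks), function(i)
    list(condition = conds[i], start = starts[i],
         end = starts[i] + lens[i] - 1L))
  p <- tinyParams(design)
  gs <- c(6, 6, 3)
  mask <- roiMask(sphereMaskLocal(gs, c(3, 3, 2), 2))
  vols <- lapply(seq_len(p$n_volumes), function(i)
    array(1000 + rnorm(prod(gs), sd = 20), gs))
  list(params = p, mask = mask, vols = vols)
}

sphereMaskLocal <- function(gs, center, radius) {
  g <- expand.grid(x = seq_len(gs[1]), y = seq_len(gs[2]), z = seq_len(gs[3]))
  array((g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2 <= radius^2, gs)
}

test_that("the registry exposes exactly the four shipped plug-ins", {
  expect_setequal(pluginNames(),
                  c("libROI", "libMotor", "libConnectivity", "libBrainDecoding"))
})

test_that("bindings resolve declared hooks and reject misspelled ones", {
  hooks <- pluginHookNames("libROI")
  expect_identical(unname(hooks["train"]), "-")
  expect_identical(unname(hooks["test"]), "processROI")
  expect_identical(unname(hooks["initialization"]), "initializeROIProcessing")
  b <- pluginBinding("libROI")
  expect_s3_class(b, "pluginBinding")
  expect_null(b$resolved$train)
  badHooks <- hooks
  badHooks["test"] <- "procesROI"
  expect_error(pluginBinding("libROI", badHooks), "no function")
  expect_error(pluginBinding("libNothing"), "unknown plug-in")
})

test_that("percent signal change matches hand-evaluated cases", {
  expect_identical(roiPercentSignalChange(102, c(100, 100, 100, 100)), 0.02)
  expect_identical(roiPercentSignalChange(100, c(100, 100, 100, 100)), 0)
  expect_error(roiPercentSignalChange(5, c(0, 0)), "DIVISION_BY_ZERO_BASELINE")
})

test_that("ROI feedback equals a brute-force recomputation from raw arrays", {
  for (seed in 1:10) {
    run <- randomTinyRun(seed)
    s <- makeHookSession(run$params, list(run$mask), "libROI")
    got <- runTestHook(s, run$vols)
    oracle <- bruteForceRoiFeedback(run$params, run$vols, run$mask)
    endSession(s$id)
    expect_identical(is.na(got), is.na(oracle))
    ok <- !is.na(oracle)
    expect_lt(max(abs(got[ok] - oracle[ok])), 1e-10)
  }
})

test_that("feedback is not ready before the first baseline block completes", {
  p <- tinyParams(list(list(condition = "BASELINE", start = 1L, end = 3L),
                       list(condition = "TASK", start = 4L, end = 6L)))
  gs <- c(4, 4, 2)
  vols <- lapply(1:6, function(i) array(100 + i, gs))
  s <- makeHookSession(p, list(roiMask(array(TRUE, gs))), "libROI")
  on.exit(endSession(s$id))
  r1 <- nfengine:::callHook(s, "test", 1, vols[[1]])
  r2 <- nfengine:::callHook(s, "test", 2, vols[[2]])
  expect_true(isNotReady(r1))
  expect_true(isNotReady(r2))
  r3 <- nfengine:::callHook(s, "test", 3, vols[[3]]) # block completes here
  expect_false(isNotReady(r3))
  expect_equal(r3$feedback_value, (103 - 102) / 102, tolerance = 1e-12)
  r4 <- nfengine:::callHook(s, "test", 4, vols[[4]])
  expect_equal(r4$feedback_value, (104 - 102) / 102, tolerance = 1e-12)
  expect_identical(r4$class_label, 2L)
})

test_that("a zero-mean baseline raises a division error", {
  p <- tinyParams(list(list(condition = "BASELINE", start = 1L, end = 2L),
                       list(condition = "TASK", start = 3L, end = 4L)))
  gs <- c(3, 3, 2)
  s <- makeHookSession(p, list(roiMask(array(TRUE, gs))), "libROI")
  on.exit(endSession(s$id))
  zero <- array(0, gs)
  nfengine:::callHook(s, "test", 1, zero)
  expect_error(nfengine:::callHook(s, "test", 2, zero), "DIVISION_BY_ZERO_BASELINE")
})

test_that("motor feedback is the per-mask composition of single-ROI feedback", {
  set.seed(21)
  p <- tinyParams(list(list(condition = "BASELINE", start = 1L, end = 4L),
                       list(condition = "TASK", start = 5L, end = 10L)))
  gs <- c(8, 8, 4)
  left <- roiMask(sphereMaskLocal(gs, c(3, 4, 2), 1.6), name = "left")
  right <- roiMask(sphereMaskLocal(gs, c(6, 4, 2), 1.6), name = "right")
  vols <- lapply(1:10, function(i) {
    v <- array(1000 + rnorm(prod(gs), sd = 5), gs)
    if (i >= 5) v[left$mask] <- v[left$mask] + 30 # +3% in the left ROI only
    v
  })
  s <- makeHookSession(p, list(left, right), "libMotor")
  on.exit(endSession(s$id), add = TRUE)
  res <- lapply(seq_along(vols), function(i) nfengine:::callHook(s, "test", i, vols[[i]]))
  vals <- do.call(rbind, lapply(res[5:10], `[[`, "feedback_value"))
  expect_identical(ncol(vals), 2L)
  expect_true(all(vals[, 1] > vals[, 2])) # left ROI activated
  # compositional oracle: each column equals a single-mask libROI run
  sl <- makeHookSession(p, list(left), "libROI")
  sr <- makeHookSession(p, list(right), "libROI")
  on.exit({ endSession(sl$id); endSession(sr$id) }, add = TRUE)
  expect_equal(vals[, 1], runTestHook(sl, vols)[5:10], tolerance = 1e-12)
  expect_equal(vals[, 2], runTestHook(sr, vols)[5:10], tolerance = 1e-12)
  # symmetry: identical signal in both ROIs gives equal values
  s2 <- makeHookSession(p, list(left, left), "libMotor")
  on.exit(endSession(s2$id), add = TRUE)
  r2 <- lapply(seq_along(vols), function(i) nfengine:::callHook(s2, "test", i, vols[[i]]))
  expect_identical(r2[[6]]$feedback_value[1], r2[[6]]$feedback_value[2])
})

test_that("sliding-window correlation matches the textbook formula", {
  set.seed(31)
  for (rep in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    expect_lt(abs(slidingWindowCorrelation(x, y, 30) - textbookPearson(x, y)), 1e-12)
  }
  longX <- rnorm(45); longY <- rnorm(45)
  expect_lt(abs(slidingWindowCorrelation(longX, longY, 30) -
                  textbookPearson(tail(longX, 30), tail(longY, 30))), 1e-12)
  x <- rnorm(20)
  expect_equal(slidingWindowCorrelation(x, x, 20), 1)
  y <- -(x - mean(x)) + 5
  expect_equal(slidingWindowCorrelation(x, y, 20), -1)
  expect_error(slidingWindowCorrelation(rnorm(10), rnorm(10), 20), "window not full")
  expect_error(slidingWindowCorrelation(rep(1, 10), rnorm(10), 10), "ZERO_VARIANCE")
  # bounds and symmetry
  for (rep in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    r1 <- slidingWindowCorrelation(a, b, 15)
    expect_lte(abs(r1), 1)
    expect_identical(r1, slidingWindowCorrelation(b, a, 15))
  }
})

test_that("connectivity feedback waits for a full window then emits rho", {
  p <- tinyParams(list(list(condition = "BASELINE", start = 1L, end = 4L),
                       list(condition = "TASK", start = 5L, end = 12L)),
                  sliding_window_L = 6L)
  gs <- c(8, 8, 4)
  m1 <- roiMask(sphereMaskLocal(gs, c(3, 4, 2), 1.6))
  m2 <- roiMask(sphereMaskLocal(gs, c(6, 4, 2), 1.6))
  set.seed(41)
  vols <- lapply(1:12, function(i) array(1000 + rnorm(prod(gs), sd = 10), gs))
  s <- makeHookSession(p, list(m1, m2), "libConnectivity")
  on.exit(endSession(s$id))
  res <- lapply(seq_along(vols), function(i) nfengine:::callHook(s, "test", i, vols[[i]]))
  expect_true(all(vapply(res[1:5], isNotReady, TRUE)))
  expect_false(isNotReady(res[[6]]))
  # oracle: textbook Pearson over the last 6 ROI-mean pairs
  mean1 <- vapply(vols, function(v) roiMean(v, m1), 0)
  mean2 <- vapply(vols, function(v) roiMean(v, m2), 0)
  for (i in 6:12) {
    expect_lt(abs(res[[i]]$feedback_value -
                    textbookPearson(mean1[(i - 5):i], mean2[(i - 5):i])), 1e-12)
  }
})

test_that("buildROIs refines masks onto the truly active sub-region", {
  set.seed(51)
  gs <- c(16, 16, 8)
  p <- defaultStudyParams(
    input_dir = "/tmp/in", n_volumes = 40,
    design = list(list(condition = "BASELINE", start = 1L, end = 10L),
                  list(condition = "TASK", start = 11L, end = 20L),
                  list(condition = "BASELINE", start = 21L, end = 30L),
                  list(condition = "TASK", start = 31L, end = 40L)),
    hrf = FALSE, feature_fraction_p = 0.3)
  big1 <- sphereMaskLocal(gs, c(5, 8, 4), 3.5)
  act1 <- sphereMaskLocal(gs, c(5, 8, 4), 2.7) # active sub-sphere of mask 1
  big2 <- sphereMaskLocal(gs, c(12, 8, 4), 3.5)
  task <- vapply(1:40, function(i) conditionAt(p, i) == "TASK", TRUE)
  vols <- lapply(1:40, function(i) {
    v <- array(1000 + rnorm(prod(gs), sd = 10), gs)
    if (task[i]) v[act1] <- v[act1] + 20
    v
  })
  refined <- connBuildRois(vols, list(roiMask(big1), roiMask(big2)), 0.3, p)
  expect_identical(sum(refined[[1]]$mask), as.integer(ceiling(0.3 * sum(big1))))
  expect_identical(sum(refined[[2]]$mask), as.integer(ceiling(0.3 * sum(big2))))
  inActive <- sum(refined[[1]]$mask & act1) / sum(refined[[1]]$mask)
  expect_gte(inActive, 0.8)
  # p = 1 keeps the input masks unchanged
  full <- connBuildRois(vols, list(roiMask(big1), roiMask(big2)), 1, p)
  expect_identical(full[[1]]$mask, big1)
})

test_that("hook invocations follow Init (Volume PostProc Test)^n Final", {
  withr::defer(rm("testRecorder", envir = nfengine:::.pluginRegistry))
  registerPluginLibrary("testRecorder", functions = list(
    rInit = function(s) invisible(NULL),
    rVol = function(s, i, path) invisible(NULL),
    rPost = function(s, i, v) invisible(NULL),
    rTest = function(s, i, v) structure(
      list(class_label = conditionIndexAt(s$params, i), feedback_value = 0),
      class = "feedbackResult"),
    rFinal = function(s) invisible(NULL)
  ), default_hooks = c(test = "rTest", initialization = "rInit",
                       finalization = "rFinal", volume = "rVol",
                       postproc = "rPost"))
  dir <- withr::local_tempdir()
  cfg <- simConfig(n_volumes = 6,
                   design = list(list(condition = "BASELINE", start = 1L, end = 3L),
                                 list(condition = "TASK", start = 4L, end = 6L)),
                   grid_shape = c(8, 8, 4), noise_sd = 0, texture_amp = 0,
                   roi_specs = list(list(name = "roi1", center = c(4, 4, 2), radius = 1.5)),
                   psc = list(roi1 = c(TASK = 0.02)), seed = 3)
  gt <- generateSession(cfg, dir)
  streamVolumes(dir, 0)
  p <- parseStudyParams(readLines(gt$params_path))
  sid <- createSession(p)
  s <- getSession(sid)
  on.exit(endSession(sid), add = TRUE)
  s$pluginBinding <- pluginBinding("testRecorder")
  expect_identical(runPreproc(s), "DONE")
  expect_identical(runPipeline(s, compute_feedback = TRUE), "DONE")
  expect_identical(s$hookTrace,
                   c("Init", rep(c("Volume", "PostProc", "Test"), 6), "Final"))
  expect_match(paste(s$hookTrace, collapse = " "),
               "^Init( Volume PostProc( Test)?)* Final$")
  # PIPELINE (no feedback): Test hook absent from the trace
  expect_identical(runPreproc(s), "DONE")
  expect_identical(runPipeline(s, compute_feedback = FALSE), "DONE")
  expect_identical(s$hookTrace,
                   c("Init", rep(c("Volume", "PostProc"), 6), "Final"))
})

test_that("plug-in state is isolated between interleaved sessions", {
  p <- tinyParams(list(list(condition = "BASELINE", start = 1L, end = 2L),
                       list(condition = "TASK", start = 3L, end = 4L)))
  gs <- c(4, 4, 2)
  mk <- roiMask(array(TRUE, gs))
  sA <- makeHookSession(p, list(mk), "libROI")
  sB <- makeHookSession(p, list(mk), "libROI")
  on.exit({ endSession(sA$id); endSession(sB$id) })
  volsA <- lapply(c(100, 100, 110, 120), function(v) array(v, gs))
  volsB <- lapply(c(200, 200, 210, 220), function(v) array(v, gs))
  # interleave the two sessions volume by volume
  for (i in 1:4) {
    nfengine:::callHook(sA, "test", i, volsA[[i]])
    nfengine:::callHook(sB, "test", i, volsB[[i]])
  }
  expect_equal(sA$pluginState$baselineMeans, 100)
  expect_equal(sB$pluginState$baselineMeans, 200)
  rA <- nfengine:::callHook(sA, "test", 4, volsA[[4]])
  rB <- nfengine:::callHook(sB, "test", 4, volsB[[4]])
  expect_equal(rA$feedback_value, 0.2)
  expect_equal(rB$feedback_value, 0.1)
})

test_that("the decoding plug-in trains on a session run and projects volumes", {
  set.seed(61)
  gs <- c(10, 10, 5)
  p <- defaultStudyParams(
    input_dir = "/tmp/in", n_volumes = 12,
    design = list(list(condition = "BASELINE", start = 1L, end = 4L),
                  list(condition = "LEFT", start = 5L, end = 8L),
                  list(condition = "RIGHT", start = 9L, end = 12L)))
  mask <- roiMask(array(TRUE, gs))
  mkVol <- function(cond) {
    v <- array(1000 + rnorm(prod(gs), sd = 5), gs)
    if (cond == "LEFT") v[2:4, 2:4, 2] <- v[2:4, 2:4, 2] + 50
    if (cond == "RIGHT") v[7:9, 7:9, 3] <- v[7:9, 7:9, 3] + 50
    v
  }
  s <- makeHookSession(p, list(mask), "libBrainDecoding")
  on.exit(endSession(s$id))
  expect_true(isNotReady(nfengine:::callHook(s, "test", 1, mkVol("BASELINE"))))
  s$processed <- lapply(1:12, function(i) mkVol(conditionAt(p, i)))
  nfengine:::callHook(s, "train")
  expect_s3_class(s$pluginState$model, "trainedSVM")
  resL <- nfengine:::callHook(s, "test", 5, s$processed[[5]])
  resR <- nfengine:::callHook(s, "test", 9, s$processed[[9]])
  expect_gt(resL$feedback_value, 0)
  expect_lt(resR$feedback_value, 0)
  expect_identical(resL$class_label, 2L) # LEFT is condition 2 in the design
  expect_identical(resR$class_label, 3L)
})
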
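test_that("a null session produces identical constant volumes", {
  dir <- withr::local_tempdir()
  cfg <- simConfig(n_volumes = 4, grid_shape = c(8, 8, 4),
                   design = list(list(condition = "BASELINE", start = 1L, end = 2L),
                                 list(condition = "TASK", start = 3L, end = 4L)),
                   psc = list(roi1 = c(TASK = 0)), noise_sd = 0,
                   drift_slope = 0, texture_amp = 0,
                   roi_specs = list(list(name = "roi1", center = c(4, 4, 2), radius = 1.5)))
  generateSession(cfg, dir)
  vols <- lapply(1:4, function(i) {
    v <- readVolume(file.path(dir, "staging", sprintf("vol%05d.nii", i)))
    array(as.numeric(v), dim(v))
  })
  for (i in 2:4) expect_identical(vols[[i]], vols[[1]])
  expect_identical(length(unique(as.numeric(vols[[1]]))), 1L)
})

test_that("generation is byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- simConfig(n_volumes = 3, grid_shape = c(8, 8, 4), seed = 99,
                   design = list(list(condition = "BASELINE", start = 1L, end = 2L),
                                 list(condition = "TASK", start = 3L, end = 3L)),
                   roi_specs = list(list(name = "roi1", center = c(4, 4, 2), radius = 1.5)),
                   psc = list(roi1 = c(TASK = 0.02)))
  generateSession(cfg, d1)
  generateSession(cfg, d2)
  for (i in 1:3) {
    f <- sprintf("vol%05d.nii", i)
    expect_identical(unname(tools::md5sum(file.path(d1, "staging", f))),
                     unname(tools::md5sum(file.path(d2, "staging", f))))
  }
})

test_that("noise-free activation reproduces the requested PSC exactly", {
  dir <- withr::local_tempdir()
  cfg <- simConfig(n_volumes = 10, grid_shape = c(12, 12, 6),
                   design = list(list(condition = "BASELINE", start = 1L, end = 5L),
                                 list(condition = "TASK", start = 6L, end = 10L)),
                   roi_specs = list(list(name = "roi1", center = c(6, 6, 3), radius = 2)),
                   psc = list(roi1 = c(TASK = 0.02)), noise_sd = 0,
                   texture_amp = 0.1, hrf = FALSE)
  gt <- generateSession(cfg, dir)
  vols <- lapply(1:10, function(i)
    as.array(readVolume(file.path(dir, "staging", sprintf("vol%05d.nii", i)))))
  m <- gt$masks$roi1
  means <- vapply(vols, function(v) mean(v[m]), 0)
  psc <- mean(means[6:10]) / mean(means[1:5]) - 1
  expect_lt(abs(psc - 0.02), 1e-10)
})

test_that("ROI-mean correlation converges to the target latent_rho", {
  dir <- withr::local_tempdir()
  cfg <- simConfig(n_volumes = 500, grid_shape = c(12, 12, 6), tr_seconds = 2,
                   design = list(list(condition = "BASELINE", start = 1L, end = 500L)),
                   roi_specs = list(list(name = "roi1", center = c(4, 6, 3), radius = 2),
                                    list(name = "roi2", center = c(9, 6, 3), radius = 2)),
                   psc = list(), noise_sd = 0.01, latent_rho = 0.6,
                   texture_amp = 0, seed = 12)
  gt <- generateSession(cfg, dir)
  vols <- lapply(1:500, function(i)
    as.array(readVolume(file.path(dir, "staging", sprintf("vol%05d.nii", i)))))
  m1 <- vapply(vols, function(v) mean(v[gt$masks$roi1]), 0)
  m2 <- vapply(vols, function(v) mean(v[gt$masks$roi2]), 0)
  expect_lt(abs(cor(m1, m2) - 0.6), 0.1)
})

test_that("plateau PSC converges to the amplitude under noise", {
  dir <- withr::local_tempdir()
  cfg <- simConfig(n_volumes = 30, grid_shape = c(12, 12, 6),
                   design = list(list(condition = "BASELINE", start = 1L, end = 15L),
                                 list(condition = "TASK", start = 16L, end = 30L)),
                   roi_specs = list(list(name = "roi1", center = c(6, 6, 3), radius = 2)),
                   psc = list(roi1 = c(TASK = 0.02)), noise_sd = 0.01,
                   hrf = FALSE, seed = 13)
  gt <- generateSession(cfg, dir)
  vols <- lapply(1:30, function(i)
    as.array(readVolume(file.path(dir, "staging", sprintf("vol%05d.nii", i)))))
  means <- vapply(vols, function(v) mean(v[gt$masks$roi1]), 0)
  est <- mean(means[16:30]) / mean(means[1:15]) - 1
  expect_lt(abs(est - 0.02), 0.005)
})

test_that("streaming paces arrivals and never exposes partial files", {
  dir <- withr::local_tempdir()
  cfg <- simConfig(n_volumes = 10, grid_shape = c(8, 8, 4),
                   design = list(list(condition = "BASELINE", start = 1L, end = 10L)),
                   roi_specs = list(list(name = "roi1", center = c(4, 4, 2), radius = 1.5)),
                   psc = list(), seed = 14)
  generateSession(cfg, dir)
  sizes <- file.info(list.files(file.path(dir, "staging"), full.names = TRUE))$size
  t0 <- Sys.time()
  streamVolumes(dir, 0.2)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_gte(elapsed, 1.8)
  arrived <- sort(list.files(file.path(dir, "input"), full.names = TRUE))
  expect_length(arrived, 10)
  expect_identical(unname(file.info(arrived)$size), sizes)
  expect_false(any(grepl("tmp", basename(arrived))))
})

test_that("labeled pattern sets are balanced and separable", {
  cfg <- simConfig(grid_shape = c(16, 16, 8), noise_sd = 0,
                   roi_specs = list(list(name = "a", center = c(5, 8, 4), radius = 2),
                                    list(name = "b", center = c(12, 8, 4), radius = 2)),
                   seed = 15)
  pat <- makeLabeledPatterns(cfg, n_per_class = 5, psc_amplitude = 0.03)
  expect_identical(as.integer(table(pat$labels)), c(5L, 5L))
  # noise-free patterns are trivially separable
  m <- svmTrain(pat$X, pat$labels)
  acc <- mean(vapply(seq_len(nrow(pat$X)), function(i)
    svmTest(pat$X[i, ], m)$class_name, "") == as.character(pat$labels))
  expect_identical(acc, 1)
  # at per-voxel SNR 3 (psc 0.03 / noise 0.01), training accuracy stays 100%
  cfgN <- simConfig(grid_shape = c(16, 16, 8), noise_sd = 0.01,
                    roi_specs = cfg$roi_specs, seed = 16)
  patN <- makeLabeledPatterns(cfgN, n_per_class = 50, psc_amplitude = 0.03)
  mN <- svmTrain(patN$X, patN$labels)
  accN <- mean(vapply(seq_len(nrow(patN$X)), function(i)
    svmTest(patN$X[i, ], mN)$class_name, "") == as.character(patN$labels))
  expect_identical(accN, 1)
})

test_that("overlapping ROIs with conflicting activation are rejected", {
  cfg <- simConfig(grid_shape = c(12, 12, 6),
                   roi_specs = list(list(name = "a", center = c(6, 6, 3), radius = 2),
                                    list(name = "b", center = c(7, 6, 3), radius = 2)),
                   psc = list(a = c(TASK = 0.02), b = c(TASK = 0.01)),
                   design = list(list(condition = "BASELINE", start = 1L, end = 2L),
                                 list(condition = "TASK", start = 3L, end = 4L)),
                   n_volumes = 4)
  expect_error(generateSession(cfg, withr::local_tempdir()), "conflicting")
})
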
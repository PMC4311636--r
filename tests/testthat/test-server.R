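# Server tests talk raw wire protocol to a background engine process.

serverSession <- function(dir, n = 6, stream = TRUE, ...) {
  cfg <- simConfig(
    n_volumes = n, grid_shape = c(8, 8, 4), noise_sd = 0.01,
    design = list(list(condition = "BASELINE", start = 1L, end = n %/% 2),
                  list(condition = "TASK", start = n %/% 2 + 1L, end = n)),
    roi_specs = list(list(name = "roi1", center = c(4, 4, 2), radius = 1.5)),
    psc = list(roi1 = c(TASK = 0.02)), seed = 6, ...)
  gt <- generateSession(cfg, dir)
  if (stream) streamVolumes(dir, 0)
  gt
}

setupWire <- function(con, configPath, plugin = "libROI") {
  cfg <- paste(readLines(configPath, warn = FALSE), collapse = "\n")
  sid <- wireSend(con, "NEWSESSION")$payload[1]
  r <- wireSend(con, sprintf("READCONFIG %d", nchar(cfg, type = "bytes")), cfg)
  stopifnot(r$ok)
  r <- wireSend(con, paste(c("PLUGIN", plugin, pluginHookNames(plugin)), collapse = " "))
  stopifnot(r$ok)
  sid
}

test_that("sessions, configs and plug-ins are negotiated over the wire", {
  dir <- withr::local_tempdir()
  gt <- serverSession(dir)
  h <- launchEngine()
  withr::defer(stopEngine(h))
  con <- wireConnect(h)
  withr::defer(close(con))

  sid1 <- wireSend(con, "NEWSESSION")$payload[1]
  sid2 <- wireSend(con, "NEWSESSION")$payload[1]
  expect_false(identical(sid1, sid2))

  # status queries on a pristine session: all IDLE
  expect_identical(wireSend(con, paste("SESSION/PREPROC", sid2))$payload[1], "IDLE")
  expect_identical(wireSend(con, paste("SESSION/FEEDBACK", sid2))$payload[1], "IDLE")
  expect_identical(wireSend(con, paste("SESSION/TEST", sid2, "1"))$status, "NOT_READY")

  # commands demand their prerequisites
  expect_match(wireSend(con, "PREPROC")$status, "ERROR NO_CONFIG")
  cfg <- paste(readLines(gt$params_path, warn = FALSE), collapse = "\n")
  expect_true(wireSend(con, sprintf("READCONFIG %d", nchar(cfg, type = "bytes")), cfg)$ok)
  expect_match(wireSend(con, "PREPROC")$status, "ERROR NO_PLUGIN")
  expect_match(wireSend(con, "PLUGIN libROI x y z - - -")$status, "ERROR BAD_PLUGIN")
  expect_match(wireSend(con, "PLUGIN libNothing")$status, "ERROR BAD_PLUGIN")
  expect_match(wireSend(con, "FROBNICATE")$status, "ERROR UNKNOWN_COMMAND")
  expect_match(wireSend(con, "READCONFIG")$status, "ERROR BAD_ARGS")
})

test_that("the blocking protocol flow completes a feedback run", {
  dir <- withr::local_tempdir()
  gt <- serverSession(dir)
  h <- launchEngine()
  withr::defer(stopEngine(h))
  con <- wireConnect(h)
  withr::defer(close(con))
  sid <- setupWire(con, gt$params_path)
  expect_identical(wireSend(con, "PREPROC")$payload[1], "DONE")
  # blocking PREPROC returns only once the status is already DONE
  expect_identical(wireSend(con, paste("SESSION/PREPROC", sid))$payload[1], "DONE")
  expect_identical(wireSend(con, "FEEDBACK")$payload[1], "DONE")
  fb <- wireSend(con, "TEST 5")
  expect_true(fb$ok)
  toks <- strsplit(fb$payload[1], " ")[[1]]
  expect_identical(toks[1], "2")
  expect_lt(abs(as.numeric(toks[2]) - 0.02), 0.01)
  mo <- wireSend(con, "GRAPHPARS 5")
  expect_true(mo$ok)
  expect_length(strsplit(mo$payload[1], " ")[[1]], 7)
  # repeated queries are idempotent: identical replies, no state change
  expect_identical(wireSend(con, paste("SESSION/TEST", sid, "5"))$payload,
                   wireSend(con, paste("SESSION/TEST", sid, "5"))$payload)
  expect_match(wireSend(con, paste("SESSION/TEST", sid, "99"))$status, "BAD_INDEX")
  expect_true(wireSend(con, "ENDSESSION")$ok)
  expect_match(wireSend(con, paste("SESSION/PREPROC", sid))$status,
               "ERROR UNKNOWN_SESSION")
})

test_that("non-blocking commands return immediately and report progress", {
  dir <- withr::local_tempdir()
  gt <- serverSession(dir, n = 4)
  # slow the handler down artificially via the study configuration
  cfgLines <- c(readLines(gt$params_path), "debug_delay_s=2")
  cfgPath <- file.path(dir, "slow_params.txt")
  writeLines(cfgLines, cfgPath)
  h <- launchEngine()
  withr::defer(stopEngine(h))
  con <- wireConnect(h)
  withr::defer(close(con))
  sid <- setupWire(con, cfgPath)

  t0 <- Sys.time()
  r <- wireSend(con, "NBPREPROC")
  expect_true(r$ok)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 0.1)
  expect_identical(wireSend(con, paste("SESSION/PREPROC", sid))$payload[1], "RUNNING")

  # a second connection bound to the same session observes the same run
  con2 <- wireConnect(h)
  withr::defer(close(con2))
  expect_identical(wireSend(con2, paste("SESSION/PREPROC", sid))$payload[1], "RUNNING")
  # and every query during the delayed handler returns fast
  lat <- replicate(5, {
    t1 <- Sys.time()
    wireSend(con2, paste("SESSION/PREPROC", sid))
    as.numeric(Sys.time() - t1, units = "secs")
  })
  expect_true(all(lat < 0.2))

  deadline <- Sys.time() + 30
  status <- "RUNNING"
  while (Sys.time() < deadline) {
    status <- wireSend(con, paste("SESSION/PREPROC", sid))$payload[1]
    if (status %in% c("DONE", "FAILED")) break
    Sys.sleep(0.1)
  }
  expect_identical(status, "DONE")

  # polled status sequence over the feedback run is monotone
  r <- wireSend(con, "NBFEEDBACK")
  expect_true(r$ok)
  seen <- character()
  while (Sys.time() < deadline) {
    stx <- wireSend(con, paste("SESSION/FEEDBACK", sid))$payload[1]
    seen <- c(seen, stx)
    if (stx %in% c("DONE", "FAILED")) break
    Sys.sleep(0.05)
  }
  expect_identical(tail(seen, 1), "DONE")
  runs <- rle(seen)$values
  expect_true(all(runs %in% c("RUNNING", "DONE")))
  expect_identical(runs, unique(runs)) # RUNNING* DONE, no regression
})

test_that("a session query after ENDSESSION from another connection errors", {
  h <- launchEngine()
  withr::defer(stopEngine(h))
  con <- wireConnect(h)
  con2 <- wireConnect(h)
  withr::defer({ close(con); close(con2) })
  sid <- wireSend(con, "NEWSESSION")$payload[1]
  expect_identical(wireSend(con2, paste("SESSION/PREPROC", sid))$payload[1], "IDLE")
  expect_true(wireSend(con, paste("ENDSESSION", sid))$ok)
  expect_match(wireSend(con2, paste("SESSION/PREPROC", sid))$status,
               "ERROR UNKNOWN_SESSION")
})

test_that("a busy port fails server startup", {
  h <- launchEngine()
  withr::defer(stopEngine(h))
  expect_error(engineServe(h$port, max_runtime_s = 1))
})
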
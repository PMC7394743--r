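mkSeries <- function(values, tr = 2) roiTimeSeries(values, trSeconds = tr)

test_that("initial-volume deletion trims series, mask and motion together", {
  ts <- mkSeries(matrix(seq_len(3 * 238), nrow = 3))
  out <- dropInitialVolumes(ts, 15)
  expect_equal(nVolumes(out), 223)
  expect_equal(seriesValues(out)[, 1], seriesValues(ts)[, 16])

  tiny <- mkSeries(matrix(rnorm(2 * 16), nrow = 2))
  expect_equal(nVolumes(dropInitialVolumes(tiny, 15)), 1)
  expect_error(dropInitialVolumes(mkSeries(matrix(rnorm(30), 2)), 15),
               "subject invalid")

  mot <- motionRecord(matrix(rnorm(238 * 6, sd = 0.01), 238, 6))
  both <- dropInitialVolumes(ts, 15, motion = mot)
  expect_equal(nrow(motionParams(both$motion)), 223)
  expect_equal(fdTrace(both$motion)[1], 0)
})

test_that("framewise displacement follows the backward-difference formula", {
  expect_equal(computeFD(matrix(0.3, 5, 6)), rep(0, 5))

  p <- matrix(0, 5, 6)
  p[3:5, 4] <- 0.1  # x-translation step at volume 3
  expect_equal(computeFD(p), c(0, 0, 0.1, 0, 0))

  q <- matrix(0, 4, 6)
  q[2:4, 1] <- 0.002  # rotation step: 50 mm * 0.002 rad = 0.1 mm
  expect_equal(computeFD(q), c(0, 0.1, 0, 0))

  # combined: sum of absolute differences across all six parameters
  set.seed(1)
  r <- matrix(rnorm(24, sd = 0.01), 4, 6)
  d <- abs(diff(r))
  expect_equal(computeFD(r),
               c(0, 50 * rowSums(d[, 1:3]) + rowSums(d[, 4:6])))
  expect_error(computeFD(matrix(0, 4, 5)), "6")
})

test_that("volume censoring applies the strict exceedance rule", {
  ts <- mkSeries(matrix(rnorm(10), 2, 5))
  out <- censorVolumes(ts, c(0, 0.1, 0.25, 0.3, 0.05))
  expect_equal(which(retainedMask(out)), c(1L, 2L, 5L))
  # values untouched
  expect_identical(seriesValues(out), seriesValues(ts))
  # exactly at threshold is retained
  out2 <- censorVolumes(ts, c(0, 0.2, 0.2, 0.19, 0.21))
  expect_equal(which(retainedMask(out2)), 1:4)
  out3 <- censorVolumes(ts, rep(0.1, 5))
  expect_true(all(retainedMask(out3)))
})

test_that("subject motion gate is strict and reports its source", {
  mk <- function(mrd) motionRecord(matrix(0, 10, 6),
                                   meanRelDisplacement = mrd)
  expect_false(subjectMotionGate(mk(0.21))$pass)
  expect_true(subjectMotionGate(mk(0.2))$pass)
  expect_true(subjectMotionGate(mk(0.05))$pass)
  expect_equal(subjectMotionGate(mk(0.05))$source, "mean_rel_displacement")

  miss <- subjectMotionGate(NULL)
  expect_false(miss$pass)
  expect_equal(miss$source, "missing_motion")

  # proxy: mean FD when the tool's metric is absent
  p <- matrix(0, 10, 6)
  p[seq(2, 10, 2), 4] <- 0.5  # alternating jumps -> high mean FD
  prox <- subjectMotionGate(motionRecord(p))
  expect_equal(prox$source, "mean_fd_proxy")
  expect_false(prox$pass)
})

test_that("36-parameter design has the required structure", {
  set.seed(2)
  tt <- 50
  mot <- motionRecord(matrix(rnorm(tt * 6, sd = 0.01), tt, 6))
  wm <- rnorm(tt); csf <- rnorm(tt); gl <- rnorm(tt)
  x <- build36pDesign(mot, wm, csf, gl)
  expect_equal(ncol(x), 36)
  expect_equal(nrow(x), tt)
  # derivative columns: backward differences, first entry 0
  expect_equal(unname(x[1, 10:18]), rep(0, 9))
  expect_equal(unname(x[, "d_wm"]), c(0, diff(wm)))
  # squares are elementwise squares of their base
  expect_equal(unname(x[, "sq_wm"]), wm^2)
  expect_equal(unname(x[, "sq_d_csf"]), c(0, diff(csf))^2)
  # constant base column -> all-zero derivative
  x2 <- build36pDesign(mot, rep(1, tt), csf, gl)
  expect_equal(unname(x2[, "d_wm"]), rep(0, tt))
  expect_error(build36pDesign(mot, wm[-1], csf, gl), "per volume")
  expect_warning(
    build36pDesign(motionRecord(matrix(0, tt, 6)), rep(0, tt),
                   rep(0, tt), rep(0, tt)),
    "rank-deficient")
})

test_that("nuisance regression residuals match the normal-equations oracle", {
  set.seed(3)
  tt <- 100
  mot <- motionRecord(matrix(rnorm(tt * 6, sd = 0.02), tt, 6))
  design <- build36pDesign(mot, rnorm(tt), rnorm(tt), rnorm(tt))
  ts <- mkSeries(matrix(rnorm(10 * tt), 10, tt))
  out <- nuisanceRegress(ts, design)

  # independent oracle: residual = y - X (X'X)^-1 X'y with intercept
  x <- cbind(1, design)
  hat <- x %*% solve(crossprod(x), t(x))
  oracle <- seriesValues(ts) - seriesValues(ts) %*% t(hat)
  expect_equal(seriesValues(out), oracle, tolerance = 1e-8)

  # residuals orthogonal to every design column (relative scale)
  ip <- seriesValues(out) %*% design
  scale <- sqrt(rowSums(seriesValues(out)^2) %o% colSums(design^2))
  expect_lt(max(abs(ip) / scale), 1e-8)

  # idempotence
  twice <- nuisanceRegress(out, design)
  expect_equal(seriesValues(twice), seriesValues(out), tolerance = 1e-8)
})

test_that("nuisance regression handles exact and orthogonal series", {
  set.seed(4)
  tt <- 60
  design <- matrix(rnorm(tt * 3), tt, 3)
  # region equal to a design column -> residual ~ 0
  ts <- mkSeries(rbind(design[, 2], rnorm(tt)))
  out <- nuisanceRegress(ts, design)
  expect_lt(max(abs(seriesValues(out)[1, ])), 1e-10)
  # orthogonal region unchanged up to mean removal
  y <- rnorm(tt)
  yOrth <- qr.resid(qr(cbind(1, design)), y)
  out2 <- nuisanceRegress(mkSeries(rbind(yOrth, yOrth)), design)
  expect_equal(seriesValues(out2)[1, ], yOrth, tolerance = 1e-8)
  # rank-deficient design warns but still projects
  expect_warning(nuisanceRegress(ts, cbind(design, design[, 1])),
                 "rank-deficient")
})

test_that("band-pass filter passes and stops the right frequencies", {
  tt <- 2000
  tsec <- (seq_len(tt) - 1) * 2
  inBand <- sin(2 * pi * 0.04 * tsec)
  stopBand <- sin(2 * pi * 0.2 * tsec)
  ts <- mkSeries(rbind(inBand, stopBand, rep(1, tt)))
  out <- seriesValues(bandpass(ts))
  core <- 200:1800  # ignore filter edge transients
  expect_gte(sd(out[1, core]) / sd(inBand[core]), 0.9)
  expect_lte(sd(out[2, core]) / sd(stopBand[core]), 0.1)
  # constant series -> DC removed
  expect_lt(max(abs(out[3, ])), 1e-8)
  expect_error(bandpass(ts, lowHz = 0.01, highHz = 0.3), "Nyquist")
})

test_that("duration gate uses the strict 240 s rule", {
  mk <- function(nKeep, tt = 250) {
    mask <- rep(FALSE, tt); mask[seq_len(nKeep)] <- TRUE
    roiTimeSeries(matrix(rnorm(2 * tt), 2, tt), trSeconds = 2,
                  retainedMask = mask)
  }
  expect_true(durationGate(mk(120))$pass)   # exactly 240 s passes
  expect_false(durationGate(mk(119))$pass)  # 238 s fails
  expect_true(durationGate(mk(223))$pass)
})

test_that("spike-only contamination is censored exactly", {
  cfg <- simulationConfig(nSubjects = 1, nRegions = 6, nModules = 2,
                          nVolumes = 238, motionSpikeProb = 0.1, seed = 31)
  mot <- genMotionTrace(cfg, seed = 77)
  base <- genBaseCorrelation(cfg)
  sub <- genSubjectTimeseries(base, 0, cfg, seed = 78)
  den <- denoiseSubject(sub$series, mot$motion, tissue = sub$tissue)
  expect_true(den$qc$pass)
  # censored volumes (post-trim indexing) equal the constructed spikes
  spikesAfterDrop <- mot$spikeVolumes[mot$spikeVolumes > 15] - 15L
  expect_equal(which(!retainedMask(den$series)), spikesAfterDrop)
  expect_equal(den$qc$nCensored, length(spikesAfterDrop))
})

test_that("denoising chain applies gates with distinct reasons", {
  cfg <- simulationConfig(nSubjects = 1, nRegions = 4, nModules = 2,
                          nVolumes = 238, motionSpikeProb = 0.9, seed = 41)
  mot <- genMotionTrace(cfg, seed = 91)
  sub <- genSubjectTimeseries(genBaseCorrelation(cfg), 0, cfg, seed = 92)
  den <- denoiseSubject(sub$series, mot$motion, tissue = sub$tissue)
  expect_false(den$qc$pass)
  expect_equal(den$qc$reason, "motion_gate")

  short <- roiTimeSeries(matrix(rnorm(4 * 10), 4, 10))
  den2 <- denoiseSubject(short, mot$motion)
  expect_false(den2$qc$pass)
  expect_equal(den2$qc$reason, "too_few_volumes")
})
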
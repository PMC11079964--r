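# Synthetic accumulation-to-bound generator.

test_that("noiseless component hits the bound exactly at the response sample", {
  cfg <- noiselessConfig(nTrials = 3)
  s <- simulateParticipant(cfg, "p", 7)
  ev <- events(s)
  w <- spatialWeights(channelPositions(s), cfg@topoCenter, cfg@topoWidth)
  w[channelLabels(s) %in% c("M1", "M2")] <- 0
  for (i in seq_len(nrow(ev))) {
    v <- sessionData(s)[, ev$response_sample[i]]
    expect_equal(v, w * 10, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("decision times follow the shifted-lognormal law (Monte-Carlo)", {
  cfg <- simConfig()
  mTheory <- cfg@dtShiftMs + exp(cfg@dtLognormMu + cfg@dtLognormSigma^2 / 2)
  vTheory <- (exp(cfg@dtLognormSigma^2) - 1) *
    exp(2 * cfg@dtLognormMu + cfg@dtLognormSigma^2)
  # 10,000 draws straight from the generator's law
  dt10k <- cppErp:::.withSeed(21, cppErp:::.drawDecisionTimes(
    10000, cfg@dtShiftMs, cfg@dtLognormMu, cfg@dtLognormSigma, cfg@onsetMs))
  expect_lt(abs(mean(dt10k) - mTheory), 3 * sqrt(vTheory / 10000))
  expect_lt(abs(stats::sd(dt10k) - sqrt(vTheory)) / sqrt(vTheory), 0.05)
  # and end-to-end through a simulated session (sample-quantized times)
  cfg2 <- noiselessConfig(nTrials = 1500, cueEvokedAmpUv = 0,
                          boundUv = c(selection_required = 0))
  s <- simulateParticipant(cfg2, "p", 21)
  dt <- events(s)$decision_time_ms
  expect_lt(abs(mean(dt) - mTheory), 3 * sqrt(vTheory / length(dt)))
})

test_that("default decision-time law matches the cohort mean of ~756 ms", {
  cfg <- simConfig()
  mTheory <- cfg@dtShiftMs + exp(cfg@dtLognormMu + cfg@dtLognormSigma^2 / 2)
  expect_equal(mTheory, 755.76, tolerance = 0.005)
})

test_that("simulation is reproducible and respects event invariants", {
  cfg <- tinyConfig()
  a <- simulateParticipant(cfg, "p", 5)
  b <- simulateParticipant(cfg, "p", 5)
  expect_identical(sessionData(a), sessionData(b))
  expect_identical(events(a), events(b))
  ev <- events(a)
  expect_true(all(ev$response_sample > ev$cue_sample))
  expect_false(is.unsorted(ev$cue_sample))
  expect_equal(ev$decision_time_ms,
               (ev$response_sample - ev$cue_sample) / sfreq(a) * 1000)
})

test_that("cohorts have distinct participants and deterministic sub-seeds", {
  cfg <- tinyConfig(nParticipants = 4, nTrials = 8)
  coh1 <- simulateCohort(cfg)
  coh2 <- simulateCohort(cfg)
  expect_length(coh1, 4)
  expect_length(unique(vapply(coh1, participantId, character(1))), 4)
  expect_identical(lapply(coh1, sessionData), lapply(coh2, sessionData))
  # different participants get different data
  expect_false(identical(sessionData(coh1[[1]]), sessionData(coh1[[2]])))
  expect_length(simulateCohort(tinyConfig(nParticipants = 0)), 0)
})

test_that("expectedSlope is the analytic bound-over-duration ramp slope", {
  cfg <- simConfig(onsetMs = 150)
  expect_equal(expectedSlope(cfg, "selection_required", 650), 20)
  expect_equal(expectedSlope(cfg, "selection_required", 1150), 10)
  dtGrid <- seq(300, 2000, by = 50)
  sl <- expectedSlope(cfg, "selection_required", dtGrid)
  expect_true(all(diff(sl) < 0))
  expect_error(expectedSlope(cfg, "selection_required", 100), "onset")
  expect_error(expectedSlope(cfg, "nope", 500), "condition")
})

test_that("decision-time redraws are bounded and config validity guards onset", {
  # law almost entirely below onset -> bounded retries then a diagnostic
  expect_error(
    cppErp:::.withSeed(1, cppErp:::.drawDecisionTimes(
      10, shift = 0, mu = 1, sigma = 0.01, onsetMs = 2.99, maxRetries = 3)),
    "redraw")
  # a config whose typical decision time sits below the onset is invalid
  expect_error(tinyConfig(dtShiftMs = 0, dtLognormMu = 1,
                          dtLognormSigma = 0.1, onsetMs = 5),
               "onset")
})

test_that("pink noise has ~1/f power between 1 and 40 Hz", {
  cfg <- noiselessConfig(nTrials = 60, pinkRmsUv = 10, cueEvokedAmpUv = 0,
                         boundUv = c(selection_required = 0))
  s <- simulateParticipant(cfg, "p", 31)
  x <- sessionData(s)[1, ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = sfreq(s)), taper = 0,
                          plot = FALSE, spans = 31)
  sel <- sp$freq >= 1 & sp$freq <= 40
  fit <- stats::lm(log10(sp$spec[sel]) ~ log10(sp$freq[sel]))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1), 0.3)
})

test_that("reproduction-error calibration matches its target mean", {
  k <- kappaForMeanError(14.14)
  expect_equal(meanAbsErrorDeg(k), 14.14, tolerance = 1e-6)
  th <- cppErp:::.withSeed(17, cppErp:::.rvonmises(20000, k))
  expect_true(all(th >= -pi & th <= pi))
  expect_equal(mean(abs(th)) * 90 / pi, 14.14, tolerance = 0.3)
})

test_that("montages carry the analysis cluster, mastoids and 61+2 channels", {
  full <- standardMontage("full")
  expect_equal(nrow(full), 63)
  expect_true(all(c("Pz", "CPz", "POz", "P1", "P2", "M1", "M2") %in%
                    full$label))
  expect_false(any(duplicated(full$label)))
  cmp <- standardMontage("compact")
  expect_true(all(c("Pz", "CPz", "POz", "P1", "P2", "M1", "M2") %in%
                    cmp$label))
})
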
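# Preprocessing chain: rereference, downsample, epoch, baseline, smoothing,
# decision-time exclusion, variance flagging.

test_that("mastoid rereference subtracts the reference mean per sample", {
  # 3-channel toy: ch = 5, M1 = 2, M2 = 4 at one sample -> 2, -1, 1
  d <- matrix(c(5, 2, 4), 3, 1)
  ev <- data.frame(trial_id = 1L, cue_sample = 1L, response_sample = 1L,
                   condition = "a", item_side = "l", response_hand = "l",
                   decision_time_ms = 0, reproduction_error_deg = 0)[0, ]
  s <- toySession(d, events = ev, labels = c("Cz", "M1", "M2"))
  r <- rereference(s, c("M1", "M2"))
  expect_equal(as.vector(sessionData(r)), c(2, -1, 1))
})

test_that("rereference rejects a common-mode offset and missing channels err", {
  s <- simulateParticipant(tinyConfig(nTrials = 3), "p", 2)
  r1 <- rereference(s)
  s2 <- s
  s2@data <- s2@data + 11.5       # add a constant to every channel
  r2 <- rereference(s2)
  expect_equal(sessionData(r1), sessionData(r2), tolerance = 1e-12)
  # zero reference channels leave the data unchanged
  s3 <- s
  s3@data[channelLabels(s) %in% c("M1", "M2"), ] <- 0
  expect_equal(sessionData(rereference(s3)), sessionData(s3))
  expect_error(rereference(s, c("M1", "nope")), "nope")
})

test_that("downsampling preserves in-band signals and remaps events", {
  n <- 20000
  mont <- c("Cz", "M1", "M2")
  tAx <- (1:n) / 1000
  d <- rbind(sin(2 * pi * 10 * tAx), 0, 0)
  ev <- data.frame(trial_id = 1L, cue_sample = 5001L, response_sample = 5601L,
                   condition = "a", item_side = "l", response_hand = "l",
                   decision_time_ms = 600, reproduction_error_deg = 1)
  s <- toySession(d, sfreqHz = 1000, events = ev, labels = mont)
  ds <- downsampleSession(s, 250)
  expect_equal(sfreq(ds), 250)
  expect_equal(ncol(sessionData(ds)), n / 4)
  # 10 Hz unit sinusoid survives within 1%
  seg <- sessionData(ds)[1, 500:4500]
  expect_lt(abs(max(abs(seg)) - 1), 0.01)
  # constant signal stays constant
  s@data[1, ] <- 7
  expect_equal(sessionData(downsampleSession(s, 250))[1, 100:4900],
               rep(7, 4801), tolerance = 1e-9)
  # events remapped by integer division, decision time recomputed
  expect_equal(events(ds)$cue_sample, 5000L %/% 4L + 1L)
  expect_equal(events(ds)$decision_time_ms, 600)
  expect_error(downsampleSession(s, 300), "unsupported rate")
})

test_that("epoching builds the time axis and drops edge trials", {
  d <- matrix(rnorm(3 * 1000), 3)
  mkEv <- function(cue) data.frame(
    trial_id = seq_along(cue), cue_sample = cue, response_sample = cue + 25L,
    condition = "a", item_side = "l", response_hand = "l",
    decision_time_ms = 100, reproduction_error_deg = 1)
  s <- toySession(d, sfreqHz = 250, events = mkEv(c(10L, 500L)))
  # window [-4, +4] ms at 250 Hz -> 3 samples at -4, 0, +4
  ep <- epochSession(s, "cue", c(-4, 4))
  expect_equal(epochTimes(ep), c(-4, 0, 4))
  expect_equal(dim(epochData(ep))[3], 3)
  expect_equal(dim(epochData(ep))[1], 2)
  # the trial 10 samples from the start cannot host a 375-sample left window
  expect_message(ep2 <- epochSession(s, "cue", c(-1500, 0)), "dropped")
  expect_equal(dim(epochData(ep2))[1], 1)
  expect_equal(attr(ep2, "nDropped"), 1)
  expect_error(suppressMessages(epochSession(s, "cue", c(-3000, 3000))),
               "no trials")
})

test_that("response-locked epochs of a noiseless session peak at t = 0", {
  cfg <- noiselessConfig(nTrials = 6)
  s <- simulateParticipant(cfg, "p", 4)
  ep <- epochSession(s, "response", c(-200, 200))
  pz <- which(channelLabels(ep) == "Pz")
  wPz <- spatialWeights(channelPositions(s), cfg@topoCenter,
                        cfg@topoWidth)[pz]
  at0 <- which(epochTimes(ep) == 0)
  expect_equal(epochData(ep)[, pz, at0], rep(10 * unname(wPz), 6),
               tolerance = 1e-12)
})

test_that("baseline correction zeroes the baseline window mean", {
  arr <- array(rnorm(5 * 2 * 100), c(5, 2, 100))
  times <- seq(-200, 196, by = 4)
  ep <- toyEpochs(arr, times)
  bc <- baselineCorrect(ep, c(-200, -100))
  idx <- times >= -200 & times <= -100
  bl <- apply(epochData(bc)[, , idx], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-6)
  # constant trial -> all zeros
  arr2 <- array(7, c(1, 1, 100))
  expect_equal(max(abs(epochData(baselineCorrect(toyEpochs(arr2, times),
                                                 c(-200, 0))))), 0)
  # ramp 0..10 over [0, 250] with baseline [0, 250]: endpoints -5 and +5
  t2 <- seq(0, 250, by = 250 / 99)
  ramp <- array(seq(0, 10, length.out = 100), c(1, 1, 100))
  rb <- baselineCorrect(toyEpochs(ramp, t2), c(0, 250))
  expect_equal(epochData(rb)[1, 1, 1], -5, tolerance = 1e-9)
  expect_equal(epochData(rb)[1, 1, 100], 5, tolerance = 1e-9)
  expect_error(baselineCorrect(ep, c(-500, -300)), "outside")
})

test_that("Gaussian smoothing preserves constants and reproduces its kernel", {
  x <- rep(3.5, 200)
  expect_equal(smoothGaussian(x, 30, 250), x, tolerance = 1e-12)
  # unit impulse in the interior -> the sampled, renormalized kernel
  imp <- numeric(201); imp[101] <- 1
  sm <- smoothGaussian(imp, 20, 250)
  sig <- 20 * 250 / 1000
  half <- ceiling(4 * sig)
  k <- dnorm(-half:half, sd = sig); k <- k / sum(k)
  expect_equal(sm[(101 - half):(101 + half)], k, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  # sub-sample sigma: identity with a warning
  expect_warning(y <- smoothGaussian(x, 1, 250), "sample period")
  expect_identical(y, x)
})

test_that("decision-time exclusion keeps boundary values", {
  dts <- c(150, 200, 1999, 2000, 2500)
  arr <- array(rnorm(5 * 1 * 10), c(5, 1, 10))
  ep <- toyEpochs(arr, seq(0, 36, by = 4), dtMs = dts, sfreqHz = 1000)
  res <- excludeByDecisionTime(ep, c(200, 2000))
  expect_equal(res$report$n_kept, 3)
  expect_equal(res$report$n_below, 1)
  expect_equal(res$report$n_above, 1)
  expect_equal(trialInfo(res$epochs)$decision_time_ms, c(200, 1999, 2000))
  # retained trials' samples are untouched (pure selection)
  expect_identical(epochData(res$epochs), arr[2:4, , , drop = FALSE])
  # all in range -> zero removed
  res2 <- excludeByDecisionTime(ep, c(0, 5000))
  expect_equal(res2$report$n_kept, 5)
})

test_that("variance flagging finds the one bad trial, condition-blind", {
  set.seed(42)
  arr <- array(rnorm(50 * 3 * 40), c(50, 3, 40))
  arr[17, , ] <- arr[17, , ] * 10      # 100x variance
  ep <- toyEpochs(arr, seq(-80, 76, by = 4))
  fl <- flagHighVarianceTrials(ep, 3.5)
  expect_identical(which(fl$flagged), 17L)
  # flagging consults no metadata: shuffling conditions changes nothing
  ep2 <- ep
  ep2@trialInfo$condition <- sample(c("a", "b"), 50, replace = TRUE)
  expect_identical(flagHighVarianceTrials(ep2, 3.5)$flagged, fl$flagged)
  # identical trials -> MAD 0 -> no flags, warning
  arr3 <- array(rep(rnorm(3 * 40), each = 10), c(10, 3, 40))
  ep3 <- toyEpochs(arr3, seq(-20, 136, by = 4))
  expect_warning(fl3 <- flagHighVarianceTrials(ep3, 3.5), "MAD")
  expect_false(any(fl3$flagged))
  expect_error(flagHighVarianceTrials(toyEpochs(arr3[1:5, , , drop = FALSE],
                                                seq(-20, 136, by = 4))),
               "8 trials")
})

test_that("baseline correction and smoothing commute on linear signals", {
  # for affine time courses, interior smoothing is the identity, so the two
  # operations commute there
  set.seed(7)
  times <- seq(-600, 596, by = 4)
  arr <- array(0, c(4, 2, 300))
  for (tr in 1:4) for (ch in 1:2)
    arr[tr, ch, ] <- rnorm(1, sd = 3) + rnorm(1) * times / 100
  ep <- toyEpochs(arr, times)
  a <- smoothGaussian(baselineCorrect(ep, c(-400, -200)), 30, 250)
  b <- baselineCorrect(smoothGaussian(ep, 30, 250), c(-400, -200))
  interior <- 50:250   # away from reflect-padded edges
  expect_equal(epochData(a)[, , interior], epochData(b)[, , interior],
               tolerance = 1e-6)
})

test_that("downsample-then-epoch equals epoch-then-downsample on 4-sample boundaries", {
  cfg <- tinyConfig(nTrials = 10)
  s <- simulateParticipant(cfg, "p", 12)
  # force events onto 4-sample boundaries
  ev <- events(s)
  ev$cue_sample <- ((ev$cue_sample - 1L) %/% 4L) * 4L + 1L
  ev$response_sample <- ((ev$response_sample - 1L) %/% 4L) * 4L + 1L
  ev$decision_time_ms <- (ev$response_sample - ev$cue_sample) / 1000 * 1000
  s@events <- ev
  a <- epochSession(downsampleSession(s, 250), "response", c(-400, 200))
  b <- epochSession(s, "response", c(-400, 200))
  # downsample each epoch of b along time via the same FIR
  kernel <- cppErp:::.firLowpass(100, 1000)
  interior <- 30:120
  for (tr in c(1, 5)) {
    for (ch in c(1, 6)) {
      filt <- cppErp:::.filterRowsFFT(matrix(epochData(b)[tr, ch, ], 1),
                                      kernel, 4L)
      expect_equal(epochData(a)[tr, ch, interior], filt[1, interior],
                   tolerance = 1e-6)
    }
  }
})
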
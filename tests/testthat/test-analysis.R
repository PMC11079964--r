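# CPP quantities: cluster ERPs, decision-time binning, slopes, sweeps,
# topography values.

test_that("clusterAverage is the unweighted channel mean", {
  arr <- array(0, c(2, 3, 4))
  arr[, 1, ] <- 1; arr[, 2, ] <- 3; arr[, 3, ] <- 99
  ep <- toyEpochs(arr, seq(0, 12, by = 4), labels = c("Pz", "CPz", "Oz"))
  out <- clusterAverage(ep, c("Pz", "CPz"))
  expect_equal(unname(out[1, 1]), 2)
  expect_equal(dim(out), c(2, 4))
  # two identical channels -> output equals either
  out2 <- clusterAverage(ep, c("Pz", "Pz"))
  expect_equal(as.vector(out2), as.vector(arr[, 1, ]))
  expect_error(clusterAverage(ep, c("Pz", "P1")), "P1")
  # default cluster has the five a priori channels
  expect_length(eval(formals(clusterAverage)$channels), 5)
})

test_that("grandErp averages in two stages with SEM across participants", {
  # two participants with constant means 1 and 3 -> grand mean 2, SEM 1
  p1 <- matrix(1, 5, 10)   # 5 trials x 10 samples
  p2 <- matrix(3, 8, 10)
  g <- grandErp(list(p1, p2))
  expect_equal(g$mean, rep(2, 10))
  expect_equal(g$sem, rep(1, 10))
  expect_equal(g$n, 2)
  # identical participants -> SEM 0
  g2 <- grandErp(list(p1, p1))
  expect_equal(g2$sem, rep(0, 10))
  # single participant -> SEM missing
  expect_true(all(is.na(grandErp(list(p1))$sem)))
  # SEM denominator is the number of participants
  pm <- rbind(rep(1, 4), rep(2, 4), rep(6, 4))
  g3 <- grandErp(pm)
  expect_equal(g3$sem, rep(stats::sd(c(1, 2, 6)) / sqrt(3), 4))
})

test_that("decision-time binning partitions trials with the remainder rule", {
  set.seed(3)
  mk <- function(n) matrix(rnorm(n * 6), n, 6)
  dt8 <- c(300, 100, 900, 500, 700, 200, 800, 400)
  b8 <- binByDecisionTime(mk(8), dt8, 4, times = 1:6)
  expect_equal(binCounts(b8), rep(2, 4))
  expect_equal(binMeanDt(b8), c(150, 350, 600, 850))
  # 10 trials, 4 bins -> sizes 3,3,2,2 (remainders to the earliest bins)
  b10 <- binByDecisionTime(mk(10), seq(100, 1000, by = 100), 4, times = 1:6)
  expect_equal(binCounts(b10), c(3, 3, 2, 2))
  expect_equal(binMeanDt(b10), c(200, 500, 750, 950))
  # partition property: disjoint, exhaustive, sizes differ by at most 1
  for (nb in c(1, 3, 4, 7, 10)) {
    b <- binByDecisionTime(mk(10), rnorm(10), nb, times = 1:6)
    expect_equal(sum(binCounts(b)), 10)
    expect_lte(diff(range(binCounts(b))), 1)
    expect_false(is.unsorted(binMeanDt(b)))
  }
  expect_error(binByDecisionTime(mk(3), rnorm(3), 4, times = 1:6), "bins")
})

test_that("binning is stable under decision-time ties (trial-id order)", {
  m <- matrix(seq_len(4), 4, 1)
  b <- binByDecisionTime(m, c(5, 5, 5, 5), 2, trialIds = c(1, 2, 3, 4),
                         times = 1)
  expect_equal(as.vector(binMeans(b)), c(1.5, 3.5))
})

test_that("erpImage averages binned data across participants", {
  mkB <- function(val, nb = 5) new("BinnedErp", participantId = "x",
    binMeans = matrix(val, nb, 8), binMeanDtMs = seq(100, 500, length.out = nb),
    binCounts = rep(2, nb), alignment = "response", times = 1:8)
  one <- erpImage(list(mkB(4)))
  expect_equal(one$image, mkB(4)@binMeans)
  two <- erpImage(list(mkB(0), mkB(2)))
  expect_true(all(two$image == 1))
  expect_error(erpImage(list(mkB(0), mkB(2, nb = 4))), "bin counts")
})

test_that("erpSlope is the OLS slope in microvolts per second", {
  # exact line gaining 2 uV per 100 ms -> 20 uV/s
  t1 <- seq(-500, -50, by = 4)
  expect_equal(erpSlope(20 * t1 / 1000 + 3, t1, c(-500, -50)), 20)
  expect_equal(erpSlope(rep(5, length(t1)), t1, c(-500, -50)), 0)
  # 5 points 0..4 uV at 4 ms spacing -> 250 uV/s
  expect_equal(erpSlope(0:4, seq(0, 16, by = 4), c(0, 16)), 250)
  # baseline independence: constant offsets leave the slope unchanged
  set.seed(9)
  y <- rnorm(length(t1))
  expect_equal(erpSlope(y, t1, c(-400, -100)),
               erpSlope(y + 123.4, t1, c(-400, -100)), tolerance = 1e-9)
  # fewer than 3 samples -> missing
  expect_true(is.na(erpSlope(y, t1, c(-500, -496))))
})

test_that("slopeBinProfile correlates slope with bin number", {
  times <- seq(-800, 200, by = 4)
  mkB <- function(slopes) {
    bm <- do.call(rbind, lapply(slopes, function(s) s * times / 1000))
    new("BinnedErp", participantId = "x", binMeans = bm,
        binMeanDtMs = seq(400, 1000, length.out = length(slopes)),
        binCounts = rep(5, length(slopes)), alignment = "response",
        times = times)
  }
  sp <- slopeBinProfile(mkB(c(20, 15, 10, 5)), c(-500, -50))
  expect_equal(sp@slopesPerBin, c(20, 15, 10, 5), tolerance = 1e-9)
  expect_equal(sp@rSlopeVsBin, -1)
  # equal slopes in every bin -> r undefined, flagged
  expect_warning(sp2 <- slopeBinProfile(mkB(c(7, 7, 7, 7)), c(-500, -50)),
                 "identical")
  expect_true(is.na(sp2@rSlopeVsBin))
  # cue-aligned input is rejected
  b <- mkB(c(1, 2, 3, 4)); b@alignment <- "cue"
  expect_error(slopeBinProfile(b), "response-aligned")
})

test_that("noiseless simulated slopes decrease with decision time, r < 0", {
  cfg <- noiselessConfig(nTrials = 80)
  s <- simulateParticipant(cfg, "p", 44)
  pr <- preprocessSession(s, preprocessConfig(), "response")
  cav <- clusterAverage(pr$epochs)
  q <- binByDecisionTime(cav, trialInfo(pr$epochs)$decision_time_ms, 4,
                         times = epochTimes(pr$epochs))
  sp <- slopeBinProfile(q, c(-500, -50))
  expect_true(all(diff(sp@slopesPerBin) < 0))
  expect_lt(sp@rSlopeVsBin, 0)
})

test_that("slope estimator recovers expectedSlope when the window is in-ramp", {
  cfg <- noiselessConfig(nTrials = 40, dtShiftMs = 1200, dtLognormMu = 5,
                         dtLognormSigma = 0.2)
  s <- simulateParticipant(cfg, "p", 15)
  pr <- preprocessSession(s, preprocessConfig(), "response")
  cav <- clusterAverage(pr$epochs)
  # single bin: all trials; DT >= 1200 so [-500, -50] lies inside the ramp
  b <- binByDecisionTime(cav, trialInfo(pr$epochs)$decision_time_ms, 1,
                         times = epochTimes(pr$epochs))
  measured <- erpSlope(binMeans(b)[1, ], epochTimes(pr$epochs), c(-500, -50))
  w <- spatialWeights(channelPositions(s), cfg@topoCenter, cfg@topoWidth)
  wBar <- mean(w[match(c("Pz", "CPz", "POz", "P1", "P2"),
                       channelLabels(s))])
  # average of per-trial ground-truth slopes, scaled by the cluster weight
  truth <- wBar * mean(expectedSlope(cfg, "selection_required",
                                     trialInfo(pr$epochs)$decision_time_ms))
  expect_lt(abs(measured - truth) / truth, 0.05)
})

test_that("windowSweep covers the a priori cell and flags invalid cells", {
  set.seed(31)
  times <- seq(-800, 0, by = 4)
  mkB <- function() {
    slopes <- c(20, 15, 10, 5) + rnorm(4, sd = 2)
    bm <- do.call(rbind, lapply(slopes, function(s) s * times / 1000))
    new("BinnedErp", participantId = "x", binMeans = bm,
        binMeanDtMs = c(400, 600, 800, 1000), binCounts = rep(5, 4),
        alignment = "response", times = times)
  }
  sw <- windowSweep(lapply(1:6, function(i) mkB()),
                    startsMs = seq(-700, -200, by = 100),
                    endsMs = seq(-300, 0, by = 100), minWindowMs = 100)
  expect_true("-500" %in% rownames(sw$tMatrix))
  expect_true("-50" %in% colnames(sw$tMatrix) ||
              "0" %in% colnames(sw$tMatrix))
  # cells with end - start < minWindow are NA
  expect_true(is.na(sw$tMatrix["-200", "-300"]))
  # linear-in-bin slopes -> strongly negative t everywhere valid
  expect_true(all(sw$tMatrix[!is.na(sw$tMatrix)] < 0))
})

test_that("windowSweep type-I error is near alpha on null profiles", {
  # no slope-bin structure: t exceeds the 5% critical value ~5% of the time
  set.seed(202)
  n <- 25
  nRep <- 400
  crit <- qt(0.975, n - 1)
  hits <- 0
  for (r in seq_len(nRep)) {
    rs <- replicate(n, cor(1:4, rnorm(4)))
    tv <- oneSampleT(rs)@statistic
    hits <- hits + (abs(tv) > crit)
  }
  expect_gt(hits / nRep, 0.02)
  expect_lt(hits / nRep, 0.09)
})

test_that("topographyValues averages windows per channel", {
  arr <- array(5, c(3, 4, 10))
  ep <- toyEpochs(arr, seq(0, 36, by = 4),
                  labels = c("Pz", "CPz", "Fz", "Oz"))
  tv <- topographyValues(list(ep, ep), c(8, 20))
  expect_equal(unname(tv), rep(5, 4))
  expect_equal(names(tv), c("Pz", "CPz", "Fz", "Oz"))
  expect_error(topographyValues(list(ep), c(-100, 20)), "outside")
})

test_that("synthetic CPP topography peaks near the component center", {
  cfg <- noiselessConfig(nTrials = 20, montage = "full")
  s <- simulateParticipant(cfg, "p", 8)
  ep <- epochSession(s, "response", c(-600, 0))
  tv <- topographyValues(list(ep), c(-300, 0))
  scalp <- setdiff(names(tv), c("M1", "M2"))
  expect_true(names(which.max(tv[scalp])) %in% c("Pz", "CPz", "P1", "P2"))
  expect_gt(tv["Pz"], tv["Fpz"])
  expect_gt(tv["CPz"], tv["Oz"])
})
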
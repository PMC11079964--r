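# Second-level statistics and the cluster-based permutation test.

test_that("one-sample t, d = t/sqrt(n), and degenerate cases", {
  g <- oneSampleT(c(1, 2, 3))
  expect_equal(g@statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(round(g@statistic, 3), 3.464)
  expect_equal(round(g@cohenD, 3), 2.000)
  expect_equal(g@df, 2)
  # agrees with the reference implementation
  tt <- t.test(c(1, 2, 3))
  expect_equal(g@statistic, unname(tt$statistic))
  expect_equal(g@p, tt$p.value)
  # all zeros -> t = 0, p = 1
  g0 <- oneSampleT(c(0, 0, 0, 0))
  expect_equal(g0@statistic, 0)
  expect_equal(g0@p, 1)
  # zero variance, nonzero mean -> infinite t, flagged
  expect_warning(gInf <- oneSampleT(c(2, 2, 2)), "infinite")
  expect_true(is.infinite(gInf@statistic))
  expect_true(is.na(gInf@p))
})

test_that("paired t is the one-sample t on differences", {
  set.seed(5)
  a <- rnorm(12); b <- rnorm(12)
  g <- pairedT(a, b)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(g@statistic, unname(tt$statistic))
  expect_equal(g@p, tt$p.value)
  expect_equal(g@cohenD, g@statistic / sqrt(12))
  expect_equal(pairedT(a, a)@statistic, 0)
  expect_warning(pairedT(c(2, 3, 4, 5), c(1, 2, 3, 4)), "infinite")
  expect_error(pairedT(1:3, 1:4), "equal length")
})

test_that("Cohen's d reproduces the t/sqrt(n) identity on reported statistics", {
  # the identity behind every printed (t, d) pair at n = 25
  expect_equal(round(cohenDFromT(-8.858, 25), 3), -1.772)
  expect_equal(round(cohenDFromT(-5.253, 25), 3), -1.051)
  expect_equal(round(cohenDFromT(-12.336, 25), 3), -2.467)
  expect_equal(round(cohenDFromT(2.583, 25), 3), 0.517)
})

test_that("pearsonR matches the closed form and cor()", {
  expect_equal(pearsonR(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearsonR(1:10, -(1:10)), -1)
  expect_equal(pearsonR(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  set.seed(2)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(pearsonR(x, y), cor(x, y))
  expect_warning(r <- pearsonR(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(r))
  expect_error(pearsonR(1:2, 1:2), "at least 3")
})

test_that("describeMeanSem reports M and SEM", {
  d <- describeMeanSem(c(1, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$sem, 1)
  expect_equal(describeMeanSem(rep(4, 6))$sem, 0)
  expect_true(is.na(describeMeanSem(7)$sem))
  expect_equal(formatMeanSem(c(1, 3), unit = "degrees"), "2.00 ± 1.00 degrees")
})

test_that("cluster test handles null and saturated inputs", {
  # all-zero data -> no clusters
  z <- clusterTest(matrix(0, 4, 20))
  expect_equal(nrow(clusters(z)), 0)
  # constant strong effect -> one cluster spanning the window, minimal p
  set.seed(8)
  X <- matrix(rnorm(8 * 30, mean = 0, sd = 0.05) + 5, 8, 30)
  ct <- clusterTest(X)      # n = 8 -> exhaustive over 256 patterns
  expect_true(ct@exhaustive)
  cl <- clusters(ct)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$istart, 1)
  expect_equal(cl$iend, 30)
  expect_equal(cl$p_perm, 2 / 256)   # only the +/- identity reach the mass
})

test_that("exact null for two identical participants is enumerable by hand", {
  # both participants show the same positive deflection; 4 sign patterns:
  # ++ and -- give |t| = Inf (capped) clusters, +- and -+ give t = 0
  X <- rbind(c(0, 5, 5, 0), c(0, 5, 5, 0))
  en <- enumerateClusterNull(X)
  expect_length(en$nullMax, 4)
  ct <- clusterTest(X)
  expect_equal(clusters(ct)$p_perm, 0.5)
  # exhaustive p >= 1/2^n always
  expect_true(all(clusters(ct)$p_perm >= 1 / 4))
})

test_that("Monte-Carlo p values converge to the exhaustive null (n = 6)", {
  set.seed(61)
  X <- matrix(rnorm(6 * 20), 6, 20) + 1.1
  exact <- clusterTest(X, exhaustive = TRUE)
  mc <- clusterTest(X, exhaustive = FALSE, nPermutations = 10000, seed = 3)
  expect_true(exact@exhaustive)
  expect_false(mc@exhaustive)
  expect_equal(nrow(clusters(exact)), nrow(clusters(mc)))
  for (k in seq_len(nrow(clusters(exact)))) {
    pE <- clusters(exact)$p_perm[k]
    pM <- clusters(mc)$p_perm[k]
    # Monte-Carlo error: ~3 binomial SDs plus the +1 correction
    tol <- 3 * sqrt(pE * (1 - pE) / 10000) + 2e-4
    expect_lt(abs(pM - pE), tol)
  }
  # a second seed agrees too (convergence, not coincidence)
  mc2 <- clusterTest(X, exhaustive = FALSE, nPermutations = 10000, seed = 99)
  expect_lt(max(abs(clusters(mc2)$p_perm - clusters(mc)$p_perm)), 0.02)
})

test_that("permutation p values are invariant to time-axis reversal", {
  set.seed(12)
  X <- matrix(rnorm(6 * 25), 6, 25) + 0.9
  a <- clusterTest(X)
  b <- clusterTest(X[, ncol(X):1])
  expect_equal(sort(clusters(a)$p_perm), sort(clusters(b)$p_perm))
  expect_equal(sort(abs(clusters(a)$mass)), sort(abs(clusters(b)$mass)),
               tolerance = 1e-9)
})

test_that("paired cluster test equals the one-sample test on differences", {
  set.seed(77)
  A <- matrix(rnorm(6 * 15), 6, 15) + 1
  B <- matrix(rnorm(6 * 15), 6, 15)
  p2 <- clusterTest(A, "paired", B)
  o1 <- clusterTest(A - B)
  expect_equal(clusters(p2), clusters(o1))
  expect_equal(p2@tSeries, o1@tSeries)
  expect_error(clusterTest(A, "paired"), "both condition")
  expect_error(clusterTest(A, "paired", B[, 1:7]), "shape")
})

test_that("cluster-forming threshold is the parametric two-sided critical t", {
  X <- matrix(rnorm(10 * 12), 10, 12)
  ct <- clusterTest(X, clusterAlpha = 0.05)
  expect_equal(ct@threshold, qt(0.975, 9))
  ct2 <- clusterTest(X, clusterAlpha = 0.01)
  expect_equal(ct2@threshold, qt(0.995, 9))
})

test_that("small permutation counts and oversized enumerations are flagged", {
  X <- matrix(rnorm(20 * 10), 20, 10)
  expect_warning(clusterTest(X, nPermutations = 50, exhaustive = FALSE),
                 "permutations")
  expect_error(enumerateClusterNull(matrix(rnorm(22 * 4), 22, 4)),
               "enumeration limit")
})
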
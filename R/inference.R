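## Second-level statistics: one-sample / paired t with Cohen's d (= t/sqrt(n)
## for these designs), Pearson correlation, mean +/- SEM description, and
## cluster-based permutation tests along the time axis with an exact
## enumeration mode for small samples.

#' One-sample t test against zero
#'
#' @param values per-participant scalars (first-level statistics)
#' @param mu null value (default 0)
#' @return \linkS4class{GroupStatResult}; zero variance with a nonzero mean
#'   yields an infinite t with \code{p = NA} and a warning
#' @export
#' @examples
#' oneSampleT(c(1, 2, 3))   # t = 3.464, d = 2.000
oneSampleT <- function(values, mu = 0) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  sem <- s / sqrt(n)
  if (s == 0) {
    if (m == mu) {
      t <- 0; p <- 1
    } else {
      warning("zero variance with nonzero mean: t is infinite")
      t <- sign(m - mu) * Inf; p <- NA_real_
    }
  } else {
    t <- (m - mu) / sem
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  new("GroupStatResult", statistic = t, df = n - 1, p = p,
      cohenD = if (is.finite(t)) t / sqrt(n) else t, mean = m, sem = sem,
      n = n)
}

#' Paired t test
#'
#' One-sample t test on the within-participant differences \code{a - b};
#' Cohen's d equals t / sqrt(n).
#'
#' @param a,b per-participant scalars of equal length
#' @return \linkS4class{GroupStatResult}
#' @export
pairedT <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  oneSampleT(a - b)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return correlation coefficient; NA with a warning when either input is
#'   constant
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: correlation undefined")
    return(NA_real_)
  }
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

#' Mean and standard error of the mean
#'
#' @param values numeric vector
#' @return list with \code{mean}, \code{sem} (NA when n < 2) and \code{n}
#' @export
describeMeanSem <- function(values) {
  n <- length(values)
  list(mean = mean(values),
       sem = if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_, n = n)
}

# ---------------------------------------------------------------------------
# cluster machinery

# Contiguous runs where t exceeds the threshold, split by sign.
# Returns data.frame(istart, iend, mass).
.findClusters <- function(tv, threshold, tail = "two") {
  supra <- switch(tail,
                  two = ifelse(tv > threshold, 1L, ifelse(tv < -threshold, -1L, 0L)),
                  pos = ifelse(tv > threshold, 1L, 0L),
                  neg = ifelse(tv < -threshold, -1L, 0L))
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0L
  if (!any(keep))
    return(data.frame(istart = integer(0), iend = integer(0),
                      mass = numeric(0)))
  data.frame(istart = starts[keep], iend = ends[keep],
             mass = vapply(which(keep), function(k)
               sum(tv[starts[k]:ends[k]]), numeric(1)))
}

# Max |cluster mass| of one t series (0 when no cluster).
.maxClusterMass <- function(tv, threshold, tail = "two") {
  cl <- .findClusters(tv, threshold, tail)
  if (nrow(cl) == 0) 0 else max(abs(cl$mass))
}

# t series for every row of a sign matrix S (rows = +/-1 patterns over
# participants) applied to data X (participants x time). Sign flipping leaves
# the per-column sum of squares unchanged, so only the mean changes. A
# zero-variance column with nonzero mean (infinite t) is capped at +/- 1e6 so
# that degenerate data still form (maximally massive) clusters.
.signFlipTSeries <- function(S, X) {
  n <- nrow(X)
  ss <- colSums(X^2)
  M <- (S %*% X) / n
  V <- sweep(-M^2, 2, ss / n, `+`) * (n / (n - 1))
  V[V < 0] <- 0
  T <- M / sqrt(V / n)
  bad <- !is.finite(T)
  if (any(bad)) T[bad] <- sign(M[bad]) * 1e6
  T
}

#' Cluster-based permutation test along the time axis
#'
#' Per-timepoint one-sample (or paired) t values are thresholded at the
#' two-sided parametric critical value for \code{clusterAlpha}; contiguous
#' suprathreshold runs of equal sign form clusters whose mass is the sum of t
#' within the run. The null distribution is built by random whole-participant
#' sign flips (one-sample) or condition swaps (paired; equivalent to sign
#' flips of the differences), taking the maximum absolute cluster mass per
#' permutation. Permutation p values follow the
#' \code{(1 + #exceedances) / (1 + nPermutations)} convention, so p >
#' 0 always. When the pattern space is small (2^n <= \code{exhaustiveLimit})
#' the null is enumerated exactly instead.
#'
#' @param x participants x time matrix (for "paired", condition A)
#' @param design "one_sample" or "paired"
#' @param y condition B matrix for the paired design
#' @param times time axis in ms (default sample indices)
#' @param clusterAlpha alpha of the cluster-forming threshold (default 0.05)
#' @param nPermutations Monte-Carlo permutations (default 10000; a value
#'   below 100 triggers a warning)
#' @param seed RNG seed for the permutations
#' @param tail "two" (default), "pos" or "neg"
#' @param exhaustive force (TRUE) or forbid (FALSE) exact enumeration;
#'   NULL (default) auto-selects when 2^n <= \code{exhaustiveLimit}
#' @param exhaustiveLimit pattern-count bound for auto-selection (2^14)
#' @return \linkS4class{ClusterTestResult}
#' @seealso \code{\link{enumerateClusterNull}}
#' @export
clusterTest <- function(x, design = c("one_sample", "paired"), y = NULL,
                        times = NULL, clusterAlpha = 0.05,
                        nPermutations = 10000, seed = 1, tail = "two",
                        exhaustive = NULL, exhaustiveLimit = 2^14) {
  design <- match.arg(design)
  x <- as.matrix(x)
  if (design == "paired") {
    if (is.null(y)) stop("paired design needs both condition matrices")
    y <- as.matrix(y)
    if (!identical(dim(x), dim(y))) stop("condition matrices differ in shape")
    X <- x - y
  } else X <- x
  n <- nrow(X)
  nT <- ncol(X)
  if (n < 2) stop("need at least 2 participants")
  if (nT < 2) stop("need at least 2 time points")
  if (is.null(times)) times <- seq_len(nT)
  if (nPermutations < 100)
    warning("fewer than 100 permutations: p values will be coarse")
  threshold <- stats::qt(1 - clusterAlpha / 2, df = n - 1)

  obsT <- as.vector(.signFlipTSeries(matrix(1, 1, n), X))
  cl <- .findClusters(obsT, threshold, tail)

  useExact <- if (is.null(exhaustive)) 2^n <= exhaustiveLimit else exhaustive
  if (useExact) {
    nullMax <- enumerateClusterNull(X, clusterAlpha = clusterAlpha,
                                    tail = tail)$nullMax
    pcl <- vapply(cl$mass, function(m)
      mean(nullMax >= abs(m) * (1 - 1e-9) - 1e-9), numeric(1))
    nPerm <- length(nullMax)
    seedOut <- NA_real_
  } else {
    nullMax <- .withSeed(seed, {
      S <- matrix(sample(c(-1, 1), nPermutations * n, replace = TRUE),
                  nPermutations, n)
      Tn <- .signFlipTSeries(S, X)
      apply(Tn, 1, .maxClusterMass, threshold = threshold, tail = tail)
    })
    pcl <- vapply(cl$mass, function(m)
      (1 + sum(nullMax >= abs(m) * (1 - 1e-9) - 1e-9)) / (1 + nPermutations),
      numeric(1))
    nPerm <- nPermutations
    seedOut <- seed
  }
  clusters <- data.frame(
    start_ms = times[cl$istart], end_ms = times[cl$iend],
    istart = cl$istart, iend = cl$iend, mass = cl$mass, p_perm = pcl)
  new("ClusterTestResult", tSeries = obsT, times = as.numeric(times),
      clusters = clusters, threshold = threshold, clusterAlpha = clusterAlpha,
      nPermutations = nPerm, seed = seedOut, tail = tail,
      exhaustive = useExact, design = design)
}

#' Exhaustive permutation null for the cluster test
#'
#' Enumerates all 2^n whole-participant sign-flip patterns (condition swaps
#' for a paired design) and returns the exact null distribution of the
#' maximum absolute cluster mass. The identity pattern is included, so exact
#' p values are always >= 1/2^n.
#'
#' @param x participants x time matrix (for "paired", condition A)
#' @param design "one_sample" or "paired"
#' @param y condition B matrix for the paired design
#' @param clusterAlpha alpha of the cluster-forming threshold
#' @param tail "two", "pos" or "neg"
#' @return list with \code{nullMax} (length 2^n) and \code{threshold}
#' @export
enumerateClusterNull <- function(x, design = c("one_sample", "paired"),
                                 y = NULL, clusterAlpha = 0.05,
                                 tail = "two") {
  design <- match.arg(design)
  x <- as.matrix(x)
  if (design == "paired") {
    if (is.null(y)) stop("paired design needs both condition matrices")
    X <- x - as.matrix(y)
  } else X <- x
  n <- nrow(X)
  if (2^n > 2^20)
    stop(sprintf("pattern space 2^%d exceeds the enumeration limit 2^20", n))
  threshold <- stats::qt(1 - clusterAlpha / 2, df = n - 1)
  nPat <- 2^n
  S <- matrix(1, nPat, n)
  for (i in seq_len(n))
    S[, i] <- ifelse(bitwAnd(seq_len(nPat) - 1L, bitwShiftL(1L, i - 1L)) > 0,
                     -1, 1)
  Tn <- .signFlipTSeries(S, X)
  nullMax <- apply(Tn, 1, .maxClusterMass, threshold = threshold, tail = tail)
  list(nullMax = nullMax, threshold = threshold)
}

#' Effect size from a t statistic
#'
#' Cohen's d for one-sample and paired designs: d = t / sqrt(n).
#'
#' @param t t statistic
#' @param n number of participants
#' @return Cohen's d
#' @export
cohenDFromT <- function(t, n) t / sqrt(n)

#' Family-wise false-positive rate of the cluster test on null data
#'
#' Simulates Gaussian-noise datasets (participants x time, no effect) and
#' returns the fraction in which the one-sample cluster test reports any
#' cluster with p below \code{alpha} — the family-wise type-I error, which a
#' calibrated test keeps near \code{alpha}.
#'
#' @param nSimulations number of null datasets
#' @param nParticipants,nTimePoints dataset shape
#' @param nPermutations Monte-Carlo permutations per test
#' @param clusterAlpha cluster-forming alpha (also the verdict alpha)
#' @param alpha significance level applied to cluster p values
#' @param seed RNG seed
#' @return list with \code{fpr}, \code{hits} and \code{nSimulations}
#' @export
clusterTestFpr <- function(nSimulations = 500, nParticipants = 25,
                           nTimePoints = 200, nPermutations = 1000,
                           clusterAlpha = 0.05, alpha = 0.05, seed = 1) {
  seeds <- .withSeed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                             2 * nSimulations),
                                  nSimulations, 2))
  hits <- 0L
  for (i in seq_len(nSimulations)) {
    X <- .withSeed(seeds[i, 1],
                   matrix(stats::rnorm(nParticipants * nTimePoints),
                          nParticipants, nTimePoints))
    ct <- clusterTest(X, clusterAlpha = clusterAlpha,
                      nPermutations = nPermutations, seed = seeds[i, 2],
                      exhaustive = FALSE)
    cl <- ct@clusters
    if (nrow(cl) && any(cl$p_perm < alpha)) hits <- hits + 1L
  }
  list(fpr = hits / nSimulations, hits = hits, nSimulations = nSimulations)
}
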
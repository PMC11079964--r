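## Preprocessing chain: mastoid-average rereference -> anti-aliased
## downsampling -> event-locked epoching -> decision-time exclusion ->
## robust variance flagging -> baseline correction (Gaussian smoothing is
## applied to averaged time courses at analysis time; it is linear, so the
## order relative to averaging does not matter).

#' Rereference a session to the average of reference channels
#'
#' Subtracts the sample-wise mean of the reference channels (by default the
#' two mastoids) from every channel. Reference channels are retained in the
#' output.
#'
#' @param session \linkS4class{RawSession}
#' @param refChannels channel labels to average as the reference
#' @return \linkS4class{RawSession}
#' @export
rereference <- function(session, refChannels = c("M1", "M2")) {
  stopifnot(is(session, "RawSession"))
  idx <- match(refChannels, session@channelLabels)
  if (anyNA(idx))
    stop("reference channel(s) not present: ",
         paste(refChannels[is.na(idx)], collapse = ", "))
  ref <- colMeans(session@data[idx, , drop = FALSE])
  session@data <- session@data - rep(ref, each = nrow(session@data))
  session
}

# Hamming-windowed FIR low-pass kernel (odd length -> exact zero phase),
# renormalized to unit DC gain so constants pass through exactly.
.firLowpass <- function(cutoffHz, sfreqHz, nTaps = 101) {
  wn <- cutoffHz / (sfreqHz / 2)
  k <- as.numeric(signal::fir1(nTaps - 1, wn))
  k / sum(k)
}

# Zero-phase FIR filtering of the rows of a matrix via FFT convolution,
# with optional decimation performed in the frequency domain. The symmetric
# kernel is wrapped so its centre tap sits at index 1; the signal is
# zero-padded, making the circular convolution linear (edge transients are
# confined to half a kernel length at each end). Decimation by `fac` folds
# the spectrum to length npad/fac, which is exactly the DFT of every
# fac-th sample of the filtered signal.
.filterRowsFFT <- function(x, kernel, fac = 1L) {
  n <- ncol(x)
  k <- length(kernel)
  half <- (k - 1) / 2
  npad <- stats::nextn(n + k, c(2, 3))
  while (npad %% (2 * fac) != 0) npad <- stats::nextn(npad + 1, c(2, 3))
  kv <- numeric(npad)
  kv[1] <- kernel[half + 1]
  kv[2:(half + 1)] <- kernel[(half + 2):k]
  kv[(npad - half + 1):npad] <- kernel[1:half]
  H <- stats::fft(kv)
  nOut <- length(seq(1, n, by = fac))
  out <- matrix(0, nrow(x), nOut)
  m <- npad / fac
  for (r in seq_len(nrow(x))) {
    X <- stats::fft(c(x[r, ], numeric(npad - n)))
    Y <- X * H
    if (fac > 1L) {
      Yd <- Y[1:m]
      for (j in seq_len(fac - 1)) Yd <- Yd + Y[(j * m + 1):((j + 1) * m)]
      out[r, ] <- Re(stats::fft(Yd, inverse = TRUE))[seq_len(nOut)] / npad
    } else {
      out[r, ] <- Re(stats::fft(Y, inverse = TRUE))[seq_len(n)] / npad
    }
  }
  out
}

#' Downsample a session with zero-phase anti-alias filtering
#'
#' Applies a zero-phase FIR low-pass (cutoff 0.4 x target rate) and decimates.
#' Event samples are remapped by integer division; decision times are
#' recomputed from the remapped samples and may therefore shift by less than
#' one target-rate sample period.
#'
#' @param session \linkS4class{RawSession}
#' @param targetSfreqHz target rate; the source rate must be an integer
#'   multiple
#' @return \linkS4class{RawSession} at the target rate
#' @export
downsampleSession <- function(session, targetSfreqHz = 250) {
  stopifnot(is(session, "RawSession"))
  fs <- session@sfreqHz
  if (fs == targetSfreqHz) return(session)
  fac <- fs / targetSfreqHz
  if (fac != round(fac) || fac < 1)
    stop(sprintf("unsupported rate: %g Hz is not an integer divisor of %g Hz",
                 targetSfreqHz, fs))
  fac <- as.integer(fac)
  kernel <- .firLowpass(0.4 * targetSfreqHz, fs)
  session@data <- .filterRowsFFT(session@data, kernel, fac)
  session@sfreqHz <- targetSfreqHz
  ev <- session@events
  ev$cue_sample <- (ev$cue_sample - 1L) %/% fac + 1L
  ev$response_sample <- (ev$response_sample - 1L) %/% fac + 1L
  ev$decision_time_ms <-
    (ev$response_sample - ev$cue_sample) / targetSfreqHz * 1000
  session@events <- ev
  validObject(session)
  session
}

#' Epoch a session around cue or response events
#'
#' Cuts one epoch per trial anchored at the cue or response sample. Trials
#' whose window would extend beyond the recording are dropped; the drop count
#' is attached as attribute \code{"nDropped"} and reported via a message.
#'
#' @param session \linkS4class{RawSession}
#' @param alignment "cue" or "response"
#' @param windowMs c(start, end) in ms relative to the anchor
#' @return \linkS4class{EpochSet} (time axis in ms, anchor at 0)
#' @export
epochSession <- function(session, alignment = c("cue", "response"),
                         windowMs) {
  stopifnot(is(session, "RawSession"))
  alignment <- match.arg(alignment)
  fs <- session@sfreqHz
  step <- 1000 / fs
  offs <- seq(round(windowMs[1] / step), round(windowMs[2] / step))
  if (length(offs) < 2) stop("epoch window must cover at least 2 samples")
  times <- offs * step
  anchor <- if (alignment == "cue") session@events$cue_sample else
    session@events$response_sample
  nS <- ncol(session@data)
  ok <- anchor + offs[1] >= 1 & anchor + offs[length(offs)] <= nS
  nDropped <- sum(!ok)
  if (!any(ok))
    stop("no trials survive epoching: every window exceeds the recording")
  if (nDropped > 0)
    message(nDropped, " trial(s) dropped: epoch window exceeds the recording")
  anchor <- anchor[ok]
  nTr <- length(anchor)
  nCh <- nrow(session@data)
  arr <- array(NA_real_, c(nTr, nCh, length(offs)))
  for (i in seq_len(nTr))
    arr[i, , ] <- session@data[, anchor[i] + offs]
  ep <- new("EpochSet", data = arr, sfreqHz = fs, alignment = alignment,
            times = times, channelLabels = session@channelLabels,
            channelPositions = session@channelPositions,
            trialInfo = session@events[ok, , drop = FALSE],
            participantId = session@participantId)
  attr(ep, "nDropped") <- nDropped
  ep
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and channel, the mean over the baseline window. The
#' mean of the corrected data over the baseline window is zero to floating
#' point tolerance.
#'
#' @param epochs \linkS4class{EpochSet}
#' @param baselineMs c(start, end) in ms; must lie inside the epoch window
#' @return \linkS4class{EpochSet}
#' @export
baselineCorrect <- function(epochs, baselineMs) {
  stopifnot(is(epochs, "EpochSet"))
  idx <- which(epochs@times >= baselineMs[1] & epochs@times <= baselineMs[2])
  step <- 1000 / epochs@sfreqHz   # allow one-sample slack at the edges
  if (length(idx) == 0 || baselineMs[1] < min(epochs@times) - step ||
      baselineMs[2] > max(epochs@times) + step)
    stop(sprintf("baseline [%g, %g] ms lies outside the epoch window [%g, %g]",
                 baselineMs[1], baselineMs[2], min(epochs@times),
                 max(epochs@times)))
  bl <- apply(epochs@data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs@data <- epochs@data - as.vector(bl)   # recycles over time (dim 3)
  epochs
}

# Discrete Gaussian kernel truncated at +/- 4 sigma, renormalized to sum 1.
.gaussKernel <- function(sigmaSamples) {
  half <- ceiling(4 * sigmaSamples)
  k <- stats::dnorm(-half:half, sd = sigmaSamples)
  k / sum(k)
}

# Reflect-padded convolution of a vector with a symmetric kernel.
.smoothVector <- function(x, kernel) {
  half <- (length(kernel) - 1) / 2
  n <- length(x)
  if (half >= n)  # fall back to edge replication for very short series
    xp <- c(rep(x[1], half), x, rep(x[n], half))
  else
    xp <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
  as.numeric(stats::filter(xp, kernel, method = "convolution",
                           sides = 2))[(half + 1):(half + n)]
}

#' Gaussian smoothing along the time axis
#'
#' Convolution with a discrete Gaussian kernel (truncated at 4 SD,
#' renormalized to sum 1) with reflect-padded boundaries, applied along time
#' only. Used in place of low-pass filtering for CPP time courses. If the
#' requested SD is shorter than one sample period the input is returned
#' unchanged with a warning.
#'
#' @param x numeric vector, matrix (series in rows) or \linkS4class{EpochSet}
#' @param sigmaMs kernel SD in ms (default 30)
#' @param sfreqHz sampling rate; taken from the object for
#'   \linkS4class{EpochSet} input
#' @return same shape as the input
#' @export
setGeneric("smoothGaussian",
           function(x, sigmaMs = 30, sfreqHz) standardGeneric("smoothGaussian"))

#' @rdname smoothGaussian
setMethod("smoothGaussian", "numeric", function(x, sigmaMs = 30, sfreqHz) {
  stopifnot(sigmaMs > 0)
  sig <- sigmaMs * sfreqHz / 1000
  if (sig < 1) {
    warning("smoothing SD shorter than one sample period; returning input")
    return(x)
  }
  .smoothVector(x, .gaussKernel(sig))
})

#' @rdname smoothGaussian
setMethod("smoothGaussian", "matrix", function(x, sigmaMs = 30, sfreqHz) {
  stopifnot(sigmaMs > 0)
  sig <- sigmaMs * sfreqHz / 1000
  if (sig < 1) {
    warning("smoothing SD shorter than one sample period; returning input")
    return(x)
  }
  k <- .gaussKernel(sig)
  t(apply(x, 1, .smoothVector, kernel = k))
})

#' @rdname smoothGaussian
setMethod("smoothGaussian", "EpochSet", function(x, sigmaMs = 30, sfreqHz) {
  sig <- sigmaMs * x@sfreqHz / 1000
  if (sig < 1) {
    warning("smoothing SD shorter than one sample period; returning input")
    return(x)
  }
  k <- .gaussKernel(sig)
  d <- dim(x@data)
  for (tr in seq_len(d[1])) {
    m <- matrix(x@data[tr, , ], nrow = d[2])
    x@data[tr, , ] <- t(apply(m, 1, .smoothVector, kernel = k))
  }
  x
})

#' Exclude trials by decision time
#'
#' Removes trials whose decision time is strictly below the lower bound or
#' strictly above the upper bound; boundary values are kept.
#'
#' @param epochs \linkS4class{EpochSet}
#' @param boundsMs c(low, high) in ms (default c(200, 2000))
#' @return list with \code{epochs} (retained trials, samples untouched) and
#'   \code{report} (counts per reason)
#' @export
excludeByDecisionTime <- function(epochs, boundsMs = c(200, 2000)) {
  stopifnot(is(epochs, "EpochSet"))
  dt <- epochs@trialInfo$decision_time_ms
  if (is.null(dt)) stop("trial metadata lacks decision_time_ms")
  below <- dt < boundsMs[1]
  above <- dt > boundsMs[2]
  keep <- !(below | above)
  report <- list(n_total = length(dt), n_below = sum(below),
                 n_above = sum(above), n_kept = sum(keep),
                 bounds_ms = boundsMs)
  epochs@data <- epochs@data[keep, , , drop = FALSE]
  epochs@trialInfo <- epochs@trialInfo[keep, , drop = FALSE]
  list(epochs = epochs, report = report)
}

#' Flag trials with exceptional broadband variance
#'
#' Automated, condition-blind stand-in for visual trial rejection: the log of
#' each trial's broadband variance (over the given channels and all epoch
#' samples) is robustly z-scored (median/MAD) and trials exceeding the
#' threshold are flagged. No trial metadata is consulted.
#'
#' @param epochs \linkS4class{EpochSet} with at least 8 trials
#' @param zThreshold robust z threshold (default 3.5)
#' @param channels channel labels to use (default: all channels)
#' @return list with \code{flagged} (logical mask over trials) and
#'   \code{report}
#' @export
flagHighVarianceTrials <- function(epochs, zThreshold = 3.5, channels = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  n <- dim(epochs@data)[1]
  if (n < 8) stop("variance flagging needs at least 8 trials")
  chIdx <- if (is.null(channels)) seq_along(epochs@channelLabels) else {
    m <- match(channels, epochs@channelLabels)
    if (anyNA(m)) stop("unknown channel(s): ",
                       paste(channels[is.na(m)], collapse = ", "))
    m
  }
  v <- vapply(seq_len(n), function(i)
    stats::var(as.vector(epochs@data[i, chIdx, ])), numeric(1))
  lv <- log(v)
  med <- stats::median(lv)
  madv <- stats::mad(lv)
  if (madv == 0) {
    warning("MAD of log trial variance is zero; no trials flagged")
    flagged <- rep(FALSE, n)
    z <- rep(0, n)
  } else {
    z <- (lv - med) / madv
    flagged <- z > zThreshold
  }
  list(flagged = flagged,
       report = list(n_total = n, n_flagged = sum(flagged),
                     z_threshold = zThreshold, z = z))
}

#' Run the full preprocessing chain on a raw session
#'
#' Rereference, downsample, epoch at the requested alignment, exclude trials
#' by decision time, drop variance-flagged trials, and baseline-correct.
#'
#' @param session \linkS4class{RawSession}
#' @param pconfig \linkS4class{PreprocessConfig}
#' @param alignment "cue" or "response"
#' @param flagChannels channels used for variance flagging (default all)
#' @return list with \code{epochs} and \code{report} (retention accounting)
#' @export
preprocessSession <- function(session, pconfig = preprocessConfig(),
                              alignment = c("cue", "response"),
                              flagChannels = NULL) {
  alignment <- match.arg(alignment)
  validObject(pconfig)
  s <- rereference(session, pconfig@refChannels)
  s <- downsampleSession(s, pconfig@targetSfreqHz)
  .epochAndClean(s, pconfig, alignment, flagChannels)
}

# Epoching half of the chain, applied to an already rereferenced and
# downsampled session (so both alignments can share that work).
.epochAndClean <- function(s, pconfig, alignment, flagChannels = NULL) {
  win <- if (alignment == "cue") pconfig@cueWindowMs else pconfig@respWindowMs
  ep <- epochSession(s, alignment, win)
  nDroppedEdge <- attr(ep, "nDropped")
  ex <- excludeByDecisionTime(ep, pconfig@dtBoundsMs)
  fl <- flagHighVarianceTrials(ex$epochs, pconfig@varianceZThreshold,
                               flagChannels)
  ep2 <- ex$epochs
  if (any(fl$flagged)) {
    ep2@data <- ep2@data[!fl$flagged, , , drop = FALSE]
    ep2@trialInfo <- ep2@trialInfo[!fl$flagged, , drop = FALSE]
  }
  bl <- if (alignment == "cue") pconfig@cueBaselineMs else
    pconfig@respBaselineMs
  ep2 <- baselineCorrect(ep2, bl)
  list(epochs = ep2,
       report = list(n_events = nTrials(s),
                     n_dropped_edge = nDroppedEdge,
                     n_below = ex$report$n_below, n_above = ex$report$n_above,
                     n_flagged = fl$report$n_flagged,
                     n_retained = dim(ep2@data)[1]))
}
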
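## CPP quantities: electrode-cluster ERPs, decision-time-binned ERP images,
## pre-decision slopes, slope-vs-bin correlations and the slope-window sweep.

#' Average an epoch set over an electrode cluster
#'
#' Unweighted mean over the named channels, per trial and sample.
#'
#' @param epochs \linkS4class{EpochSet}
#' @param channels channel labels (default: the a priori Pz-centred cluster)
#' @return trials x time matrix with attribute \code{"times"} (ms)
#' @export
clusterAverage <- function(epochs,
                           channels = c("Pz", "CPz", "POz", "P1", "P2")) {
  stopifnot(is(epochs, "EpochSet"))
  idx <- match(channels, epochs@channelLabels)
  if (anyNA(idx))
    stop("cluster channel(s) missing from the montage: ",
         paste(channels[is.na(idx)], collapse = ", "))
  d <- dim(epochs@data)
  sub <- epochs@data[, idx, , drop = FALSE]
  out <- apply(sub, c(1, 3), mean)
  dim(out) <- c(d[1], d[3])
  attr(out, "times") <- epochs@times
  out
}

#' Grand-average ERP with across-participant SEM
#'
#' Two-stage averaging: trials are averaged within participant first, then
#' the mean and SEM are taken across participants (the SEM denominator is the
#' number of participants).
#'
#' @param perParticipant list of trials x time matrices (one per participant),
#'   or a participants x time matrix of participant means
#' @return list with \code{mean}, \code{sem} (NA when only one participant)
#'   and \code{n}
#' @export
grandErp <- function(perParticipant) {
  pm <- if (is.list(perParticipant))
    do.call(rbind, lapply(perParticipant, colMeans))
  else as.matrix(perParticipant)
  n <- nrow(pm)
  if (n < 1) stop("no participants")
  m <- colMeans(pm)
  sem <- if (n >= 2) apply(pm, 2, stats::sd) / sqrt(n) else
    rep(NA_real_, ncol(pm))
  list(mean = m, sem = sem, n = n)
}

#' Bin trials by decision time
#'
#' Sorts trials by decision time (stable sort; ties broken by trial id) and
#' partitions them into contiguous bins as equal in size as possible, with
#' remainder trials assigned to the earliest (fastest) bins. Computes the
#' bin-average ERP and per-bin mean decision time.
#'
#' @param trialSeries trials x time matrix (e.g. from
#'   \code{\link{clusterAverage}})
#' @param dtMs per-trial decision times (ms)
#' @param nBins number of bins (at most the trial count); 100 for the fine
#'   ERP-image binning, 4 for quartile bins
#' @param trialIds tie-break ids (default: input order)
#' @param times time axis stored in the result (ms)
#' @param alignment alignment tag ("cue" or "response")
#' @param participantIdent identifier stored in the result
#' @return \linkS4class{BinnedErp}
#' @export
binByDecisionTime <- function(trialSeries, dtMs, nBins,
                              trialIds = seq_along(dtMs),
                              times = attr(trialSeries, "times"),
                              alignment = "response",
                              participantIdent = "participant") {
  trialSeries <- as.matrix(trialSeries)
  n <- nrow(trialSeries)
  if (length(dtMs) != n) stop("dtMs must have one entry per trial")
  if (nBins > n)
    stop(sprintf("cannot form %d bins from %d trials", nBins, n))
  if (is.null(times)) times <- seq_len(ncol(trialSeries))
  ord <- order(dtMs, trialIds)
  base <- n %/% nBins
  sizes <- base + (seq_len(nBins) <= n %% nBins)
  stopEnd <- cumsum(sizes)
  startAt <- stopEnd - sizes + 1
  bm <- matrix(NA_real_, nBins, ncol(trialSeries))
  mdt <- numeric(nBins)
  for (b in seq_len(nBins)) {
    rows <- ord[startAt[b]:stopEnd[b]]
    bm[b, ] <- colMeans(trialSeries[rows, , drop = FALSE])
    mdt[b] <- mean(dtMs[rows])
  }
  new("BinnedErp", participantId = participantIdent, binMeans = bm,
      binMeanDtMs = mdt, binCounts = sizes, alignment = alignment,
      times = times)
}

#' Across-participant ERP image
#'
#' Element-wise mean of per-participant binned ERPs, plus the
#' across-participant mean of per-bin mean decision times (the "black line"
#' of an ERP image).
#'
#' @param binnedList list of \linkS4class{BinnedErp} with identical bin counts
#'   and time axes
#' @return list with \code{image} (bins x time), \code{meanDtMs} (per bin),
#'   \code{times} and \code{n}
#' @export
erpImage <- function(binnedList) {
  stopifnot(length(binnedList) >= 1)
  nb <- nrow(binnedList[[1]]@binMeans)
  tms <- binnedList[[1]]@times
  for (b in binnedList) {
    if (nrow(b@binMeans) != nb) stop("bin counts differ across participants")
    if (length(b@times) != length(tms) || any(abs(b@times - tms) > 1e-9))
      stop("time axes differ across participants")
  }
  img <- Reduce(`+`, lapply(binnedList, binMeans)) / length(binnedList)
  mdt <- Reduce(`+`, lapply(binnedList, binMeanDt)) / length(binnedList)
  list(image = img, meanDtMs = mdt, times = tms, n = length(binnedList))
}

#' Pre-decision slope of a time series
#'
#' Ordinary least-squares slope of potential (microvolts) on time (seconds)
#' over samples with window start <= t <= window end (closed interval).
#' Adding a constant to the series leaves the slope unchanged, so the
#' estimate is baseline independent.
#'
#' @param series numeric vector (one time course)
#' @param times time axis in ms
#' @param windowMs c(start, end) in ms
#' @return slope in microvolts/second (NA if fewer than 3 samples fall in the
#'   window)
#' @export
erpSlope <- function(series, times, windowMs) {
  idx <- which(times >= windowMs[1] & times <= windowMs[2])
  if (length(idx) < 3) return(NA_real_)
  tSec <- times[idx] / 1000
  y <- series[idx]
  tc <- tSec - mean(tSec)
  sum(tc * (y - mean(y))) / sum(tc^2)
}

#' Slope profile across decision-time bins
#'
#' Computes the pre-decision slope per bin and the Pearson correlation
#' between bin number (1..n) and slope. A degenerate profile (zero slope
#' variance, or a missing slope) propagates as NA with a warning.
#'
#' @param binned \linkS4class{BinnedErp} (response-aligned)
#' @param windowMs slope window (ms, default the a priori c(-500, -50))
#' @return \linkS4class{SlopeResult}
#' @export
slopeBinProfile <- function(binned, windowMs = c(-500, -50)) {
  stopifnot(is(binned, "BinnedErp"))
  if (binned@alignment != "response")
    stop("slope profiles are defined on response-aligned binned ERPs")
  nb <- nrow(binned@binMeans)
  slopes <- vapply(seq_len(nb), function(b)
    erpSlope(binned@binMeans[b, ], binned@times, windowMs), numeric(1))
  r <- if (anyNA(slopes)) {
    warning("missing slope in at least one bin; correlation undefined")
    NA_real_
  } else if (stats::sd(slopes) == 0) {
    warning("slopes identical across bins; correlation undefined")
    NA_real_
  } else pearsonR(seq_len(nb), slopes)
  new("SlopeResult", participantId = binned@participantId,
      windowMs = windowMs, slopesPerBin = slopes, rSlopeVsBin = r)
}

#' Slope-window sweep
#'
#' For every (start, end) pair on the sweep grids with end - start >=
#' \code{minWindowMs}, computes the per-participant correlation between bin
#' number and slope and the group-level one-sample t across participants.
#' Invalid cells are NA.
#'
#' @param binnedList list of response-aligned \linkS4class{BinnedErp}
#'   (quartile binning), one per participant
#' @param startsMs,endsMs window-sweep grids (ms)
#' @param minWindowMs minimum window length (ms)
#' @param aprioriWindowMs the a priori window, marked in the result
#' @return list with \code{tMatrix} (starts x ends, dimnames in ms),
#'   \code{startsMs}, \code{endsMs} and \code{apriori} (start, end)
#' @export
windowSweep <- function(binnedList, startsMs = seq(-1000, -200, by = 50),
                        endsMs = seq(-400, 0, by = 50), minWindowMs = 100,
                        aprioriWindowMs = c(-500, -50)) {
  stopifnot(length(binnedList) >= 2)
  tm <- matrix(NA_real_, length(startsMs), length(endsMs),
               dimnames = list(start_ms = startsMs, end_ms = endsMs))
  anyValid <- FALSE
  for (i in seq_along(startsMs)) for (j in seq_along(endsMs)) {
    if (endsMs[j] - startsMs[i] < minWindowMs) next
    rs <- vapply(binnedList, function(b)
      suppressWarnings(
        slopeBinProfile(b, c(startsMs[i], endsMs[j]))@rSlopeVsBin),
      numeric(1))
    if (anyNA(rs)) next
    anyValid <- TRUE
    tm[i, j] <- oneSampleT(rs)@statistic
  }
  if (!anyValid) stop("sweep grids admit no valid window")
  list(tMatrix = tm, startsMs = startsMs, endsMs = endsMs,
       apriori = aprioriWindowMs)
}

#' Time-window mean per channel (topography values)
#'
#' Averages each channel over a time window within trials, then over trials,
#' then across participants. No spatial interpolation is performed; values
#' are returned per channel label for external rendering.
#'
#' @param epochsList list of \linkS4class{EpochSet} (one per participant) with
#'   identical montages
#' @param windowMs c(start, end) in ms; must lie inside the epoch window
#' @return named numeric vector (microvolts per channel)
#' @export
topographyValues <- function(epochsList, windowMs) {
  if (is(epochsList, "EpochSet")) epochsList <- list(epochsList)
  tms <- epochsList[[1]]@times
  if (windowMs[1] < min(tms) || windowMs[2] > max(tms))
    stop(sprintf("window [%g, %g] ms lies outside the epoch window [%g, %g]",
                 windowMs[1], windowMs[2], min(tms), max(tms)))
  per <- vapply(epochsList, function(ep) {
    idx <- which(ep@times >= windowMs[1] & ep@times <= windowMs[2])
    colMeans(apply(ep@data[, , idx, drop = FALSE], c(1, 2), mean))
  }, numeric(length(epochsList[[1]]@channelLabels)))
  out <- rowMeans(as.matrix(per))
  names(out) <- epochsList[[1]]@channelLabels
  out
}
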
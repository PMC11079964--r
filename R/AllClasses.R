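#' @import methods
NULL

#' Simulation configuration for synthetic CPP cohorts
#'
#' Parameters of the generative model: an accumulation-to-bound
#' centro-parietal component that ramps linearly from a post-cue onset to a
#' fixed bound amplitude at the moment of response (so that the ramp slope is
#' inversely proportional to decision time), superimposed on 1/f ("pink")
#' noise, white noise, alpha-band oscillation, a common-mode reference drift,
#' and a cue-evoked transient. Decision times follow a shifted lognormal law.
#'
#' @slot nParticipants number of participants in a cohort
#' @slot nTrials trials per participant
#' @slot sfreqHz sampling rate of the continuous recording (Hz)
#' @slot dtShiftMs,dtLognormMu,dtLognormSigma shifted-lognormal decision-time
#'   parameters: DT = shift + exp(N(mu, sigma)) in ms
#' @slot onsetMs accumulation onset relative to cue (ms)
#' @slot boundUv named numeric, CPP bound amplitude per condition (microvolts)
#' @slot decayTauMs exponential decay constant of the component after response
#' @slot topoCenter,topoWidth 2-D Gaussian spatial profile over scalp positions
#' @slot pinkRmsUv,whiteRmsUv,alphaRmsUv,commonModeRmsUv noise RMS amplitudes
#' @slot cueEvokedAmpUv amplitude of the cue-evoked transient
#' @slot pCondition probability that a trial requires item selection
#'   (the "selection_required" condition)
#' @slot errorKappa named numeric, von Mises concentration of the reproduction
#'   error distribution per condition (orientation space, 180 degrees)
#' @slot dtConditionShiftMs named numeric, additional decision-time shift per
#'   condition (ms)
#' @slot onsetJitterSdMs optional trial-wise jitter (SD, ms) of the
#'   accumulation onset; 0 disables it
#' @slot montage "full" (61 scalp channels + 2 mastoids) or "compact"
#'   (12 channels including the Pz cluster and mastoids)
#' @slot seed integer seed from which per-participant sub-seeds are derived
#' @export
setClass("SimConfig",
  representation(
    nParticipants = "numeric", nTrials = "numeric", sfreqHz = "numeric",
    dtShiftMs = "numeric", dtLognormMu = "numeric", dtLognormSigma = "numeric",
    onsetMs = "numeric", boundUv = "numeric", decayTauMs = "numeric",
    topoCenter = "numeric", topoWidth = "numeric",
    pinkRmsUv = "numeric", whiteRmsUv = "numeric", alphaRmsUv = "numeric",
    commonModeRmsUv = "numeric", cueEvokedAmpUv = "numeric",
    pCondition = "numeric", errorKappa = "numeric",
    dtConditionShiftMs = "numeric", onsetJitterSdMs = "numeric",
    montage = "character", seed = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  nonneg <- c(
    nTrials = object@nTrials, sfreqHz = object@sfreqHz,
    dtShiftMs = object@dtShiftMs, decayTauMs = object@decayTauMs,
    pinkRmsUv = object@pinkRmsUv, whiteRmsUv = object@whiteRmsUv,
    alphaRmsUv = object@alphaRmsUv, commonModeRmsUv = object@commonModeRmsUv,
    cueEvokedAmpUv = object@cueEvokedAmpUv,
    onsetJitterSdMs = object@onsetJitterSdMs,
    nParticipants = object@nParticipants
  )
  bad <- names(nonneg)[!is.finite(nonneg) | nonneg < 0]
  if (length(bad))
    msg <- c(msg, paste0("negative or non-finite: ", paste(bad, collapse = ", ")))
  if (any(object@boundUv < 0)) msg <- c(msg, "boundUv must be >= 0")
  if (is.null(names(object@boundUv)) || any(!nzchar(names(object@boundUv))))
    msg <- c(msg, "boundUv must be a named vector (condition -> amplitude)")
  if (object@pCondition < 0 || object@pCondition > 1)
    msg <- c(msg, "pCondition must lie in [0, 1]")
  if (!identical(sort(names(object@boundUv)), sort(names(object@errorKappa))))
    msg <- c(msg, "errorKappa must carry the same condition names as boundUv")
  if (!identical(sort(names(object@boundUv)), sort(names(object@dtConditionShiftMs))))
    msg <- c(msg, "dtConditionShiftMs must carry the same condition names as boundUv")
  typicalDt <- object@dtShiftMs + exp(object@dtLognormMu)
  if (object@onsetMs >= typicalDt)
    msg <- c(msg, "onsetMs must be below the typical decision time")
  if (length(object@topoCenter) != 2L)
    msg <- c(msg, "topoCenter must have length 2")
  if (!object@montage %in% c("full", "compact"))
    msg <- c(msg, "montage must be 'full' or 'compact'")
  if (length(msg)) msg else TRUE
})

#' Continuous multichannel recording for one participant
#'
#' @slot data channels x samples matrix, microvolts
#' @slot sfreqHz sampling rate (Hz)
#' @slot channelLabels 10-10 channel names (rows of \code{data})
#' @slot channelPositions channels x 2 matrix of 2-D scalp coordinates
#' @slot events one row per trial: trial_id, cue_sample, response_sample,
#'   condition, item_side, response_hand, decision_time_ms,
#'   reproduction_error_deg
#' @slot participantId identifier
#' @export
setClass("RawSession",
  representation(
    data = "matrix", sfreqHz = "numeric", channelLabels = "character",
    channelPositions = "matrix", events = "data.frame",
    participantId = "character"
  )
)

.EVENT_COLS <- c("trial_id", "cue_sample", "response_sample", "condition",
                 "item_side", "response_hand", "decision_time_ms",
                 "reproduction_error_deg")

setValidity("RawSession", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "channel count of data and channelLabels disagree")
  if (nrow(object@channelPositions) != length(object@channelLabels))
    msg <- c(msg, "channelPositions rows must match channelLabels")
  miss <- setdiff(.EVENT_COLS, names(object@events))
  if (length(miss)) {
    msg <- c(msg, paste0("events lacks columns: ", paste(miss, collapse = ", ")))
  } else if (nrow(object@events)) {
    ev <- object@events
    if (any(ev$response_sample <= ev$cue_sample))
      msg <- c(msg, "response_sample must exceed cue_sample for every trial")
    dt <- (ev$response_sample - ev$cue_sample) / object@sfreqHz * 1000
    if (any(abs(dt - ev$decision_time_ms) > 1e-9))
      msg <- c(msg, "decision_time_ms inconsistent with cue/response samples")
    if (is.unsorted(ev$cue_sample))
      msg <- c(msg, "events must be sorted by cue_sample")
    if (nrow(ev) > 1 &&
        any(ev$cue_sample[-1] <= ev$response_sample[-nrow(ev)]))
      msg <- c(msg, "trials overlap (cue before previous response)")
  }
  if (length(msg)) msg else TRUE
})

#' Epoched trials for one participant
#'
#' @slot data trials x channels x time array, microvolts
#' @slot sfreqHz sampling rate (Hz)
#' @slot alignment "cue" or "response"
#' @slot times time axis in ms relative to the alignment event
#' @slot channelLabels,channelPositions channel info
#' @slot trialInfo per-trial metadata (same columns as RawSession events)
#' @slot participantId identifier
#' @export
setClass("EpochSet",
  representation(
    data = "array", sfreqHz = "numeric", alignment = "character",
    times = "numeric", channelLabels = "character",
    channelPositions = "matrix", trialInfo = "data.frame",
    participantId = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be trials x channels x time")
  else {
    if (d[2] != length(object@channelLabels))
      msg <- c(msg, "channel dimension must match channelLabels")
    if (d[3] != length(object@times))
      msg <- c(msg, "time dimension must match times")
    if (d[1] != nrow(object@trialInfo))
      msg <- c(msg, "trial dimension must match trialInfo rows")
  }
  if (!object@alignment %in% c("cue", "response"))
    msg <- c(msg, "alignment must be 'cue' or 'response'")
  if (length(msg)) msg else TRUE
})

#' Decision-time-binned ERP for one participant
#'
#' @slot participantId identifier
#' @slot binMeans bins x time matrix of bin-average potentials (microvolts)
#' @slot binMeanDtMs per-bin mean decision time (ms)
#' @slot binCounts trials per bin
#' @slot alignment "cue" or "response"
#' @slot times time axis (ms)
#' @export
setClass("BinnedErp",
  representation(
    participantId = "character", binMeans = "matrix", binMeanDtMs = "numeric",
    binCounts = "numeric", alignment = "character", times = "numeric"
  )
)

setValidity("BinnedErp", function(object) {
  msg <- character()
  nb <- nrow(object@binMeans)
  if (length(object@binMeanDtMs) != nb || length(object@binCounts) != nb)
    msg <- c(msg, "binMeanDtMs and binCounts must have one entry per bin")
  if (ncol(object@binMeans) != length(object@times))
    msg <- c(msg, "binMeans columns must match times")
  if (nb > 1 && any(diff(object@binMeanDtMs) < -1e-9))
    msg <- c(msg, "binMeanDtMs must be non-decreasing with bin index")
  if (any(object@binCounts < 1))
    msg <- c(msg, "every bin must contain at least one trial")
  if (length(msg)) msg else TRUE
})

#' Per-participant pre-decision slope profile across decision-time bins
#'
#' @slot participantId identifier
#' @slot windowMs slope window (ms, relative to response)
#' @slot slopesPerBin OLS slope per bin (microvolts per second)
#' @slot rSlopeVsBin Pearson correlation between bin number and slope
#'   (NA when degenerate)
#' @export
setClass("SlopeResult",
  representation(
    participantId = "character", windowMs = "numeric",
    slopesPerBin = "numeric", rSlopeVsBin = "numeric"
  )
)

setValidity("SlopeResult", function(object) {
  msg <- character()
  r <- object@rSlopeVsBin
  if (length(r) != 1L) msg <- c(msg, "rSlopeVsBin must be a scalar")
  else if (!is.na(r) && (r < -1 - 1e-12 || r > 1 + 1e-12))
    msg <- c(msg, "rSlopeVsBin must lie in [-1, 1]")
  if (length(object@windowMs) != 2L)
    msg <- c(msg, "windowMs must be c(start, end)")
  if (length(msg)) msg else TRUE
})

#' Second-level (group) statistic bundle
#'
#' One-sample or paired t statistic with two-sided p, Cohen's d (= t / sqrt(n)
#' for these designs), and the mean +/- SEM of the tested values.
#'
#' @slot statistic t value
#' @slot df degrees of freedom (n - 1)
#' @slot p two-sided p value (NA when t is infinite)
#' @slot cohenD standardized effect size t / sqrt(n)
#' @slot mean,sem mean and standard error of the tested values
#' @slot n number of participants
#' @export
setClass("GroupStatResult",
  representation(
    statistic = "numeric", df = "numeric", p = "numeric", cohenD = "numeric",
    mean = "numeric", sem = "numeric", n = "numeric"
  )
)

setValidity("GroupStatResult", function(object) {
  msg <- character()
  if (object@df != object@n - 1) msg <- c(msg, "df must equal n - 1")
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    msg <- c(msg, "p must lie in [0, 1]")
  if (is.finite(object@statistic) &&
      abs(object@cohenD - object@statistic / sqrt(object@n)) > 1e-9)
    msg <- c(msg, "cohenD must equal t / sqrt(n)")
  if (length(msg)) msg else TRUE
})

#' Cluster-based permutation test result
#'
#' @slot tSeries observed per-timepoint t values
#' @slot times time axis (ms)
#' @slot clusters data.frame with one row per suprathreshold cluster:
#'   start_ms, end_ms, mass (sum of t), p_perm
#' @slot threshold cluster-forming |t| threshold
#' @slot clusterAlpha alpha used to derive the threshold
#' @slot nPermutations permutations evaluated (pattern count in exhaustive mode)
#' @slot seed RNG seed (NA in exhaustive mode)
#' @slot tail "two", "pos" or "neg"
#' @slot exhaustive TRUE when the null was enumerated exactly
#' @slot design "one_sample" or "paired"
#' @export
setClass("ClusterTestResult",
  representation(
    tSeries = "numeric", times = "numeric", clusters = "data.frame",
    threshold = "numeric", clusterAlpha = "numeric", nPermutations = "numeric",
    seed = "numeric", tail = "character", exhaustive = "logical",
    design = "character"
  )
)

setValidity("ClusterTestResult", function(object) {
  msg <- character()
  if (length(object@tSeries) != length(object@times))
    msg <- c(msg, "tSeries and times must have equal length")
  cl <- object@clusters
  if (nrow(cl)) {
    if (any(cl$p_perm < 1 / (object@nPermutations + !object@exhaustive) - 1e-12))
      msg <- c(msg, "cluster p below the attainable minimum")
    if (nrow(cl) > 1 && any(diff(cl$start_ms) <= 0))
      msg <- c(msg, "clusters must be ordered and non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' Preprocessing configuration
#'
#' @slot refChannels reference channels (mastoids)
#' @slot targetSfreqHz target rate after downsampling (Hz)
#' @slot cueWindowMs,respWindowMs epoch windows (ms)
#' @slot cueBaselineMs,respBaselineMs baseline windows (ms)
#' @slot smoothSigmaMs Gaussian smoothing SD (ms)
#' @slot dtBoundsMs decision-time exclusion bounds (ms, inclusive)
#' @slot varianceZThreshold robust z threshold for trial variance flagging
#' @export
setClass("PreprocessConfig",
  representation(
    refChannels = "character", targetSfreqHz = "numeric",
    cueWindowMs = "numeric", respWindowMs = "numeric",
    cueBaselineMs = "numeric", respBaselineMs = "numeric",
    smoothSigmaMs = "numeric", dtBoundsMs = "numeric",
    varianceZThreshold = "numeric"
  )
)

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  inside <- function(b, w) b[1] >= w[1] && b[2] <= w[2] && b[1] < b[2]
  if (!inside(object@cueBaselineMs, object@cueWindowMs))
    msg <- c(msg, "cue baseline must lie within the cue epoch window")
  if (!inside(object@respBaselineMs, object@respWindowMs))
    msg <- c(msg, "response baseline must lie within the response epoch window")
  if (object@dtBoundsMs[1] >= object@dtBoundsMs[2])
    msg <- c(msg, "dtBoundsMs must be increasing")
  if (object@smoothSigmaMs <= 0) msg <- c(msg, "smoothSigmaMs must be > 0")
  if (length(msg)) msg else TRUE
})

#' CPP analysis configuration
#'
#' @slot clusterChannels the a priori electrode cluster centred on Pz
#' @slot nBinsFine,nBinsCoarse decision-time bin counts (ERP image / quartiles)
#' @slot slopeWindowMs a priori slope window relative to response (ms)
#' @slot sweepStartsMs,sweepEndsMs window-sweep grids (ms)
#' @slot minWindowMs minimum sweep window length (ms)
#' @slot topoWindowsMs named list of topography windows (cue, resp, contrast)
#' @export
setClass("AnalysisConfig",
  representation(
    clusterChannels = "character", nBinsFine = "numeric",
    nBinsCoarse = "numeric", slopeWindowMs = "numeric",
    sweepStartsMs = "numeric", sweepEndsMs = "numeric", minWindowMs = "numeric",
    topoWindowsMs = "list"
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@slopeWindowMs[2] > 0)
    msg <- c(msg, "slope window must end at or before the response (end <= 0)")
  if (object@slopeWindowMs[1] >= object@slopeWindowMs[2])
    msg <- c(msg, "slope window must be increasing")
  ok <- outer(object@sweepStartsMs, object@sweepEndsMs,
              function(s, e) e - s >= object@minWindowMs)
  if (!any(ok)) msg <- c(msg, "sweep grids admit no valid window")
  if (length(msg)) msg else TRUE
})
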
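#' Mean absolute reproduction error of a von Mises orientation error model
#'
#' Reproduction errors are modelled on the doubled orientation angle: the
#' report deviates from the target by theta/2 where theta ~ von Mises(0,
#' kappa) on (-pi, pi]. This returns E|theta|/2 in degrees.
#'
#' @param kappa concentration parameter (> 0)
#' @return expected absolute error in degrees (orientation space, max 90)
#' @export
meanAbsErrorDeg <- function(kappa) {
  stopifnot(kappa > 0)
  f <- function(th) th * exp(kappa * cos(th))
  num <- stats::integrate(f, 0, pi, rel.tol = 1e-10)$value
  den <- pi * besselI(kappa, 0)
  (num / den) * (90 / pi)
}

#' Solve the von Mises concentration for a target mean absolute error
#'
#' @param errorDeg target mean absolute reproduction error (degrees)
#' @return kappa such that \code{meanAbsErrorDeg(kappa) == errorDeg}
#' @export
kappaForMeanError <- function(errorDeg) {
  stopifnot(errorDeg > 0, errorDeg < 45)
  stats::uniroot(function(k) meanAbsErrorDeg(k) - errorDeg,
                 lower = 1e-3, upper = 500, tol = 1e-9)$root
}

#' Construct a simulation configuration
#'
#' Defaults emulate the single-condition study: 25 participants, ~605 trials,
#' 1000 Hz, shifted-lognormal decision times with cohort mean
#' 200 + exp(6.17 + 0.55^2/2) = 756.6 ms, a 10 microvolt bound reached at
#' response over the centro-parietal scalp, and reproduction errors
#' calibrated to a 14.14 degree mean absolute error.
#'
#' @param nParticipants,nTrials cohort size and trials per participant
#' @param sfreqHz sampling rate (Hz)
#' @param dtShiftMs,dtLognormMu,dtLognormSigma decision-time law parameters
#' @param onsetMs accumulation onset after cue (ms)
#' @param boundUv named amplitude-at-bound per condition (microvolts)
#' @param decayTauMs post-response exponential decay constant (ms)
#' @param topoCenter,topoWidth spatial Gaussian of the component
#' @param pinkRmsUv,whiteRmsUv,alphaRmsUv,commonModeRmsUv noise RMS (microvolts)
#' @param cueEvokedAmpUv cue-evoked transient amplitude (microvolts)
#' @param pCondition probability of the "selection_required" condition
#' @param errorKappa named von Mises concentration per condition; defaults are
#'   solved from \code{targetErrorDeg}
#' @param targetErrorDeg mean absolute reproduction error used to derive
#'   \code{errorKappa} when the latter is not given (degrees, recycled over
#'   conditions)
#' @param dtConditionShiftMs named additional decision-time shift per condition
#' @param onsetJitterSdMs trial-wise onset jitter SD (ms); default 0 (fixed)
#' @param montage "full" or "compact" (see \code{\link{standardMontage}})
#' @param seed RNG seed
#' @return \linkS4class{SimConfig}
#' @export
#' @examples
#' cfg <- simConfig(nParticipants = 2, nTrials = 20)
#' expectedSlope(cfg, "selection_required", 650)  # 20 uV/s
simConfig <- function(nParticipants = 25, nTrials = 605, sfreqHz = 1000,
                      dtShiftMs = 200, dtLognormMu = 6.17,
                      dtLognormSigma = 0.55, onsetMs = 50,
                      boundUv = c(selection_required = 10), decayTauMs = 300,
                      topoCenter = c(0, -0.335), topoWidth = 0.3,
                      pinkRmsUv = 10, whiteRmsUv = 5, alphaRmsUv = 4,
                      commonModeRmsUv = 2, cueEvokedAmpUv = 3, pCondition = 1,
                      errorKappa = NULL, targetErrorDeg = 14.14,
                      dtConditionShiftMs = NULL, onsetJitterSdMs = 0,
                      montage = "full", seed = 20240327) {
  conds <- names(boundUv)
  if (is.null(errorKappa)) {
    errorKappa <- vapply(rep_len(targetErrorDeg, length(conds)),
                         kappaForMeanError, numeric(1))
    names(errorKappa) <- conds
  }
  if (is.null(dtConditionShiftMs))
    dtConditionShiftMs <- stats::setNames(rep(0, length(conds)), conds)
  new("SimConfig",
      nParticipants = nParticipants, nTrials = nTrials, sfreqHz = sfreqHz,
      dtShiftMs = dtShiftMs, dtLognormMu = dtLognormMu,
      dtLognormSigma = dtLognormSigma, onsetMs = onsetMs, boundUv = boundUv,
      decayTauMs = decayTauMs, topoCenter = topoCenter, topoWidth = topoWidth,
      pinkRmsUv = pinkRmsUv, whiteRmsUv = whiteRmsUv, alphaRmsUv = alphaRmsUv,
      commonModeRmsUv = commonModeRmsUv, cueEvokedAmpUv = cueEvokedAmpUv,
      pCondition = pCondition, errorKappa = errorKappa,
      dtConditionShiftMs = dtConditionShiftMs,
      onsetJitterSdMs = onsetJitterSdMs, montage = montage, seed = seed)
}

#' Two-condition (memory-load contrast) simulation configuration
#'
#' Emulates the load manipulation: on 20% of trials the relevant memory item
#' still has to be selected after the cue ("selection_required"), on the rest
#' it was preselected at encoding ("preselected"). The selection-required
#' condition carries a larger CPP bound and a +250 ms decision-time shift;
#' the lognormal location is lowered so the preselected condition averages
#' ~627.6 ms and the selection-required condition ~877.6 ms. Reproduction
#' errors are calibrated to 13.0 vs 11.1 degrees.
#'
#' @param ... overrides passed on to \code{\link{simConfig}}
#' @return \linkS4class{SimConfig}
#' @export
simConfigLoadContrast <- function(...) {
  args <- list(
    nTrials = 705, dtLognormMu = 5.9068, pCondition = 0.2,
    boundUv = c(selection_required = 12, preselected = 8),
    dtConditionShiftMs = c(selection_required = 250, preselected = 0),
    targetErrorDeg = c(selection_required = 13.0, preselected = 11.1),
    montage = "compact", seed = 20210427
  )
  over <- list(...)
  args[names(over)] <- over
  if (is.null(over$errorKappa) && !is.null(args$targetErrorDeg)) {
    t <- args$targetErrorDeg
    args$targetErrorDeg <- unname(t[names(args$boundUv)])
  }
  do.call(simConfig, args)
}

#' Construct a preprocessing configuration
#'
#' Defaults follow the analysis chain: mastoid-average rereference,
#' downsampling to 250 Hz, cue epochs -250..+1500 ms baselined on the 250 ms
#' before the cue, response epochs -1500..+500 ms baselined on the 250 ms
#' after response initiation, 30 ms Gaussian smoothing, and exclusion of
#' trials with decision times below 200 or above 2000 ms.
#'
#' @param refChannels,targetSfreqHz,cueWindowMs,respWindowMs,cueBaselineMs,respBaselineMs,smoothSigmaMs,dtBoundsMs,varianceZThreshold see slots of \linkS4class{PreprocessConfig}
#' @return \linkS4class{PreprocessConfig}
#' @export
preprocessConfig <- function(refChannels = c("M1", "M2"), targetSfreqHz = 250,
                             cueWindowMs = c(-250, 1500),
                             respWindowMs = c(-1500, 500),
                             cueBaselineMs = c(-250, 0),
                             respBaselineMs = c(0, 250), smoothSigmaMs = 30,
                             dtBoundsMs = c(200, 2000),
                             varianceZThreshold = 3.5) {
  new("PreprocessConfig", refChannels = refChannels,
      targetSfreqHz = targetSfreqHz, cueWindowMs = cueWindowMs,
      respWindowMs = respWindowMs, cueBaselineMs = cueBaselineMs,
      respBaselineMs = respBaselineMs, smoothSigmaMs = smoothSigmaMs,
      dtBoundsMs = dtBoundsMs, varianceZThreshold = varianceZThreshold)
}

#' Construct an analysis configuration
#'
#' @param clusterChannels the a priori Pz-centred electrode cluster
#' @param nBinsFine,nBinsCoarse decision-time bin counts
#' @param slopeWindowMs a priori pre-decision slope window (ms)
#' @param sweepStartsMs,sweepEndsMs,minWindowMs window-sweep grids (ms)
#' @param topoWindowsMs topography averaging windows (ms)
#' @return \linkS4class{AnalysisConfig}
#' @export
analysisConfig <- function(clusterChannels = c("Pz", "CPz", "POz", "P1", "P2"),
                           nBinsFine = 100, nBinsCoarse = 4,
                           slopeWindowMs = c(-500, -50),
                           sweepStartsMs = seq(-1000, -200, by = 50),
                           sweepEndsMs = seq(-400, 0, by = 50),
                           minWindowMs = 100,
                           topoWindowsMs = list(cue = c(300, 600),
                                                resp = c(-300, 0),
                                                contrast = c(-600, -300))) {
  new("AnalysisConfig", clusterChannels = clusterChannels,
      nBinsFine = nBinsFine, nBinsCoarse = nBinsCoarse,
      slopeWindowMs = slopeWindowMs, sweepStartsMs = sweepStartsMs,
      sweepEndsMs = sweepEndsMs, minWindowMs = minWindowMs,
      topoWindowsMs = topoWindowsMs)
}
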
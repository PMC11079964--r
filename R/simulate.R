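## Synthetic accumulation-to-bound EEG generator.
##
## Per trial the noiseless component at channel c is
##   w_c * A_cond * max(0, (t - t0) / (DT - t0))   for t0 <= t <= DT after cue
## and decays as exp(-(t - DT) / tau) after the response, so the ramp reaches
## the bound A_cond exactly at the response sample and its slope is
## A_cond / (DT - t0): steeper for faster decisions.

# Run expr with a private RNG state restored afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Synthesize 1/f ("pink") noise
#'
#' Frequency-domain synthesis: complex Gaussian spectral coefficients scaled
#' by f^(-1/2) (power spectral density proportional to 1/f, i.e. slope -1 on
#' log-log axes), flat below \code{fMin} to keep the variance finite, inverse
#' transformed and rescaled to the requested RMS.
#'
#' @param n number of samples
#' @param sfreqHz sampling rate (Hz)
#' @param rms target standard deviation
#' @param fMin corner frequency below which the spectrum is flat (Hz)
#' @return numeric vector of length \code{n}
#' @export
pinkNoise <- function(n, sfreqHz, rms = 1, fMin = 0.05) {
  if (rms == 0) return(numeric(n))
  nfft <- stats::nextn(n, c(2, 3))
  if (nfft %% 2 != 0) nfft <- stats::nextn(nfft + 1, c(2, 3))
  nhalf <- nfft / 2
  f <- seq_len(nhalf - 1) * sfreqHz / nfft        # positive freqs, no DC/Nyq
  amp <- 1 / sqrt(pmax(f, fMin))
  pos <- complex(real = stats::rnorm(nhalf - 1),
                 imaginary = stats::rnorm(nhalf - 1)) * amp
  spec <- c(0, pos, complex(real = stats::rnorm(1)) * 1 / sqrt(sfreqHz / 2),
            Conj(rev(pos)))
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  x <- x - mean(x)
  x / stats::sd(x) * rms
}

# Best-Fisher rejection sampler for von Mises(0, kappa) on (-pi, pi].
.rvonmises <- function(n, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5)[ok] * acos(pmin(1, pmax(-1, f[ok])))
    take <- min(length(theta), n - got)
    if (take > 0) out[got + seq_len(take)] <- theta[seq_len(take)]
    got <- got + take
  }
  out
}

# Draw shifted-lognormal decision times; redraw values at or below the
# accumulation onset (bounded retries).
.drawDecisionTimes <- function(n, shift, mu, sigma, onsetMs, maxRetries = 100) {
  shift <- rep_len(shift, n)
  dt <- shift + stats::rlnorm(n, mu, sigma)
  tries <- 0L
  while (any(bad <- dt <= onsetMs)) {
    tries <- tries + 1L
    if (tries > maxRetries)
      stop(sprintf(
        "decision-time redraw failed after %d retries: %d draws <= onset (%g ms); ",
        maxRetries, sum(bad), onsetMs),
        "check dtShiftMs/dtLognormMu against onsetMs")
    dt[bad] <- shift[bad] + stats::rlnorm(sum(bad), mu, sigma)
  }
  dt
}

#' Simulate one participant's continuous EEG session
#'
#' Generates a continuous multichannel recording containing one
#' accumulation-to-bound CPP component per trial (linear ramp from onset to a
#' condition-specific bound at the response sample, exponential decay after),
#' a cue-evoked transient, and pink / white / alpha / common-mode noise.
#' Decision times are drawn from the shifted-lognormal law and are NOT
#' truncated to the analysis bounds, so the decision-time exclusion filter
#' downstream has work to do.
#'
#' @param config \linkS4class{SimConfig}
#' @param participantIdent identifier stored in the session
#' @param seed integer seed for this participant
#' @return \linkS4class{RawSession}
#' @seealso \code{\link{simulateCohort}}, \code{\link{expectedSlope}}
#' @export
simulateParticipant <- function(config, participantIdent, seed) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  .withSeed(seed, .simulateParticipantImpl(config, participantIdent))
}

.simulateParticipantImpl <- function(config, participantIdent) {
  fs <- config@sfreqHz
  ms2smp <- function(ms) round(ms * fs / 1000)
  mont <- standardMontage(config@montage)
  nch <- nrow(mont)
  pos <- as.matrix(mont[, c("x", "y")])
  rownames(pos) <- mont$label
  w <- spatialWeights(pos, config@topoCenter, config@topoWidth)
  wCue <- spatialWeights(pos, c(0, -0.75), 0.45)  # occipital visual transient
  w[mont$label %in% c("M1", "M2")] <- 0
  wCue[mont$label %in% c("M1", "M2")] <- 0

  n <- config@nTrials
  conds <- names(config@boundUv)
  cond <- if (length(conds) == 1L) rep(conds, n) else
    ifelse(stats::runif(n) < config@pCondition, "selection_required",
           setdiff(conds, "selection_required")[1])
  dt <- .drawDecisionTimes(n, config@dtShiftMs + config@dtConditionShiftMs[cond],
                           config@dtLognormMu, config@dtLognormSigma,
                           config@onsetMs)

  # trial layout: 2 s lead-in, cue->response, 1.6 s gap to the next cue
  gap <- ms2smp(1600)
  cueS <- integer(n); respS <- integer(n)
  at <- ms2smp(2000)
  for (i in seq_len(n)) {
    cueS[i] <- at
    respS[i] <- at + max(1L, ms2smp(dt[i]))
    at <- respS[i] + gap
  }
  nS <- at + ms2smp(2000)
  dtMs <- (respS - cueS) / fs * 1000          # sample-exact decision times

  data <- matrix(0, nch, nS)

  # noise ------------------------------------------------------------------
  if (config@pinkRmsUv > 0)
    for (c in seq_len(nch))
      data[c, ] <- data[c, ] + pinkNoise(nS, fs, config@pinkRmsUv)
  if (config@whiteRmsUv > 0)
    data <- data + matrix(stats::rnorm(nch * nS, sd = config@whiteRmsUv),
                          nch, nS)
  tAx <- seq_len(nS) / fs
  if (config@alphaRmsUv > 0) {
    # sin(wt + ph) expanded so only two long waveforms are evaluated
    ph <- stats::runif(nch, 0, 2 * pi)
    base <- rbind(sin(2 * pi * 10 * tAx), cos(2 * pi * 10 * tAx))
    data <- data + config@alphaRmsUv * sqrt(2) *
      (cbind(cos(ph), sin(ph)) %*% base)
  }
  if (config@commonModeRmsUv > 0) {
    drift <- config@commonModeRmsUv * sqrt(2) *
      sin(2 * pi * 0.3 * tAx + stats::runif(1, 0, 2 * pi))
    data <- data + matrix(drift, nch, nS, byrow = TRUE)
  }

  # deterministic components -----------------------------------------------
  onsJit <- if (config@onsetJitterSdMs > 0)
    stats::rnorm(n, 0, config@onsetJitterSdMs) else numeric(n)
  nDecay <- ms2smp(5 * config@decayTauMs)
  cueBumpHalf <- ms2smp(120)
  bumpIdx <- -cueBumpHalf:cueBumpHalf
  bump <- exp(-(bumpIdx / ms2smp(40))^2 / 2)
  for (i in seq_len(n)) {
    A <- config@boundUv[[cond[i]]]
    t0 <- config@onsetMs + onsJit[i]
    accLen <- dtMs[i] - t0
    if (accLen > 0 && A != 0) {
      onsS <- max(1L, cueS[i] + ms2smp(t0))
      idx <- onsS:respS[i]
      ramp <- A * ((idx - cueS[i]) / fs * 1000 - t0) / accLen
      ramp[ramp < 0] <- 0
      dec <- A * exp(-(seq_len(nDecay) / fs * 1000) / config@decayTauMs)
      prof <- c(ramp, dec)
      span <- onsS:min(nS, respS[i] + nDecay)
      data[, span] <- data[, span] + outer(w, prof[seq_along(span)])
    }
    if (config@cueEvokedAmpUv != 0) {
      span <- cueS[i] + ms2smp(60) + bumpIdx
      keep <- span >= 1 & span <= nS
      data[, span[keep]] <- data[, span[keep]] +
        outer(wCue, config@cueEvokedAmpUv * bump[keep])
    }
  }

  err <- numeric(n)
  for (cc in conds) {
    sel <- cond == cc
    err[sel] <- abs(.rvonmises(sum(sel), config@errorKappa[[cc]])) * (90 / pi)
  }
  ev <- data.frame(
    trial_id = seq_len(n), cue_sample = cueS, response_sample = respS,
    condition = cond,
    item_side = sample(c("left", "right"), n, replace = TRUE),
    response_hand = sample(c("left", "right"), n, replace = TRUE),
    decision_time_ms = dtMs, reproduction_error_deg = round(err, 4),
    stringsAsFactors = FALSE
  )
  new("RawSession", data = data, sfreqHz = fs, channelLabels = mont$label,
      channelPositions = pos, events = ev, participantId = participantIdent)
}

#' Simulate a cohort of participants
#'
#' Per-participant sub-seeds are derived deterministically from
#' \code{config@seed}, so identical configurations yield bit-identical
#' cohorts.
#'
#' @param config \linkS4class{SimConfig}
#' @return list of \linkS4class{RawSession}, one per participant
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  n <- as.integer(config@nParticipants)
  if (n == 0L) return(list())
  seeds <- .withSeed(config@seed, sample.int(.Machine$integer.max - 1L, n))
  out <- lapply(seq_len(n), function(i)
    simulateParticipant(config, sprintf("sub-%02d", i), seeds[i]))
  names(out) <- vapply(out, participantId, character(1))
  out
}

#' Ground-truth pre-decision ramp slope
#'
#' Analytic slope of the noiseless accumulation-to-bound component for a
#' given condition and decision time: bound / accumulation duration, in
#' microvolts per second. Used as the oracle in parameter-recovery tests.
#'
#' @param config \linkS4class{SimConfig}
#' @param condition condition label (a name of \code{config@boundUv})
#' @param dtMs decision time in ms (must exceed the accumulation onset)
#' @return slope in microvolts/second
#' @export
#' @examples
#' cfg <- simConfig()
#' expectedSlope(cfg, "selection_required", 650)   # 10 uV over 0.5 s = 20
expectedSlope <- function(config, condition, dtMs) {
  stopifnot(is(config, "SimConfig"))
  if (!condition %in% names(config@boundUv))
    stop("unknown condition: ", condition)
  if (any(dtMs <= config@onsetMs))
    stop(sprintf("dtMs must exceed the accumulation onset (%g ms)",
                 config@onsetMs))
  config@boundUv[[condition]] / ((dtMs - config@onsetMs) / 1000)
}
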
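# Small fixtures used across test files; everything is generated in code.

# Tiny, fast simulation configuration for unit tests.
tinyConfig <- function(...) {
  args <- list(nParticipants = 2, nTrials = 20, montage = "compact",
               seed = 101)
  over <- list(...)
  args[names(over)] <- over
  do.call(simConfig, args)
}

# Noiseless configuration: only the deterministic components remain.
noiselessConfig <- function(...) {
  tinyConfig(pinkRmsUv = 0, whiteRmsUv = 0, alphaRmsUv = 0,
             commonModeRmsUv = 0, cueEvokedAmpUv = 0, ...)
}

# Hand-built session: deterministic data matrix, explicit events.
toySession <- function(data, sfreqHz = 1000, events = NULL,
                       labels = NULL) {
  nch <- nrow(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nch))
  pos <- cbind(x = seq_len(nch) / nch, y = rep(0, nch))
  rownames(pos) <- labels
  if (is.null(events)) {
    events <- data.frame(
      trial_id = 1L, cue_sample = 10L, response_sample = 20L,
      condition = "a", item_side = "left", response_hand = "left",
      decision_time_ms = 10 / sfreqHz * 1000, reproduction_error_deg = 5)
  }
  new("RawSession", data = data, sfreqHz = sfreqHz, channelLabels = labels,
      channelPositions = pos, events = events, participantId = "toy")
}

# Hand-built epoch set: trials x channels x time array with a metadata table.
toyEpochs <- function(arr, times, alignment = "response", dtMs = NULL,
                      sfreqHz = 250, labels = NULL) {
  d <- dim(arr)
  if (is.null(labels)) labels <- paste0("ch", seq_len(d[2]))
  pos <- cbind(x = seq_len(d[2]) / d[2], y = rep(0, d[2]))
  rownames(pos) <- labels
  if (is.null(dtMs)) dtMs <- rep(600, d[1])
  ti <- data.frame(
    trial_id = seq_len(d[1]), cue_sample = seq_len(d[1]) * 1000L,
    response_sample = seq_len(d[1]) * 1000L + as.integer(dtMs * sfreqHz / 1000),
    condition = "a", item_side = "left", response_hand = "left",
    decision_time_ms = dtMs, reproduction_error_deg = 5)
  ti$decision_time_ms <-
    (ti$response_sample - ti$cue_sample) / sfreqHz * 1000
  new("EpochSet", data = arr, sfreqHz = sfreqHz, alignment = alignment,
      times = times, channelLabels = labels, channelPositions = pos,
      trialInfo = ti, participantId = "toy")
}
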
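## Structured text configuration (YAML). One file governs every stage:
##
##   simulation:  fields of simConfig() in snake_case
##   preprocess:  fields of preprocessConfig()
##   analysis:    fields of analysisConfig(); sweep grids are [from, to, by]
##   inference:   cluster_alpha, n_permutations, seed
##
## Unknown fields raise a schema error naming them.

.snake2camel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)

.checkFields <- function(given, allowed, section) {
  extra <- setdiff(names(given), allowed)
  if (length(extra))
    stop("config schema error in section '", section, "': unknown field(s) ",
         paste(extra, collapse = ", "))
}

.namedNum <- function(x) if (is.null(x)) NULL else unlist(x)

#' Read a pipeline configuration file
#'
#' Parses the YAML configuration and builds the stage configuration objects.
#' Missing sections or fields fall back to package defaults; unknown fields
#' are a schema error.
#'
#' @param path YAML file
#' @return list with \code{simulation} (\linkS4class{SimConfig}),
#'   \code{preprocess} (\linkS4class{PreprocessConfig}), \code{analysis}
#'   (\linkS4class{AnalysisConfig}) and \code{inference} (list)
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  .checkFields(y, c("simulation", "preprocess", "analysis", "inference"),
               "(top level)")

  simFields <- c("n_participants", "n_trials", "sfreq_hz", "dt_shift_ms",
                 "dt_lognorm_mu", "dt_lognorm_sigma", "onset_ms", "bound_uv",
                 "decay_tau_ms", "topo_center", "topo_width", "pink_rms_uv",
                 "white_rms_uv", "alpha_rms_uv", "common_mode_rms_uv",
                 "cue_evoked_amp_uv", "p_condition", "error_kappa",
                 "target_error_deg", "dt_condition_shift_ms",
                 "onset_jitter_sd_ms", "montage", "seed")
  s <- y$simulation %||% list()
  .checkFields(s, simFields, "simulation")
  simArgs <- stats::setNames(s, .snake2camel(names(s)))
  for (f in c("boundUv", "errorKappa", "dtConditionShiftMs"))
    if (!is.null(simArgs[[f]])) simArgs[[f]] <- .namedNum(simArgs[[f]])
  for (f in c("topoCenter", "targetErrorDeg"))
    if (!is.null(simArgs[[f]])) simArgs[[f]] <- as.numeric(unlist(simArgs[[f]]))
  sim <- do.call(simConfig, simArgs)

  prepFields <- c("ref_channels", "target_sfreq_hz", "cue_window_ms",
                  "resp_window_ms", "cue_baseline_ms", "resp_baseline_ms",
                  "smooth_sigma_ms", "dt_bounds_ms", "variance_z_threshold")
  p <- y$preprocess %||% list()
  .checkFields(p, prepFields, "preprocess")
  prepArgs <- stats::setNames(p, .snake2camel(names(p)))
  vecFields <- c("cueWindowMs", "respWindowMs", "cueBaselineMs",
                 "respBaselineMs", "dtBoundsMs")
  for (f in vecFields)
    if (!is.null(prepArgs[[f]])) prepArgs[[f]] <- as.numeric(unlist(prepArgs[[f]]))
  if (!is.null(prepArgs$refChannels))
    prepArgs$refChannels <- as.character(unlist(prepArgs$refChannels))
  prep <- do.call(preprocessConfig, prepArgs)

  anaFields <- c("cluster_channels", "n_bins_fine", "n_bins_coarse",
                 "slope_window_ms", "sweep_starts_ms", "sweep_ends_ms",
                 "min_window_ms", "topo_windows_ms")
  a <- y$analysis %||% list()
  .checkFields(a, anaFields, "analysis")
  anaArgs <- stats::setNames(a, .snake2camel(names(a)))
  for (f in c("sweepStartsMs", "sweepEndsMs")) {
    g <- anaArgs[[f]]
    if (!is.null(g)) {
      g <- as.numeric(unlist(g))
      if (length(g) != 3)
        stop("config schema error: ", f, " must be [from, to, by]")
      anaArgs[[f]] <- seq(g[1], g[2], by = g[3])
    }
  }
  if (!is.null(anaArgs$slopeWindowMs))
    anaArgs$slopeWindowMs <- as.numeric(unlist(anaArgs$slopeWindowMs))
  if (!is.null(anaArgs$clusterChannels))
    anaArgs$clusterChannels <- as.character(unlist(anaArgs$clusterChannels))
  if (!is.null(anaArgs$topoWindowsMs))
    anaArgs$topoWindowsMs <- lapply(anaArgs$topoWindowsMs, as.numeric)
  ana <- do.call(analysisConfig, anaArgs)

  infFields <- c("cluster_alpha", "n_permutations", "seed")
  i <- y$inference %||% list()
  .checkFields(i, infFields, "inference")
  inf <- list(clusterAlpha = i$cluster_alpha %||% 0.05,
              nPermutations = i$n_permutations %||% 10000,
              seed = i$seed %||% 1)

  list(simulation = sim, preprocess = prep, analysis = ana, inference = inf)
}

#' Write a template pipeline configuration file
#'
#' Emits the package defaults as a documented YAML file that can be edited
#' and fed to the pipeline stages or the command-line tool.
#'
#' @param path output file
#' @param simulation optional \linkS4class{SimConfig} whose values seed the
#'   simulation section
#' @return invisibly, \code{path}
#' @export
writePipelineConfigTemplate <- function(path, simulation = simConfig()) {
  s <- simulation
  y <- list(
    simulation = list(
      n_participants = s@nParticipants, n_trials = s@nTrials,
      sfreq_hz = s@sfreqHz, dt_shift_ms = s@dtShiftMs,
      dt_lognorm_mu = s@dtLognormMu, dt_lognorm_sigma = s@dtLognormSigma,
      onset_ms = s@onsetMs, bound_uv = as.list(s@boundUv),
      decay_tau_ms = s@decayTauMs, topo_center = s@topoCenter,
      topo_width = s@topoWidth, pink_rms_uv = s@pinkRmsUv,
      white_rms_uv = s@whiteRmsUv, alpha_rms_uv = s@alphaRmsUv,
      common_mode_rms_uv = s@commonModeRmsUv,
      cue_evoked_amp_uv = s@cueEvokedAmpUv, p_condition = s@pCondition,
      error_kappa = as.list(s@errorKappa),
      dt_condition_shift_ms = as.list(s@dtConditionShiftMs),
      onset_jitter_sd_ms = s@onsetJitterSdMs, montage = s@montage,
      seed = s@seed),
    preprocess = list(
      ref_channels = c("M1", "M2"), target_sfreq_hz = 250,
      cue_window_ms = c(-250, 1500), resp_window_ms = c(-1500, 500),
      cue_baseline_ms = c(-250, 0), resp_baseline_ms = c(0, 250),
      smooth_sigma_ms = 30, dt_bounds_ms = c(200, 2000),
      variance_z_threshold = 3.5),
    analysis = list(
      cluster_channels = c("Pz", "CPz", "POz", "P1", "P2"),
      n_bins_fine = 100, n_bins_coarse = 4, slope_window_ms = c(-500, -50),
      sweep_starts_ms = c(-1000, -200, 50), sweep_ends_ms = c(-400, 0, 50),
      min_window_ms = 100,
      topo_windows_ms = list(cue = c(300, 600), resp = c(-300, 0),
                             contrast = c(-600, -300))),
    inference = list(cluster_alpha = 0.05, n_permutations = 10000, seed = 1)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
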
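## Pipeline orchestration: simulate -> preprocess -> analyze -> report.
## Sessions can come from disk containers or be generated lazily, one
## participant at a time, so full cohorts never have to fit in memory.

#' Lazy session sources for cohort analyses
#'
#' A session source is a list with \code{n} (participant count) and
#' \code{get(i)} returning the i-th \linkS4class{RawSession}.
#' \code{cohortSource} generates sessions on demand from a
#' \linkS4class{SimConfig} (deterministic per-participant sub-seeds, as in
#' \code{\link{simulateCohort}}); \code{diskSource} reads stored containers;
#' \code{listSource} wraps an in-memory list.
#'
#' @param config \linkS4class{SimConfig}
#' @return a session source
#' @export
cohortSource <- function(config) {
  stopifnot(is(config, "SimConfig"))
  n <- as.integer(config@nParticipants)
  seeds <- .withSeed(config@seed, sample.int(.Machine$integer.max - 1L, n))
  list(n = n, get = function(i)
    simulateParticipant(config, sprintf("sub-%02d", i), seeds[i]))
}

#' @rdname cohortSource
#' @param stems container path stems (see \code{\link{writeRawSession}})
#' @export
diskSource <- function(stems) {
  list(n = length(stems), get = function(i) readRawSession(stems[i]))
}

#' @rdname cohortSource
#' @param sessions list of \linkS4class{RawSession}
#' @export
listSource <- function(sessions) {
  list(n = length(sessions), get = function(i) sessions[[i]])
}

.statAsList <- function(g) {
  list(t = g@statistic, df = g@df, p = g@p, d = g@cohenD, mean = g@mean,
       sem = g@sem, n = g@n)
}

.clusterAsList <- function(ct) {
  list(clusters = ct@clusters, threshold = ct@threshold,
       n_permutations = ct@nPermutations, exhaustive = ct@exhaustive,
       tail = ct@tail,
       min_p = if (nrow(ct@clusters)) min(ct@clusters$p_perm) else NA)
}

#' Simulate a cohort and write session containers
#'
#' @param config \linkS4class{SimConfig}
#' @param outDir output directory (created if needed)
#' @param seed optional override of \code{config@seed}
#' @return invisibly, the run manifest (also written as
#'   \code{manifest.json}): configuration snapshot, per-participant seeds,
#'   file hashes and trial counts
#' @export
runSimulateStage <- function(config, outDir, seed = NULL) {
  stopifnot(is(config, "SimConfig"))
  if (!is.null(seed)) config@seed <- seed
  if (config@nTrials < 1) stop("n_trials must be at least 1")
  validObject(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  n <- as.integer(config@nParticipants)
  seeds <- .withSeed(config@seed, sample.int(.Machine$integer.max - 1L, n))
  files <- character(0)
  counts <- integer(n)
  for (i in seq_len(n)) {
    s <- simulateParticipant(config, sprintf("sub-%02d", i), seeds[i])
    stem <- file.path(outDir, sprintf("sub-%02d", i))
    files <- c(files, writeRawSession(s, stem))
    counts[i] <- nTrials(s)
  }
  cfgPath <- file.path(outDir, "config.yaml")
  writePipelineConfigTemplate(cfgPath, simulation = config)
  manifest <- list(
    stage = "simulate", package_version = as.character(utils::packageVersion("cppErp")),
    seed = config@seed, participant_seeds = seeds,
    n_participants = n, n_trials = counts,
    config_snapshot = cfgPath,
    files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Preprocess stored sessions into epoch containers
#'
#' @param stems session container stems
#' @param outDir output directory
#' @param prepCfg \linkS4class{PreprocessConfig}
#' @param alignment "cue" or "response"
#' @return invisibly, the list of written epoch stems; a retention table is
#'   written as \code{retention.tsv}
#' @export
runPreprocessStage <- function(stems, outDir, prepCfg = preprocessConfig(),
                               alignment = c("cue", "response")) {
  alignment <- match.arg(alignment)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  out <- character(length(stems))
  rep <- vector("list", length(stems))
  for (i in seq_along(stems)) {
    s <- readRawSession(stems[i])
    pr <- preprocessSession(s, prepCfg, alignment)
    out[i] <- file.path(outDir,
                        paste0(participantId(s), "_", alignment, "-epochs"))
    writeEpochSet(pr$epochs, out[i])
    rep[[i]] <- data.frame(participant = participantId(s),
                           as.data.frame(pr$report))
  }
  utils::write.table(do.call(rbind, rep),
                     file.path(outDir, "retention.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Analyze a cohort
#'
#' Runs the full analysis chain on each participant (preprocessing at both
#' alignments, electrode-cluster averaging, decision-time binning, slope
#' profiles) and the group level (grand ERPs with SEM, ERP images, quartile
#' slope table with slope-bin correlations and their group t, the
#' slope-window sweep t-map, cluster-based permutation tests against zero,
#' topography values, condition contrasts when two conditions are present,
#' and trial-retention accounting).
#'
#' @param source a session source (see \code{\link{cohortSource}}), a list of
#'   \linkS4class{RawSession}, or a \linkS4class{SimConfig}
#' @param prepCfg \linkS4class{PreprocessConfig}
#' @param anaCfg \linkS4class{AnalysisConfig}
#' @param infCfg list with \code{clusterAlpha}, \code{nPermutations},
#'   \code{seed}
#' @param smoothBinned smooth bin-average ERPs after binning (default TRUE)
#' @param verbose log per-participant progress
#' @return a results bundle (list); see \code{\link{writeResultsBundle}}
#' @export
analyzeCohort <- function(source, prepCfg = preprocessConfig(),
                          anaCfg = analysisConfig(),
                          infCfg = list(clusterAlpha = 0.05,
                                        nPermutations = 10000, seed = 1),
                          smoothBinned = TRUE, verbose = FALSE) {
  if (is(source, "SimConfig")) source <- cohortSource(source)
  if (is.list(source) && is.null(source$get)) source <- listSource(source)
  n <- source$n
  if (n < 2) stop("cohort analysis needs at least 2 participants")
  sig <- prepCfg@smoothSigmaMs
  fsT <- prepCfg@targetSfreqHz

  meanCue <- meanResp <- NULL          # participants x time
  condMeans <- list()                  # [[cond]][[align]] participants x time
  quartiles <- vector("list", n)
  fineResp <- vector("list", n)
  fineCue <- vector("list", n)
  topoCue <- topoResp <- topoContrast <- NULL
  rVec <- numeric(n)
  slopeTab <- binDtTab <- NULL
  behav <- vector("list", n)
  retain <- data.frame()
  timesCue <- timesResp <- NULL
  ids <- character(n)
  conds <- character(0)

  winMean <- function(ep, win, trials = NULL) {
    idx <- which(ep@times >= win[1] & ep@times <= win[2])
    d <- ep@data
    if (!is.null(trials)) d <- d[trials, , , drop = FALSE]
    stats::setNames(colMeans(apply(d[, , idx, drop = FALSE], c(1, 2), mean)),
                    ep@channelLabels)
  }

  for (i in seq_len(n)) {
    s <- source$get(i)
    ids[i] <- participantId(s)
    if (verbose) message("participant ", ids[i])
    sd <- downsampleSession(rereference(s, prepCfg@refChannels),
                            prepCfg@targetSfreqHz)
    rm(s)
    pc <- .epochAndClean(sd, prepCfg, "cue",
                         flagChannels = anaCfg@clusterChannels)
    pr <- .epochAndClean(sd, prepCfg, "response",
                         flagChannels = anaCfg@clusterChannels)
    rm(sd)
    epC <- pc$epochs; epR <- pr$epochs
    timesCue <- epC@times; timesResp <- epR@times
    cavC <- clusterAverage(epC, anaCfg@clusterChannels)
    cavR <- clusterAverage(epR, anaCfg@clusterChannels)
    meanCue <- rbind(meanCue, smoothGaussian(colMeans(cavC), sig, fsT))
    meanResp <- rbind(meanResp, smoothGaussian(colMeans(cavR), sig, fsT))

    dtR <- epR@trialInfo$decision_time_ms
    nb4 <- anaCfg@nBinsCoarse
    q <- binByDecisionTime(cavR, dtR, nb4, trialIds = epR@trialInfo$trial_id,
                           times = timesResp, alignment = "response",
                           participantIdent = ids[i])
    nbF <- min(anaCfg@nBinsFine, nrow(cavR), nrow(cavC))
    fR <- binByDecisionTime(cavR, dtR, nbF, trialIds = epR@trialInfo$trial_id,
                            times = timesResp, alignment = "response",
                            participantIdent = ids[i])
    fC <- binByDecisionTime(cavC, epC@trialInfo$decision_time_ms, nbF,
                            trialIds = epC@trialInfo$trial_id,
                            times = timesCue, alignment = "cue",
                            participantIdent = ids[i])
    if (smoothBinned) {
      q@binMeans <- smoothGaussian(q@binMeans, sig, fsT)
      fR@binMeans <- smoothGaussian(fR@binMeans, sig, fsT)
      fC@binMeans <- smoothGaussian(fC@binMeans, sig, fsT)
    }
    quartiles[[i]] <- q
    fineResp[[i]] <- fR
    fineCue[[i]] <- fC
    sp <- slopeBinProfile(q, anaCfg@slopeWindowMs)
    rVec[i] <- sp@rSlopeVsBin
    slopeTab <- rbind(slopeTab, sp@slopesPerBin)
    binDtTab <- rbind(binDtTab, binMeanDt(q))

    topoCue <- rbind(topoCue, winMean(epC, anaCfg@topoWindowsMs$cue))
    topoResp <- rbind(topoResp, winMean(epR, anaCfg@topoWindowsMs$resp))

    condHere <- sort(unique(epR@trialInfo$condition))
    conds <- sort(union(conds, condHere))
    if (length(condHere) >= 2) {
      for (cc in condHere) {
        selC <- epC@trialInfo$condition == cc
        selR <- epR@trialInfo$condition == cc
        condMeans[[cc]]$cue <- rbind(
          condMeans[[cc]]$cue,
          smoothGaussian(colMeans(cavC[selC, , drop = FALSE]), sig, fsT))
        condMeans[[cc]]$resp <- rbind(
          condMeans[[cc]]$resp,
          smoothGaussian(colMeans(cavR[selR, , drop = FALSE]), sig, fsT))
      }
      cA <- condHere[1]; cB <- condHere[2]
      topoContrast <- rbind(
        topoContrast,
        winMean(epR, anaCfg@topoWindowsMs$contrast,
                trials = epR@trialInfo$condition == cB) -
        winMean(epR, anaCfg@topoWindowsMs$contrast,
                trials = epR@trialInfo$condition == cA))
    }
    behav[[i]] <- stats::aggregate(
      cbind(decision_time_ms, reproduction_error_deg) ~ condition,
      data = epR@trialInfo, FUN = mean)
    retain <- rbind(retain,
                    data.frame(participant = ids[i],
                               as.data.frame(pr$report)))
    chLabels <- epR@channelLabels
  }

  grandCue <- grandErp(meanCue)
  grandResp <- grandErp(meanResp)
  exh <- infCfg$exhaustive %||% NULL
  ctCue <- clusterTest(meanCue, times = timesCue,
                       clusterAlpha = infCfg$clusterAlpha,
                       nPermutations = infCfg$nPermutations,
                       seed = infCfg$seed, exhaustive = exh)
  ctResp <- clusterTest(meanResp, times = timesResp,
                        clusterAlpha = infCfg$clusterAlpha,
                        nPermutations = infCfg$nPermutations,
                        seed = infCfg$seed, exhaustive = exh)
  imgResp <- tryCatch(erpImage(fineResp), error = function(e) NULL)
  imgCue <- tryCatch(erpImage(fineCue), error = function(e) NULL)
  groupR <- oneSampleT(rVec)
  sweep <- windowSweep(quartiles, anaCfg@sweepStartsMs, anaCfg@sweepEndsMs,
                       anaCfg@minWindowMs, anaCfg@slopeWindowMs)

  contrast <- NULL
  if (length(conds) >= 2 &&
      all(vapply(condMeans, function(cm)
        nrow(cm$cue) == n && nrow(cm$resp) == n, logical(1)))) {
    cA <- conds[1]; cB <- conds[2]   # alphabetical: A = preselected-like
    behTab <- do.call(rbind, lapply(seq_len(n), function(i)
      cbind(participant = ids[i], behav[[i]])))
    dtA <- vapply(behav, function(b)
      b$decision_time_ms[b$condition == cA], numeric(1))
    dtB <- vapply(behav, function(b)
      b$decision_time_ms[b$condition == cB], numeric(1))
    erA <- vapply(behav, function(b)
      b$reproduction_error_deg[b$condition == cA], numeric(1))
    erB <- vapply(behav, function(b)
      b$reproduction_error_deg[b$condition == cB], numeric(1))
    contrast <- list(
      conditions = c(cA, cB),
      cue = clusterTest(condMeans[[cB]]$cue, "paired", condMeans[[cA]]$cue,
                        times = timesCue, clusterAlpha = infCfg$clusterAlpha,
                        nPermutations = infCfg$nPermutations,
                        seed = infCfg$seed, exhaustive = exh),
      resp = clusterTest(condMeans[[cB]]$resp, "paired", condMeans[[cA]]$resp,
                         times = timesResp, clusterAlpha = infCfg$clusterAlpha,
                         nPermutations = infCfg$nPermutations,
                         seed = infCfg$seed, exhaustive = exh),
      dt_t = pairedT(dtA, dtB), error_t = pairedT(erA, erB),
      dt_means = c(mean(dtA), mean(dtB)), error_means = c(mean(erA), mean(erB)),
      behavior = behTab,
      topoContrast = colMeans(topoContrast))
  } else if (length(conds) < 2) {
    message("single condition cohort: condition-contrast outputs skipped")
  }

  list(
    n_participants = n, participant_ids = ids, conditions = conds,
    times_cue = timesCue, times_resp = timesResp,
    channel_labels = chLabels,
    grand_cue = grandCue, grand_resp = grandResp,
    cluster_cue = ctCue, cluster_resp = ctResp,
    erp_image_resp = imgResp, erp_image_cue = imgCue,
    slope_table = slopeTab, bin_mean_dt = binDtTab,
    r_per_participant = rVec, group_r = groupR,
    slope_window_ms = anaCfg@slopeWindowMs, sweep = sweep,
    topo_cue = colMeans(topoCue), topo_resp = colMeans(topoResp),
    contrast = contrast, retention = retain,
    retention_text = formatRetention(retain$n_retained, retain$n_events),
    behavior = do.call(rbind, lapply(seq_len(n), function(i)
      cbind(participant = ids[i], behav[[i]])))
  )
}

#' Write a results bundle to disk
#'
#' Serializes the output of \code{\link{analyzeCohort}} as TSV matrices plus
#' a \code{stats.json} with every scalar statistic and a \code{bundle.json}
#' index.
#'
#' @param res results list from \code{\link{analyzeCohort}}
#' @param outDir output directory
#' @return invisibly, the bundle index (list)
#' @export
writeResultsBundle <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(m, name, rowLabelName = "row") {
    p <- file.path(outDir, name)
    exportMatrix(m, p, rowLabelName)
    paths <<- c(paths, p)
  }
  erpMat <- function(g, times) {
    m <- rbind(mean = g$mean, sem = g$sem)
    colnames(m) <- times
    m
  }
  put(erpMat(res$grand_cue, res$times_cue), "grand_erp_cue.tsv", "stat")
  put(erpMat(res$grand_resp, res$times_resp), "grand_erp_resp.tsv", "stat")
  if (!is.null(res$erp_image_resp)) {
    img <- cbind(mean_dt_ms = res$erp_image_resp$meanDtMs,
                 res$erp_image_resp$image)
    colnames(img)[-1] <- res$times_resp
    rownames(img) <- paste0("bin", seq_len(nrow(img)))
    put(img, "erp_image_resp.tsv", "bin")
  }
  if (!is.null(res$erp_image_cue)) {
    img <- cbind(mean_dt_ms = res$erp_image_cue$meanDtMs,
                 res$erp_image_cue$image)
    colnames(img)[-1] <- res$times_cue
    rownames(img) <- paste0("bin", seq_len(nrow(img)))
    put(img, "erp_image_cue.tsv", "bin")
  }
  st <- res$slope_table
  dimnames(st) <- list(res$participant_ids,
                       paste0("slope_bin", seq_len(ncol(st))))
  dt <- res$bin_mean_dt
  colnames(dt) <- paste0("dt_bin", seq_len(ncol(dt)))
  put(cbind(st, dt, r = res$r_per_participant), "slopes_quartile.tsv",
      "participant")
  put(res$sweep$tMatrix, "sweep_tmap.tsv", "start_ms")
  topo <- rbind(cue = res$topo_cue, resp = res$topo_resp)
  if (!is.null(res$contrast))
    topo <- rbind(topo, contrast = res$contrast$topoContrast)
  put(topo, "topography.tsv", "window")
  put(as.matrix(res$cluster_cue@clusters), "clusters_cue.tsv", "cluster")
  put(as.matrix(res$cluster_resp@clusters), "clusters_resp.tsv", "cluster")
  rt <- file.path(outDir, "retention.tsv")
  utils::write.table(res$retention, rt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, rt)
  bt <- file.path(outDir, "behavior.tsv")
  utils::write.table(res$behavior, bt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, bt)

  stats <- list(
    n_participants = res$n_participants,
    conditions = res$conditions,
    slope_window_ms = res$slope_window_ms,
    r_per_participant = res$r_per_participant,
    r_mean_sem = describeMeanSem(res$r_per_participant)[c("mean", "sem")],
    group_r = .statAsList(res$group_r),
    cluster_cue = .clusterAsList(res$cluster_cue),
    cluster_resp = .clusterAsList(res$cluster_resp),
    retention_text = res$retention_text
  )
  if (!is.null(res$contrast)) {
    stats$contrast <- list(
      conditions = res$contrast$conditions,
      cluster_cue = .clusterAsList(res$contrast$cue),
      cluster_resp = .clusterAsList(res$contrast$resp),
      dt_t = .statAsList(res$contrast$dt_t),
      error_t = .statAsList(res$contrast$error_t),
      dt_means = res$contrast$dt_means,
      error_means = res$contrast$error_means)
  }
  sp <- file.path(outDir, "stats.json")
  jsonlite::write_json(stats, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, sp)
  index <- list(kind = "cppErp-results-bundle",
                files = as.list(basename(paths)))
  jsonlite::write_json(index, file.path(outDir, "bundle.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(index)
}

#' Analyze stored sessions and write the results bundle
#'
#' @param stems session container stems
#' @param outDir output directory
#' @param prepCfg,anaCfg,infCfg stage configurations (see
#'   \code{\link{analyzeCohort}})
#' @param ... passed on to \code{\link{analyzeCohort}}
#' @return invisibly, the results list
#' @export
runAnalyzeStage <- function(stems, outDir, prepCfg = preprocessConfig(),
                            anaCfg = analysisConfig(),
                            infCfg = list(clusterAlpha = 0.05,
                                          nPermutations = 10000, seed = 1),
                            ...) {
  res <- analyzeCohort(diskSource(stems), prepCfg, anaCfg, infCfg, ...)
  writeResultsBundle(res, outDir)
  invisible(res)
}

#' Render a human-readable report from a results bundle
#'
#' Reads \code{stats.json} from a bundle directory and formats every
#' statistic in reporting style (t(df), p, d; M ± SEM). A missing or empty
#' bundle yields an explicit "nothing to report" outcome; missing pieces are
#' listed.
#'
#' @param bundleDir directory written by \code{\link{writeResultsBundle}}
#' @return character vector of report lines (also written to
#'   \code{report.txt} in the bundle)
#' @export
runReportStage <- function(bundleDir) {
  sp <- file.path(bundleDir, "stats.json")
  if (!file.exists(sp)) {
    lines <- "nothing to report: no stats.json in bundle"
    return(lines)
  }
  st <- jsonlite::fromJSON(sp, simplifyVector = TRUE)
  need <- c("n_participants", "group_r", "cluster_cue", "cluster_resp",
            "retention_text")
  miss <- setdiff(need, names(st))
  if (length(miss))
    return(c("incomplete bundle; missing pieces:", paste(" -", miss)))
  fmtStat <- function(g)
    sprintf("t(%d) = %.3f, p = %s, d = %.3f", as.integer(g$df), g$t,
            format(signif(g$p, 4)), g$d)
  fmtCl <- function(cl) {
    if (is.null(cl$min_p) || is.na(cl$min_p)) "no suprathreshold clusters"
    else sprintf("min cluster p = %s (%s permutations%s)",
                 format(signif(cl$min_p, 4)),
                 format(cl$n_permutations, big.mark = ","),
                 if (isTRUE(cl$exhaustive)) ", exhaustive" else "")
  }
  lines <- c(
    sprintf("Cohort: n = %d participants", st$n_participants),
    sprintf("Retained: %s", st$retention_text),
    sprintf("Slope-bin correlation: r = %.3f ± %.3f (M ± SEM)",
            st$r_mean_sem$mean, st$r_mean_sem$sem),
    sprintf("Group test of r vs 0: %s", fmtStat(st$group_r)),
    sprintf("Cue-locked ERP vs 0: %s", fmtCl(st$cluster_cue)),
    sprintf("Response-locked ERP vs 0: %s", fmtCl(st$cluster_resp))
  )
  if (!is.null(st$contrast)) {
    lines <- c(lines,
      sprintf("Condition contrast (%s vs %s):",
              st$contrast$conditions[2], st$contrast$conditions[1]),
      sprintf("  cue-locked: %s", fmtCl(st$contrast$cluster_cue)),
      sprintf("  response-locked: %s", fmtCl(st$contrast$cluster_resp)),
      sprintf("  decision time: %.1f vs %.1f ms, %s",
              st$contrast$dt_means[1], st$contrast$dt_means[2],
              fmtStat(st$contrast$dt_t)),
      sprintf("  reproduction error: %.2f vs %.2f deg, %s",
              st$contrast$error_means[1], st$contrast$error_means[2],
              fmtStat(st$contrast$error_t)))
  }
  writeLines(lines, file.path(bundleDir, "report.txt"))
  lines
}
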
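#' @name accessors
#' @title Accessors for cppErp data classes
#' @description Slot accessors shared by \linkS4class{RawSession},
#'   \linkS4class{EpochSet}, \linkS4class{BinnedErp} and the statistic
#'   bundles.
#' @param object a cppErp S4 object
NULL

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("channelPositions",
           function(object) standardGeneric("channelPositions"))
#' @rdname accessors
#' @export
setGeneric("sfreq", function(object) standardGeneric("sfreq"))
#' @rdname accessors
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("sessionData", function(object) standardGeneric("sessionData"))
#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("trialInfo", function(object) standardGeneric("trialInfo"))
#' @rdname accessors
#' @export
setGeneric("epochTimes", function(object) standardGeneric("epochTimes"))
#' @rdname accessors
#' @export
setGeneric("alignment", function(object) standardGeneric("alignment"))
#' @rdname accessors
#' @export
setGeneric("binMeans", function(object) standardGeneric("binMeans"))
#' @rdname accessors
#' @export
setGeneric("binMeanDt", function(object) standardGeneric("binMeanDt"))
#' @rdname accessors
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))
#' @rdname accessors
#' @export
setGeneric("clusters", function(object) standardGeneric("clusters"))

#' @rdname accessors
setMethod("channelLabels", "RawSession", function(object) object@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "EpochSet", function(object) object@channelLabels)
#' @rdname accessors
setMethod("channelPositions", "RawSession",
          function(object) object@channelPositions)
#' @rdname accessors
setMethod("channelPositions", "EpochSet",
          function(object) object@channelPositions)
#' @rdname accessors
setMethod("sfreq", "RawSession", function(object) object@sfreqHz)
#' @rdname accessors
setMethod("sfreq", "EpochSet", function(object) object@sfreqHz)
#' @rdname accessors
setMethod("participantId", "RawSession", function(object) object@participantId)
#' @rdname accessors
setMethod("participantId", "EpochSet", function(object) object@participantId)
#' @rdname accessors
setMethod("participantId", "BinnedErp", function(object) object@participantId)
#' @rdname accessors
setMethod("nTrials", "RawSession", function(object) nrow(object@events))
#' @rdname accessors
setMethod("nTrials", "EpochSet", function(object) dim(object@data)[1])
#' @rdname accessors
setMethod("sessionData", "RawSession", function(object) object@data)
#' @rdname accessors
setMethod("events", "RawSession", function(object) object@events)
#' @rdname accessors
setMethod("epochData", "EpochSet", function(object) object@data)
#' @rdname accessors
setMethod("trialInfo", "EpochSet", function(object) object@trialInfo)
#' @rdname accessors
setMethod("epochTimes", "EpochSet", function(object) object@times)
#' @rdname accessors
setMethod("alignment", "EpochSet", function(object) object@alignment)
#' @rdname accessors
setMethod("alignment", "BinnedErp", function(object) object@alignment)
#' @rdname accessors
setMethod("epochTimes", "BinnedErp", function(object) object@times)
#' @rdname accessors
setMethod("binMeans", "BinnedErp", function(object) object@binMeans)
#' @rdname accessors
setMethod("binMeanDt", "BinnedErp", function(object) object@binMeanDtMs)
#' @rdname accessors
setMethod("binCounts", "BinnedErp", function(object) object@binCounts)
#' @rdname accessors
setMethod("clusters", "ClusterTestResult", function(object) object@clusters)

setMethod("show", "RawSession", function(object) {
  cat(sprintf("RawSession '%s': %d channels x %d samples at %g Hz, %d trials\n",
              object@participantId, nrow(object@data), ncol(object@data),
              object@sfreqHz, nrow(object@events)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochSet '%s' (%s-locked): %d trials x %d channels x %d samples at %g Hz\n",
    object@participantId, object@alignment, d[1], d[2], d[3], object@sfreqHz))
  cat(sprintf("  time %g..%g ms\n", min(object@times), max(object@times)))
})

setMethod("show", "BinnedErp", function(object) {
  cat(sprintf(
    "BinnedErp '%s' (%s-locked): %d decision-time bins x %d samples\n",
    object@participantId, object@alignment, nrow(object@binMeans),
    ncol(object@binMeans)))
  cat(sprintf("  bin mean DT %.0f..%.0f ms\n",
              min(object@binMeanDtMs), max(object@binMeanDtMs)))
})

setMethod("show", "GroupStatResult", function(object) {
  cat(formatGroupStat(object), "\n")
})

setMethod("show", "ClusterTestResult", function(object) {
  cat(sprintf(
    "Cluster-based permutation test (%s, tail = %s, %s permutations%s)\n",
    object@design, object@tail, format(object@nPermutations, big.mark = ","),
    if (object@exhaustive) ", exhaustive" else ""))
  cat(sprintf("  cluster-forming |t| threshold %.3f\n", object@threshold))
  if (nrow(object@clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    print(object@clusters, row.names = FALSE)
  }
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d participants x %d trials at %g Hz (montage '%s', seed %d)\n",
    object@nParticipants, object@nTrials, object@sfreqHz, object@montage,
    as.integer(object@seed)))
  cat(sprintf("  DT ~ %g + logN(%g, %g) ms; onset %g ms; bound(s) %s uV\n",
              object@dtShiftMs, object@dtLognormMu, object@dtLognormSigma,
              object@onsetMs,
              paste(sprintf("%s=%g", names(object@boundUv), object@boundUv),
                    collapse = ", ")))
})
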
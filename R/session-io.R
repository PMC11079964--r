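## On-disk containers. A stored object is a file triplet:
##   <stem>.json        header (format version, kind, rate, labels, shape, ...)
##   <stem>.f32         payload, little-endian float32
##   <stem>.events.tsv  one row per trial (raw) / retained trial (epochs)
## Payload ordering is declared in the header: "channel,time" for raw
## (all samples of channel 1, then channel 2, ...) and "trial,channel,time"
## for epochs (trial slowest, time fastest).

.FORMAT_VERSION <- "1.0"

.containerPaths <- function(stem) {
  list(header = paste0(stem, ".json"), payload = paste0(stem, ".f32"),
       events = paste0(stem, ".events.tsv"))
}

.writeHeader <- function(header, path) {
  jsonlite::write_json(header, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

.readHeader <- function(path, kindWanted) {
  if (!file.exists(path)) stop("missing container header: ", path)
  h <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  required <- c("format_version", "kind", "sfreq_hz", "channel_labels",
                "channel_positions", "shape", "dtype", "units")
  miss <- setdiff(required, names(h))
  if (length(miss))
    stop("malformed container header (", path, "): missing field '",
         miss[1], "'")
  if (!identical(h$dtype, "float32-le"))
    stop("malformed container header (", path, "): unsupported dtype '",
         h$dtype, "'")
  if (!identical(h$kind, kindWanted))
    stop("container kind mismatch: expected '", kindWanted, "', found '",
         h$kind, "' in ", path)
  h
}

.readPayload <- function(path, shape) {
  nExpect <- prod(shape)
  sz <- file.size(path)
  if (is.na(sz)) stop("missing container payload: ", path)
  if (sz != 4 * nExpect)
    stop(sprintf(
      "payload size mismatch in %s: %d bytes on disk, %d expected from shape",
      path, sz, 4 * nExpect))
  readBin(path, what = "numeric", n = nExpect, size = 4, endian = "little")
}

.writeEventsTsv <- function(ev, path) {
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

.readEventsTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

.posFromHeader <- function(h) {
  p <- h$channel_positions
  pos <- if (is.matrix(p)) p else do.call(rbind, lapply(p, as.numeric))
  rownames(pos) <- h$channel_labels
  colnames(pos) <- NULL
  pos
}

#' Write a raw session container
#'
#' @param session \linkS4class{RawSession}
#' @param stem output path without extension; writes \code{<stem>.json},
#'   \code{<stem>.f32} and \code{<stem>.events.tsv}
#' @return invisibly, the vector of file paths written
#' @export
writeRawSession <- function(session, stem) {
  stopifnot(is(session, "RawSession"))
  p <- .containerPaths(stem)
  header <- list(
    format_version = .FORMAT_VERSION, kind = "raw",
    sfreq_hz = session@sfreqHz, channel_labels = session@channelLabels,
    channel_positions = unname(apply(session@channelPositions, 1, c,
                                     simplify = FALSE)),
    shape = dim(session@data), dtype = "float32-le", units = "µV",
    payload_order = "channel,time", participant_id = session@participantId
  )
  .writeHeader(header, p$header)
  con <- file(p$payload, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(session@data)), con, size = 4, endian = "little")
  .writeEventsTsv(session@events, p$events)
  invisible(unlist(p))
}

#' Read a raw session container
#'
#' @param stem path stem used when writing (see \code{\link{writeRawSession}})
#' @return \linkS4class{RawSession}
#' @export
readRawSession <- function(stem) {
  p <- .containerPaths(stem)
  h <- .readHeader(p$header, "raw")
  shape <- as.numeric(h$shape)
  x <- .readPayload(p$payload, shape)
  data <- t(matrix(x, nrow = shape[2], ncol = shape[1]))  # channel-major
  pos <- .posFromHeader(h)
  ev <- .readEventsTsv(p$events)
  new("RawSession", data = data, sfreqHz = as.numeric(h$sfreq_hz),
      channelLabels = as.character(h$channel_labels), channelPositions = pos,
      events = ev,
      participantId = as.character(h$participant_id %||% "unknown"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an epoch-set container
#'
#' @param epochs \linkS4class{EpochSet}
#' @param stem output path stem
#' @return invisibly, the vector of file paths written
#' @export
writeEpochSet <- function(epochs, stem) {
  stopifnot(is(epochs, "EpochSet"))
  p <- .containerPaths(stem)
  header <- list(
    format_version = .FORMAT_VERSION, kind = "epochs",
    sfreq_hz = epochs@sfreqHz, channel_labels = epochs@channelLabels,
    channel_positions = unname(apply(epochs@channelPositions, 1, c,
                                     simplify = FALSE)),
    shape = dim(epochs@data), dtype = "float32-le", units = "µV",
    payload_order = "trial,channel,time", alignment = epochs@alignment,
    times_ms = epochs@times, participant_id = epochs@participantId
  )
  .writeHeader(header, p$header)
  con <- file(p$payload, "wb")
  on.exit(close(con))
  # trial slowest, then channel, then time fastest
  writeBin(as.vector(aperm(epochs@data, c(3, 2, 1))), con, size = 4,
           endian = "little")
  .writeEventsTsv(epochs@trialInfo, p$events)
  invisible(unlist(p))
}

#' Read an epoch-set container
#'
#' @param stem path stem used when writing (see \code{\link{writeEpochSet}})
#' @return \linkS4class{EpochSet}
#' @export
readEpochSet <- function(stem) {
  p <- .containerPaths(stem)
  h <- .readHeader(p$header, "epochs")
  for (fld in c("alignment", "times_ms"))
    if (is.null(h[[fld]]))
      stop("malformed container header (", p$header, "): missing field '",
           fld, "'")
  shape <- as.numeric(h$shape)
  x <- .readPayload(p$payload, shape)
  data <- aperm(array(x, dim = rev(shape)), c(3, 2, 1))
  pos <- .posFromHeader(h)
  ti <- .readEventsTsv(p$events)
  new("EpochSet", data = data, sfreqHz = as.numeric(h$sfreq_hz),
      alignment = as.character(h$alignment), times = as.numeric(h$times_ms),
      channelLabels = as.character(h$channel_labels), channelPositions = pos,
      trialInfo = ti,
      participantId = as.character(h$participant_id %||% "unknown"))
}

#' Export a labelled matrix as TSV
#'
#' Writes a tab-separated file with row labels in the first column and column
#' labels in the header row; NaN values are rendered as "NA". Serves the ERP
#' images, topography value tables and sweep t-maps.
#'
#' @param m matrix (may carry dimnames; defaults are generated otherwise)
#' @param path output file
#' @param rowLabelName header of the row-label column
#' @return invisibly, \code{path}
#' @export
exportMatrix <- function(m, path, rowLabelName = "row") {
  m <- as.matrix(m)
  if (is.null(rownames(m)) && nrow(m))
    rownames(m) <- paste0("r", seq_len(nrow(m)))
  if (is.null(colnames(m)) && ncol(m))
    colnames(m) <- paste0("c", seq_len(ncol(m)))
  m[is.nan(m)] <- NA
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- rowLabelName
  if (nrow(m) == 0)
    df <- stats::setNames(
      data.frame(matrix(ncol = ncol(m) + 1, nrow = 0)),
      c(rowLabelName, colnames(m)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read back a matrix written by \code{\link{exportMatrix}}
#'
#' @param path TSV file
#' @return numeric matrix with dimnames
#' @export
readMatrixTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    m <- matrix(numeric(0), 0, ncol(df) - 1)
    colnames(m) <- names(df)[-1]
    return(m)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
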
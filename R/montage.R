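#' Standard 10-10 scalp montage with 2-D coordinates
#'
#' Builds a flattened-scalp coordinate table for the simulator and for the
#' spatial weighting of the synthetic CPP component. The full montage carries
#' 61 scalp electrodes (the 10-10 rows Fp through O) plus the two mastoids
#' "M1"/"M2"; the compact montage keeps the a priori Pz-centred analysis
#' cluster ("Pz", "CPz", "POz", "P1", "P2"), a handful of context channels,
#' and the mastoids. Coordinates are unit-head-radius projections: y runs from
#' posterior (-1) to anterior (+1), x from left (-1) to right (+1), with row
#' width shrinking towards the poles.
#'
#' @param type "full" (63 channels) or "compact" (12 channels)
#' @return data.frame with columns \code{label}, \code{x}, \code{y}
#' @export
#' @examples
#' m <- standardMontage("full")
#' nrow(m)  # 63
standardMontage <- function(type = c("full", "compact")) {
  type <- match.arg(type)
  rowdef <- list(
    list(pre = "Fp", y = 0.85, idx = c(1, 0, 2)),
    list(pre = "AF", y = 0.65, idx = c(7, 3, 0, 4, 8)),
    list(pre = "F",  y = 0.45, idx = c(7, 5, 3, 1, 0, 2, 4, 6, 8)),
    list(pre = "FC", y = 0.22, idx = c(7, 5, 3, 1, 0, 2, 4, 6, 8),
         lat = c("FT7", "FT8")),
    list(pre = "C",  y = 0.00, idx = c(7, 5, 3, 1, 0, 2, 4, 6, 8),
         lat = c("T7", "T8")),
    list(pre = "CP", y = -0.22, idx = c(7, 5, 3, 1, 0, 2, 4, 6, 8),
         lat = c("TP7", "TP8")),
    list(pre = "P",  y = -0.45, idx = c(7, 5, 3, 1, 0, 2, 4, 6, 8)),
    list(pre = "PO", y = -0.65, idx = c(7, 3, 0, 4, 8)),
    list(pre = "O",  y = -0.85, idx = c(1, 0, 2))
  )
  out <- do.call(rbind, lapply(rowdef, function(r) {
    w <- sqrt(max(0, 1 - r$y^2))          # row half-width on a round head
    lab <- ifelse(r$idx == 0, paste0(r$pre, "z"), paste0(r$pre, r$idx))
    if (!is.null(r$lat)) {
      lab[lab == paste0(r$pre, 7)] <- r$lat[1]
      lab[lab == paste0(r$pre, 8)] <- r$lat[2]
    }
    # indices 1,3,5,7 left; 2,4,6,8 right; spacing 1/4 of half-width
    side <- ifelse(r$idx == 0, 0, ifelse(r$idx %% 2 == 1, -1, 1))
    rank <- ifelse(r$idx == 0, 0, ceiling(r$idx / 2))
    if (length(r$idx) == 3) rank <- rank * 1.2   # Fp/O rows sit closer in
    data.frame(label = lab, x = side * rank * w / 4, y = r$y,
               stringsAsFactors = FALSE)
  }))
  out <- rbind(out, data.frame(label = c("M1", "M2"), x = c(-0.98, 0.98),
                               y = c(-0.35, -0.35), stringsAsFactors = FALSE))
  if (type == "compact") {
    keep <- c("Fz", "Cz", "C3", "C4", "Pz", "CPz", "POz", "P1", "P2", "Oz",
              "M1", "M2")
    out <- out[match(keep, out$label), ]
    rownames(out) <- NULL
  }
  out
}

#' Gaussian spatial weights over a montage
#'
#' Isotropic 2-D Gaussian evaluated at each channel position; used as the
#' forward projection of the simulated CPP component.
#'
#' @param positions channels x 2 matrix (or montage data.frame)
#' @param center length-2 numeric
#' @param width Gaussian SD in montage units
#' @return numeric weight per channel (peak value 1 at the center)
#' @export
spatialWeights <- function(positions, center, width) {
  if (is.data.frame(positions)) positions <- as.matrix(positions[, c("x", "y")])
  d2 <- (positions[, 1] - center[1])^2 + (positions[, 2] - center[2])^2
  exp(-d2 / (2 * width^2))
}
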
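#' Format a group statistic in reporting style
#'
#' Renders a \linkS4class{GroupStatResult} as "t(df) = x.xxx, p = ..., d =
#' x.xxx".
#'
#' @param res \linkS4class{GroupStatResult}
#' @param digits decimal places for t and d
#' @return character scalar
#' @export
formatGroupStat <- function(res, digits = 3) {
  stopifnot(is(res, "GroupStatResult"))
  pTxt <- if (is.na(res@p)) "NA" else format(signif(res@p, 4),
                                             scientific = res@p < 1e-4)
  sprintf("t(%d) = %.*f, p = %s, d = %.*f", as.integer(res@df), digits,
          res@statistic, pTxt, digits, res@cohenD)
}

#' Format a value as "M \eqn{\pm} SEM"
#'
#' @param values numeric vector, or a list as returned by
#'   \code{\link{describeMeanSem}}
#' @param digits decimal places
#' @param unit optional unit suffix
#' @return character scalar like "14.14 ± 0.84 degrees"
#' @export
formatMeanSem <- function(values, digits = 2, unit = "") {
  d <- if (is.list(values)) values else describeMeanSem(values)
  out <- sprintf("%.*f ± %.*f", digits, d$mean, digits, d$sem)
  if (nzchar(unit)) out <- paste(out, unit)
  out
}

#' Format a trial-retention report
#'
#' Mirrors the reporting convention "1,027 \eqn{\pm} 25 trials (86 \eqn{\pm}
#' 2\%)": mean \eqn{\pm} SEM of retained trial counts across participants and
#' of retention percentages.
#'
#' @param retained per-participant retained trial counts
#' @param total per-participant total trial counts
#' @return character scalar
#' @export
formatRetention <- function(retained, total) {
  cnt <- describeMeanSem(retained)
  pct <- describeMeanSem(100 * retained / total)
  sprintf("%s ± %s trials (%.0f ± %.0f%%)",
          format(round(cnt$mean), big.mark = ","),
          format(round(cnt$sem)), pct$mean, pct$sem)
}
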
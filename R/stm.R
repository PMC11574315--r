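#' Spectral-temporal metric from observation series
#'
#' Per-pixel percentile of a spectral index over a multi-year period,
#' pooling all clear observations of the period. The percentile uses
#' linear interpolation between order statistics ([stats::quantile()]
#' type 7). Pixels with no clear observation in the period are nodata (NA)
#' and are thereby excluded from every sampling rule.
#'
#' @param series scene series as produced by [simulate_landscape()]: a list
#'   indexed `[[pixel]][[year index]]` of [observation_series()], pixels in
#'   column-major order of the scene grid.
#' @param rows,cols scene grid size.
#' @param index band/index name from [LC_BANDS] (e.g. `"ndvi"`).
#' @param percentile value in `[0, 100]`.
#' @param years restrict to these calendar years (default: all).
#' @return numeric `rows` x `cols` matrix (NA = nodata).
#' @export
compute_stm <- function(series, rows, cols, index = "ndvi", percentile = 90,
                        years = NULL) {
  stopifnot(index %in% LC_BANDS, percentile >= 0, percentile <= 100,
            length(series) == rows * cols)
  b <- match(index, LC_BANDS)
  out <- matrix(NA_real_, rows, cols)
  for (p in seq_along(series)) {
    vals <- unlist(lapply(series[[p]], function(s) {
      if (is.null(s)) return(numeric(0))
      if (!is.null(years) && !(s$year %in% years)) return(numeric(0))
      s$values[s$clear, b]
    }), use.names = FALSE)
    if (length(vals) > 0L) {
      out[p] <- stats::quantile(vals, percentile / 100, names = FALSE, type = 7)
    }
  }
  out
}
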
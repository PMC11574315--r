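#' Band layout of encoded samples
#'
#' Six surface-reflectance bands plus three derived indices, in the fixed
#' order used by the weekly encoder and the classifier.
#' @export
LC_BANDS <- c("red", "green", "blue", "nir", "swir1", "swir2",
              "ndvi", "ndwi", "savi")

#' Spectral indices from reflectance bands
#'
#' NDVI = (nir - red)/(nir + red); NDWI (green/NIR form) =
#' (green - nir)/(green + nir); SAVI = (nir - red)(1 + L)/(nir + red + L)
#' with soil factor L = 0.5. A zero denominator yields an index of 0 and is
#' flagged in the `zero_denominator` attribute.
#'
#' @param red,green,blue,nir,swir1,swir2 reflectance fractions in `[0, 1]`
#'   (vectors of equal length; `blue`, `swir1`, `swir2` are accepted for a
#'   uniform signature but unused by these three indices).
#' @param L SAVI soil-adjustment factor.
#' @return data.frame with columns `ndvi`, `ndwi`, `savi`;
#'   attribute `zero_denominator` marks rows where a guard fired.
#' @export
compute_indices <- function(red, green, blue = NULL, nir, swir1 = NULL,
                            swir2 = NULL, L = 0.5) {
  dv <- nir + red
  dw <- green + nir
  ds <- nir + red + L
  flag <- dv == 0 | dw == 0 | ds == 0
  ndvi <- ifelse(dv == 0, 0, (nir - red) / dv)
  ndwi <- ifelse(dw == 0, 0, (green - nir) / dw)
  savi <- ifelse(ds == 0, 0, (nir - red) * (1 + L) / ds)
  out <- data.frame(ndvi = ndvi, ndwi = ndwi, savi = savi)
  attr(out, "zero_denominator") <- flag
  out
}

#' One pixel-year of dated observations
#'
#' @param year calendar year.
#' @param doy integer day-of-year vector (1-366), strictly increasing.
#' @param bands numeric matrix `length(doy)` x 6 of reflectance fractions,
#'   columns red, green, blue, nir, swir1, swir2.
#' @param clear logical clear-sky flag per observation (default all clear).
#' @return object of class `obs_series`: carries `values`, the n x 9 matrix
#'   of bands plus indices in [LC_BANDS] order.
#' @export
observation_series <- function(year, doy, bands, clear = rep(TRUE, length(doy))) {
  doy <- as.integer(doy)
  if (length(doy) == 0L) {
    values <- matrix(numeric(0), 0, 9, dimnames = list(NULL, LC_BANDS))
    return(structure(list(year = year, doy = integer(0), values = values,
                          clear = logical(0)), class = "obs_series"))
  }
  bands <- matrix(as.numeric(bands), nrow = length(doy), ncol = 6)
  stopifnot(all(doy >= 1L & doy <= 366L), !is.unsorted(doy, strictly = TRUE),
            length(clear) == length(doy))
  idx <- compute_indices(red = bands[, 1], green = bands[, 2],
                         blue = bands[, 3], nir = bands[, 4],
                         swir1 = bands[, 5], swir2 = bands[, 6])
  values <- cbind(bands, idx$ndvi, idx$ndwi, idx$savi)
  colnames(values) <- LC_BANDS
  structure(list(year = year, doy = doy, values = values,
                 clear = as.logical(clear)),
            class = "obs_series")
}

#' @export
print.obs_series <- function(x, ...) {
  cat(sprintf("obs_series: year %s, %d observations (%d clear)\n",
              x$year, length(x$doy), sum(x$clear)))
  invisible(x)
}

#' Week index of a day of year
#'
#' `floor((doy - 1)/7)` capped at 51, so days 365/366 fold into week 51 and
#' the year maps onto exactly 52 slots.
#'
#' @param doy integer day(s) of year.
#' @return 0-based week index in 0..51.
#' @export
week_of_doy <- function(doy) {
  pmin((as.integer(doy) - 1L) %/% 7L, 51L)
}

#' Weekly temporal encoding of one pixel-year
#'
#' Converts an irregular annual series into the fixed 52 x 9 matrix fed to
#' the temporal classifier: clear observations of each calendar week are
#' averaged into that week's slot; weeks with no clear observation hold
#' exactly 0. Non-clear observations are ignored.
#'
#' @param series an [observation_series()].
#' @return numeric 52 x 9 matrix (weeks x bands, [LC_BANDS] order) with a
#'   `counts` attribute: clear observations per week.
#' @export
encode_weekly <- function(series) {
  stopifnot(inherits(series, "obs_series"))
  m <- matrix(0, 52, 9, dimnames = list(NULL, LC_BANDS))
  counts <- integer(52)
  keep <- series$clear
  if (any(keep)) {
    wk <- week_of_doy(series$doy[keep])
    v <- series$values[keep, , drop = FALSE]
    sums <- rowsum(v, wk)
    n <- as.vector(table(factor(wk, levels = sort(unique(wk)))))
    rows <- as.integer(rownames(sums)) + 1L
    m[rows, ] <- sums / n
    counts[rows] <- n
  }
  attr(m, "counts") <- counts
  m
}

#' Encode many pixel-years at once
#'
#' Vectorised version of [encode_weekly()] used by training and prediction.
#'
#' @param series_list list of [observation_series()].
#' @return numeric array `length(series_list)` x 52 x 9.
#' @export
encode_weekly_batch <- function(series_list) {
  n <- length(series_list)
  out <- array(0, dim = c(n, 52, 9))
  if (n == 0L) return(out)
  ids <- rep.int(seq_len(n), vapply(series_list, function(s) sum(s$clear), 0L))
  if (length(ids) > 0L) {
    doys <- unlist(lapply(series_list, function(s) s$doy[s$clear]), use.names = FALSE)
    vals <- do.call(rbind, lapply(series_list, function(s) {
      s$values[s$clear, , drop = FALSE]
    }))
    key <- (ids - 1L) * 52L + week_of_doy(doys) # 0-based flat (sample, week)
    sums <- rowsum(vals, key)
    cnt <- as.vector(table(factor(key, levels = sort(unique(key)))))
    k <- as.integer(rownames(sums))
    samp <- k %/% 52L + 1L
    week <- k %% 52L + 1L
    for (b in 1:9) out[cbind(samp, week, b)] <- sums[, b] / cnt
  }
  out
}

#' Annual clear-sky observation counts
#'
#' @param series_list list of [observation_series()] (any mix of pixels and
#'   years).
#' @return data.frame with one row per series: `year`, `n_clear`.
#' @export
compute_cso <- function(series_list) {
  data.frame(
    year = vapply(series_list, function(s) as.numeric(s$year), 0),
    n_clear = vapply(series_list, function(s) sum(s$clear), 0L)
  )
}

#' Random observation selection (training augmentation)
#'
#' Draws a keep fraction uniformly from `keep_fraction_range`, then keeps
#' each clear observation independently with that probability; if the input
#' is non-empty at least one observation is always retained. Kept
#' observations are unmodified. Mimics the sparser acquisition record of
#' early years so the classifier transfers across observation densities.
#'
#' @param series an [observation_series()].
#' @param keep_fraction_range numeric length-2 interval in (0, 1].
#' @param seed optional integer seed for reproducibility.
#' @return an [observation_series()] with a subset of the observations.
#' @export
augment_random_obs_selection <- function(series, keep_fraction_range = c(0.25, 1),
                                         seed = NULL) {
  stopifnot(inherits(series, "obs_series"), length(keep_fraction_range) == 2,
            keep_fraction_range[1] > 0, keep_fraction_range[2] <= 1,
            keep_fraction_range[1] <= keep_fraction_range[2])
  n <- length(series$doy)
  if (n == 0L) return(series)
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(1, keep_fraction_range[1], keep_fraction_range[2])
  keep <- stats::runif(n) < p
  if (!any(keep)) keep[sample.int(n, 1L)] <- TRUE
  subset_series(series, keep)
}

#' Random day shifting (training augmentation)
#'
#' Applies one shared integer day offset, drawn uniformly from
#' `[-max_shift_days, +max_shift_days]`, to all observation dates —
#' emulating a phenological shift of the whole season. Observations shifted
#' outside day 1-365 are dropped; values are unmodified.
#'
#' @param series an [observation_series()].
#' @param max_shift_days nonnegative integer.
#' @param seed optional integer seed.
#' @return shifted [observation_series()].
#' @export
augment_random_day_shift <- function(series, max_shift_days = 7, seed = NULL) {
  stopifnot(inherits(series, "obs_series"), max_shift_days >= 0)
  max_shift_days <- as.integer(max_shift_days)
  if (!is.null(seed)) set.seed(seed)
  off <- sample.int(2L * max_shift_days + 1L, 1L) - max_shift_days - 1L
  if (off == 0L || length(series$doy) == 0L) return(series)
  doy <- series$doy + off
  keep <- doy >= 1L & doy <= 365L
  out <- subset_series(series, keep)
  out$doy <- doy[keep]
  out
}

subset_series <- function(series, keep) {
  structure(list(year = series$year, doy = series$doy[keep],
                 values = series$values[keep, , drop = FALSE],
                 clear = series$clear[keep]),
            class = "obs_series")
}
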
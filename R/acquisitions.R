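#' Annual acquisition profile
#'
#' Describes the clear-sky observation record of one year: the expected
#' number of clear observations and a 52-week seasonal weighting of when
#' they fall. The defaults mirror the two epochs of the optical archive:
#' sparse Landsat-only years (~8 clear obs/yr) and dense years once
#' Sentinel-2 operates (~30 clear obs/yr from 2015).
#'
#' @param year calendar year.
#' @param expected_clear_obs expected clear observations in the year (> 0).
#' @param weights nonnegative length-52 seasonal weights (normalised
#'   internally; default uniform).
#' @return object of class `acquisition_profile`.
#' @export
acquisition_profile <- function(year, expected_clear_obs,
                                weights = rep(1, 52)) {
  stopifnot(expected_clear_obs > 0, length(weights) == 52,
            all(weights >= 0), sum(weights) > 0)
  structure(list(year = year,
                 expected_clear_obs = expected_clear_obs,
                 weights = weights / sum(weights)),
            class = "acquisition_profile")
}

#' Default year-dependent acquisition profiles
#'
#' @param years calendar years.
#' @param sparse_rate,dense_rate expected clear obs/yr before and from
#'   `dense_from`.
#' @param dense_from first dense (Sentinel-2 era) year.
#' @return named list of [acquisition_profile()]s.
#' @export
default_acquisition_profiles <- function(years, sparse_rate = 8,
                                         dense_rate = 30, dense_from = 2015) {
  out <- lapply(years, function(y) {
    acquisition_profile(y, if (y >= dense_from) dense_rate else sparse_rate)
  })
  names(out) <- as.character(years)
  out
}

#' Draw clear-sky acquisition dates for one year
#'
#' The number of observations is Poisson with the profile's rate; dates are
#' distinct days of year drawn (without replacement) with per-day
#' probability proportional to the week's seasonal weight. All returned
#' dates are clear-sky.
#'
#' @param profile an [acquisition_profile()].
#' @param seed optional integer seed.
#' @return sorted integer vector of days of year (possibly empty).
#' @export
simulate_acquisitions <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "acquisition_profile"))
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, profile$expected_clear_obs)
  if (n == 0L) return(integer(0))
  n <- min(n, 365L)
  wk <- week_of_doy(1:365)                       # 0..51; week 51 has 8 days
  days_in_week <- tabulate(wk + 1L, 52L)
  p_day <- profile$weights[wk + 1L] / days_in_week[wk + 1L]
  sort(sample.int(365L, n, replace = FALSE, prob = p_day))
}
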
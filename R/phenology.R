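#' Double-logistic phenology model for one land-cover class
#'
#' Annual reflectance dynamics of a class are modelled per band as
#' \deqn{v(t) = base + amp \left[\sigma(k_g (t - t_g)) - \sigma(k_s (t - t_s))\right]}
#' with \eqn{\sigma} the logistic function, green-up day \eqn{t_g} <
#' senescence day \eqn{t_s}, and additive Gaussian observation noise —
#' the standard double-logistic form for vegetation seasonality.
#'
#' @param class_code legend code 1-18.
#' @param base numeric length-6, off-season reflectance per band
#'   (red, green, blue, nir, swir1, swir2).
#' @param amplitude numeric length-6, seasonal amplitude per band (may be
#'   negative, e.g. red dims under a closed canopy); `base` and
#'   `base + amplitude` must lie in `[0, 1]`.
#' @param greenup_doy,senescence_doy season start/end days (greenup < senescence).
#' @param slope_up,slope_down logistic slopes (1/day).
#' @param noise_sd observation noise s.d. (reflectance fraction).
#' @return object of class `phenology_model`.
#' @export
phenology_model <- function(class_code, base, amplitude, greenup_doy,
                            senescence_doy, slope_up = 0.10,
                            slope_down = 0.08, noise_sd = 0.02) {
  stopifnot(length(base) == 6, length(amplitude) == 6,
            all(base >= 0 & base <= 1), all(base + amplitude >= 0),
            all(base + amplitude <= 1),
            greenup_doy < senescence_doy, noise_sd >= 0)
  structure(list(class_code = as.integer(class_code), base = base,
                 amplitude = amplitude, greenup_doy = greenup_doy,
                 senescence_doy = senescence_doy, slope_up = slope_up,
                 slope_down = slope_down, noise_sd = noise_sd),
            class = "phenology_model")
}

#' Evaluate the noise-free double-logistic curve
#'
#' @param model a [phenology_model()].
#' @param doy day(s) of year.
#' @return matrix `length(doy)` x 6 of band reflectances (unclipped form is
#'   already within `[0, 1]` by the constructor's constraints).
#' @export
phenology_curve <- function(model, doy) {
  s <- stats::plogis(model$slope_up * (doy - model$greenup_doy)) -
    stats::plogis(model$slope_down * (doy - model$senescence_doy))
  out <- outer(s, model$amplitude) +
    matrix(model$base, length(doy), 6, byrow = TRUE)
  colnames(out) <- LC_BANDS[1:6]
  out
}

#' Simulate one pixel-year of observations from a phenology model
#'
#' Band values are the double-logistic curve at each date plus Gaussian
#' noise, clipped to `[0, 1]`; indices are derived downstream by
#' [observation_series()].
#'
#' @param model a [phenology_model()].
#' @param dates integer days of year (will be sorted, must be distinct).
#' @param year calendar year tag for the series.
#' @param seed optional integer seed.
#' @return an [observation_series()]; empty `dates` yield an empty series.
#' @export
simulate_phenology <- function(model, dates, year = NA_integer_, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dates <- sort(as.integer(dates))
  if (length(dates) == 0L) {
    return(observation_series(year, integer(0),
                              matrix(numeric(0), 0, 6)))
  }
  v <- phenology_curve(model, dates)
  if (model$noise_sd > 0) {
    v <- v + matrix(stats::rnorm(length(v), 0, model$noise_sd),
                    nrow(v), ncol(v))
  }
  v[v < 0] <- 0
  v[v > 1] <- 1
  observation_series(year, dates, v)
}

#' Default per-class phenology models
#'
#' A package-default parameter table giving each of the eighteen classes a
#' distinct, learnable annual signature: stable surfaces (built-up,
#' bareland, water) are flat with characteristic band levels; forests,
#' shrubs and wetlands differ in amplitude, base and season length; the
#' eight crop types differ chiefly in sowing/harvest timing (winter vs
#' spring cereals, late-season maize and root crops), with grassland green
#' over the whole season. The defaults claim class separability, not
#' spectral realism.
#'
#' @param noise_sd observation noise s.d. applied to every class.
#' @return named list of 18 [phenology_model()]s, names = class codes.
#' @export
default_phenologies <- function(noise_sd = 0.02) {
  #              red   green blue  nir   swir1 swir2
  p <- list(
    list(1, c(0.18, 0.17, 0.15, 0.22, 0.25, 0.22), rep(0, 6), 100, 300),
    list(2, c(0.28, 0.26, 0.24, 0.33, 0.38, 0.35), rep(0, 6), 100, 300),
    list(3, c(0.03, 0.05, 0.06, 0.02, 0.01, 0.01), rep(0, 6), 100, 300),
    list(4, c(0.11, 0.09, 0.07, 0.22, 0.26, 0.22),
         c(-0.03, -0.01, -0.01, 0.08, -0.03, -0.03), 115, 285),
    list(5, c(0.05, 0.06, 0.04, 0.28, 0.12, 0.10),
         c(-0.01, 0.00, 0.00, 0.05, -0.02, -0.02), 100, 300),
    list(6, c(0.08, 0.08, 0.06, 0.15, 0.18, 0.12),
         c(-0.04, -0.02, -0.02, 0.30, -0.06, -0.05), 120, 280),
    list(7, c(0.07, 0.08, 0.06, 0.18, 0.10, 0.08),
         c(-0.03, -0.02, -0.01, 0.15, -0.04, -0.03), 130, 270),
    list(8, c(0.08, 0.10, 0.08, 0.14, 0.20, 0.18),
         c(-0.02, -0.01, 0.00, 0.12, -0.04, -0.04), 140, 260),
    list(9, c(0.07, 0.08, 0.06, 0.20, 0.14, 0.11),
         c(-0.02, -0.01, -0.01, 0.10, -0.03, -0.03), 120, 290),
    # crops: winter cereals green up early, spring cereals later,
    # maize/root crops late and long, rapeseed with a green bloom signal
    list(10, c(0.16, 0.14, 0.12, 0.18, 0.30, 0.26),
         c(-0.10, -0.05, -0.05, 0.38, -0.14, -0.12), 95, 205),
    list(11, c(0.16, 0.14, 0.12, 0.18, 0.31, 0.27),
         c(-0.10, -0.05, -0.05, 0.36, -0.14, -0.12), 125, 215),
    list(12, c(0.16, 0.14, 0.12, 0.18, 0.29, 0.25),
         c(-0.10, -0.05, -0.05, 0.34, -0.13, -0.11), 80, 190),
    list(13, c(0.16, 0.14, 0.12, 0.18, 0.32, 0.28),
         c(-0.10, -0.05, -0.05, 0.36, -0.14, -0.12), 135, 230),
    list(14, c(0.17, 0.15, 0.13, 0.19, 0.33, 0.29),
         c(-0.11, -0.06, -0.05, 0.40, -0.15, -0.13), 165, 285),
    list(15, c(0.16, 0.14, 0.12, 0.18, 0.30, 0.26),
         c(-0.10, 0.08, -0.04, 0.36, -0.13, -0.11), 105, 215),
    list(16, c(0.17, 0.15, 0.13, 0.19, 0.31, 0.27),
         c(-0.11, -0.05, -0.05, 0.38, -0.14, -0.12), 150, 295),
    list(17, c(0.16, 0.14, 0.12, 0.18, 0.28, 0.24),
         c(-0.10, -0.05, -0.04, 0.35, -0.13, -0.11), 140, 250),
    list(18, c(0.09, 0.11, 0.07, 0.17, 0.19, 0.15),
         c(-0.05, -0.03, -0.02, 0.28, -0.08, -0.07), 85, 310)
  )
  out <- lapply(p, function(q) {
    phenology_model(q[[1]], q[[2]], q[[3]], q[[4]], q[[5]],
                    noise_sd = noise_sd)
  })
  names(out) <- vapply(out, function(m) as.character(m$class_code), "")
  out
}
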
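#' Synthetic reference-product code dictionaries
#'
#' Package constants mapping truth classes to the class codes of the two
#' synthetic categorical reference products: a coarse land-cover inventory
#' ("clc_code", CORINE-like) and a finer protected-sites product
#' ("n2k_code") that separates exploited from unexploited peat bog. Real
#' product code lists are out of scope; these dictionaries only preserve
#' the semantics the sampling rules need.
#'
#' @return list with elements `clc` and `n2k`, each an integer vector
#'   indexed by truth code 1-18, plus the subclass sets used by rules.
#' @export
reference_code_tables <- function() {
  clc <- c(111L, 331L, 511L, 322L, 312L, 311L, 411L, 412L, 412L,
           rep(211L, 8), 231L)
  n2k <- c(1100L, 3300L, 5100L, 3220L, 3120L, 3110L, 4110L, 4120L, 4130L,
           rep(2110L, 8), 2310L)
  list(
    clc = clc, n2k = n2k,
    clc_shrub = c(322L, 323L, 324L),        # moors/heath, sclerophyllous, transitional
    n2k_shrub = c(3220L, 3230L, 3240L),
    clc_marsh = c(411L, 421L),              # inland marsh, salt marsh
    n2k_marsh = c(4110L, 4210L),
    clc_bog = 412L,
    n2k_exploited = 4120L, n2k_unexploited = 4130L,
    clc_cropgrass = c(211L, 231L, 321L),    # arable, pasture, natural grassland
    n2k_cropgrass = c(2110L, 2310L, 3210L),
    forest_type = c(nonforest = 0L, broadleaf = 1L, coniferous = 2L)
  )
}

#' Multi-year reference-product stack
#'
#' @param products named list: product name (`imperviousness`,
#'   `tree_density`, `forest_type`, `clc_code`, `n2k_code`) -> named list of
#'   per-year matrices (names = years).
#' @param stm named list of period spectral-temporal-metric matrices
#'   (`ndvi_p10`, `ndvi_p90`, `ndwi_p10`, `ndwi_p90`).
#' @param pixel_size,xmin,ymax,crs_code georeference.
#' @return object of class `reference_stack`.
#' @export
reference_stack <- function(products, stm = list(), pixel_size = 30,
                            xmin = 0, ymax = NULL, crs_code = "EPSG:3035") {
  d <- dim(products[[1]][[1]])
  for (p in products) for (m in p) stopifnot(all(dim(m) == d))
  for (m in stm) stopifnot(all(dim(m) == d))
  if (is.null(ymax)) ymax <- d[1] * pixel_size
  structure(list(products = products, stm = stm, dim = d,
                 pixel_size = pixel_size, xmin = xmin, ymax = ymax,
                 crs_code = crs_code),
            class = "reference_stack")
}

#' Simulate reference products from a truth label cube
#'
#' Builds the synthetic stand-ins driving the sampling rules:
#' imperviousness high (80) on built-up and 0 elsewhere, tree-cover density
#' 90 on forest / 15 on shrubland / 0 elsewhere, forest-type codes, and
#' CLC-like and N2K-like code rasters from [reference_code_tables()].
#' Continuous products are contaminated (uniform redraw) with probability
#' `contamination` per pixel-year; categorical products disagree with the
#' relabeled truth (random other code) with probability `disagreement`.
#' Spectral-temporal metric layers are the noise-free closed-form
#' percentiles of each class's phenology (see [stm_from_phenology()]).
#'
#' @param truth an [lc_cube()] covering (or bracketing) the product years.
#' @param years named list of integer year vectors per product; default
#'   the standard reference epochs.
#' @param contamination,disagreement rates in `[0, 1]`.
#' @param phenologies phenology set for the closed-form STM layers.
#' @param seed optional integer seed.
#' @return a [reference_stack()].
#' @export
simulate_reference_products <- function(truth,
                                        years = list(
                                          imperviousness = c(2006, 2009, 2012, 2015, 2018),
                                          tree_density = c(2012, 2015, 2018),
                                          forest_type = c(2006, 2012, 2015, 2018),
                                          clc_code = c(2006, 2012, 2018),
                                          n2k_code = c(2006, 2012, 2018)),
                                        contamination = 0, disagreement = 0,
                                        phenologies = default_phenologies(),
                                        seed = NULL) {
  stopifnot(inherits(truth, "lc_cube"))
  if (!is.null(seed)) set.seed(seed)
  tabs <- reference_code_tables()
  truth_at <- function(y) {
    k <- which.min(abs(truth$years - y))
    truth$values[, , k]
  }
  contaminate <- function(m, rate, redraw) {
    if (rate > 0) {
      hit <- stats::runif(length(m)) < rate
      m[hit] <- redraw(sum(hit))
    }
    m
  }
  recode <- function(tr, lut, rate) {
    m <- matrix(lut[tr], nrow(tr), ncol(tr))
    if (rate > 0) {
      hit <- which(stats::runif(length(m)) < rate)
      pool <- unique(lut)
      for (i in hit) {
        m[i] <- sample(setdiff(pool, m[i]), 1L)
      }
    }
    m
  }
  per_year <- function(ys, fun) {
    out <- lapply(ys, fun)
    names(out) <- as.character(ys)
    out
  }
  products <- list(
    imperviousness = per_year(years$imperviousness, function(y) {
      tr <- truth_at(y)
      contaminate(ifelse(tr == 1L, 80, 0), contamination,
                  function(n) stats::runif(n, 0, 100))
    }),
    tree_density = per_year(years$tree_density, function(y) {
      tr <- truth_at(y)
      m <- matrix(0, nrow(tr), ncol(tr))
      m[tr == 5L | tr == 6L] <- 90
      m[tr == 4L] <- 15
      contaminate(m, contamination, function(n) stats::runif(n, 0, 100))
    }),
    forest_type = per_year(years$forest_type, function(y) {
      tr <- truth_at(y)
      m <- matrix(0L, nrow(tr), ncol(tr))
      m[tr == 6L] <- 1L
      m[tr == 5L] <- 2L
      contaminate(m, contamination, function(n) sample(0:2, n, replace = TRUE))
    }),
    clc_code = per_year(years$clc_code, function(y) {
      recode(truth_at(y), tabs$clc, disagreement)
    }),
    n2k_code = per_year(years$n2k_code, function(y) {
      recode(truth_at(y), tabs$n2k, disagreement)
    })
  )
  stm <- stm_from_phenology(truth_at(stats::median(truth$years)), phenologies)
  reference_stack(products, stm, pixel_size = truth$pixel_size,
                  xmin = truth$xmin, ymax = truth$ymax,
                  crs_code = truth$crs_code)
}

#' Closed-form spectral-temporal metric layers from phenologies
#'
#' Noise-free NDVI/NDWI 10th and 90th percentiles per pixel, computed from
#' the daily double-logistic curve of the pixel's class (linear-interpolation
#' percentile over days 1-365).
#'
#' @param class_map integer truth matrix.
#' @param phenologies named list of [phenology_model()]s.
#' @return named list of matrices `ndvi_p10`, `ndvi_p90`, `ndwi_p10`,
#'   `ndwi_p90`.
#' @export
stm_from_phenology <- function(class_map, phenologies) {
  classes <- sort(unique(as.vector(class_map)))
  classes <- classes[classes >= 1]
  per_class <- lapply(classes, function(cc) {
    v <- phenology_curve(phenologies[[as.character(cc)]], 1:365)
    idx <- compute_indices(red = v[, 1], green = v[, 2], blue = v[, 3],
                           nir = v[, 4], swir1 = v[, 5], swir2 = v[, 6])
    c(ndvi_p10 = stats::quantile(idx$ndvi, 0.10, names = FALSE),
      ndvi_p90 = stats::quantile(idx$ndvi, 0.90, names = FALSE),
      ndwi_p10 = stats::quantile(idx$ndwi, 0.10, names = FALSE),
      ndwi_p90 = stats::quantile(idx$ndwi, 0.90, names = FALSE))
  })
  lut <- do.call(rbind, per_class)
  rownames(lut) <- as.character(classes)
  out <- lapply(colnames(lut), function(nm) {
    m <- matrix(NA_real_, nrow(class_map), ncol(class_map))
    ok <- class_map >= 1
    m[ok] <- lut[as.character(class_map[ok]), nm]
    m
  })
  names(out) <- colnames(lut)
  out
}
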
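#' Default crop rotation matrix
#'
#' Year-to-year transition probabilities among the nine cropland/grassland
#' classes (codes 10-18). Arable crops (10-17) persist with probability
#' `p_stay` and otherwise rotate uniformly to another arable crop;
#' grassland is persistent.
#'
#' @param p_stay probability an arable crop pixel keeps its class.
#' @return 9 x 9 row-stochastic matrix with dimnames "10".."18".
#' @export
default_rotation_matrix <- function(p_stay = 0.4) {
  codes <- as.character(10:18)
  m <- matrix(0, 9, 9, dimnames = list(codes, codes))
  for (i in 1:8) {
    m[i, ] <- c(rep((1 - p_stay) / 7, 8), 0)
    m[i, i] <- p_stay
  }
  m[9, 9] <- 1
  m
}

#' Synthetic scene configuration
#'
#' @param rows,cols grid size in pixels.
#' @param years calendar years to simulate.
#' @param mean_patch_pixels mean landscape patch size (pixels) controlling
#'   the patchiness of the class map.
#' @param rotation_matrix 9 x 9 row-stochastic matrix over codes 10-18
#'   (see [default_rotation_matrix()]).
#' @param peat_expansion_rate unexploited-bog pixels converted to exploited
#'   bog per year.
#' @param profiles named list of [acquisition_profile()] per year (default
#'   [default_acquisition_profiles()]).
#' @param phenologies named list of 18 [phenology_model()]s (default
#'   [default_phenologies()]).
#' @param classes class codes present in the scene (default all 18).
#' @param init_map optional fixed first-year class matrix (`rows` x `cols`)
#'   overriding the random patch generator — useful for structured test
#'   stands.
#' @param seed integer seed.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(rows = 40, cols = 40, years = 2013:2018,
                         mean_patch_pixels = 40,
                         rotation_matrix = default_rotation_matrix(),
                         peat_expansion_rate = 2,
                         profiles = default_acquisition_profiles(years),
                         phenologies = default_phenologies(),
                         classes = 1:18, init_map = NULL, seed = 1L) {
  if (!is.null(init_map)) {
    stopifnot(is.matrix(init_map), nrow(init_map) == rows,
              ncol(init_map) == cols)
  }
  stopifnot(rows >= 3, cols >= 3, length(years) >= 1,
            all(dim(rotation_matrix) == c(9, 9)),
            max(abs(rowSums(rotation_matrix) - 1)) < 1e-8,
            all(rotation_matrix >= 0), peat_expansion_rate >= 0)
  structure(list(rows = rows, cols = cols, years = as.integer(years),
                 mean_patch_pixels = mean_patch_pixels,
                 rotation_matrix = rotation_matrix,
                 peat_expansion_rate = peat_expansion_rate,
                 profiles = profiles, phenologies = phenologies,
                 classes = as.integer(classes), init_map = init_map,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# patchy class map: Voronoi tessellation of seeded patch centers, classes
# assigned to patches cycling through the class list so all are present;
# the patch (field) partition is returned alongside because crop rotation
# operates per field, not per pixel
patchy_class_map <- function(rows, cols, classes, mean_patch_pixels) {
  n_patch <- max(length(classes), round(rows * cols / mean_patch_pixels))
  cy <- stats::runif(n_patch, 0.5, rows + 0.5)
  cx <- stats::runif(n_patch, 0.5, cols + 0.5)
  patch_class <- rep(sample(classes), length.out = n_patch)
  py <- rep(seq_len(rows), cols)
  px <- rep(seq_len(cols), each = rows)
  d2 <- outer(py, cy, "-")^2 + outer(px, cx, "-")^2
  patch <- matrix(max.col(-d2), rows, cols)
  list(class_map = matrix(patch_class[patch], rows, cols),
       patch_map = patch)
}

# 4-connected components of equal-valued cells (fields of a supplied map)
connected_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  for (start in seq_along(m)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0L) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (p - 1L) %% nrow(m) + 1L
      j <- (p - 1L) %/% nrow(m) + 1L
      for (q in c(if (i > 1L) p - 1L, if (i < nrow(m)) p + 1L,
                  if (j > 1L) p - nrow(m), if (j < ncol(m)) p + nrow(m))) {
        if (lab[q] == 0L && m[q] == m[p]) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Simulate a synthetic scene
#'
#' Generates a multi-year truth label cube and per-pixel observation
#' series. Non-crop classes are persistent; cropland/grassland fields
#' (patches) rotate as units following the configured rotation matrix;
#' unexploited-bog pixels convert to exploited bog at
#' `peat_expansion_rate` pixels/year (capped, with a warning, by the
#' available bog pixels). Reflectances are drawn from each pixel's class
#' phenology at acquisition dates drawn from the year's profile.
#'
#' @param config a [scene_config()].
#' @param observations generate observation series (set `FALSE` for
#'   label-only scenes).
#' @return list with elements `truth` (an [lc_cube()]), `series` (list
#'   indexed `[[pixel]][[year index]]` of [observation_series()]; pixels in
#'   column-major order), `patch_map` (the field partition used for
#'   rotation), and `config`.
#' @export
simulate_landscape <- function(config, observations = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  rows <- config$rows; cols <- config$cols
  years <- config$years; ny <- length(years)
  truth <- array(0L, c(rows, cols, ny))
  if (is.null(config$init_map)) {
    pm <- patchy_class_map(rows, cols, config$classes,
                           config$mean_patch_pixels)
    truth[, , 1] <- pm$class_map
    patch_map <- pm$patch_map
  } else {
    truth[, , 1] <- config$init_map
    patch_map <- connected_components(config$init_map)
  }
  rot <- config$rotation_matrix
  for (k in seq_len(ny)[-1]) {
    prev <- truth[, , k - 1]
    cur <- prev
    # crop rotation: each field (patch) rotates as one unit
    crop_patches <- unique(patch_map[prev >= 10L & prev <= 18L])
    for (pid in crop_patches) {
      sel <- which(patch_map == pid & prev >= 10L & prev <= 18L)
      c0 <- prev[sel[1]]
      cur[sel] <- 9L + sample.int(9L, 1L, prob = rot[c0 - 9L, ])
    }
    # peat exploitation expansion
    r <- config$peat_expansion_rate
    if (r > 0) {
      unexp <- which(cur == 9L)
      n_conv <- min(round(r), length(unexp))
      if (n_conv < round(r)) {
        warning("peat_expansion_rate exceeds remaining unexploited bog; capped")
      }
      if (n_conv > 0L) {
        cur[sample(unexp, n_conv)] <- 8L
      }
    }
    truth[, , k] <- cur
  }
  cube <- lc_cube(truth, years, pixel_size = 30)
  out <- list(truth = cube, series = NULL, patch_map = patch_map,
              config = config)
  if (observations) {
    phen <- config$phenologies
    series <- vector("list", rows * cols)
    for (p in seq_len(rows * cols)) series[[p]] <- vector("list", ny)
    for (k in seq_len(ny)) {
      prof <- config$profiles[[as.character(years[k])]]
      lab <- truth[, , k]
      for (p in seq_len(rows * cols)) {
        dates <- simulate_acquisitions(prof)
        series[[p]][[k]] <- simulate_phenology(phen[[as.character(lab[p])]],
                                               dates, year = years[k])
      }
    }
    out$series <- series
  }
  out
}
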
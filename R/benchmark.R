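#' Split scene pixels into training and held-out sets
#'
#' Stratified by the pixel's first-year class so every class is present on
#' both sides.
#'
#' @param scene output of [simulate_landscape()].
#' @param train_frac fraction of pixels used for training.
#' @param seed integer seed.
#' @return list with integer pixel indices `train` and `test`
#'   (column-major scene order).
#' @export
split_pixels <- function(scene, train_frac = 0.7, seed = 1L) {
  set.seed(seed)
  lab <- as.vector(scene$truth$values[, , 1])
  train <- integer(0)
  for (cc in sort(unique(lab))) {
    idx <- which(lab == cc)
    n_tr <- max(1L, round(train_frac * length(idx)))
    train <- c(train, sample(idx, n_tr))
  }
  list(train = sort(train),
       test = setdiff(seq_along(lab), train))
}

#' Assemble the three hierarchical training sets from truth labels
#'
#' Level-1 samples are one per pixel (the Level-1 class is invariant under
#' crop rotation and peat-bog conversion) and carry all annual series, so
#' training draws a year per epoch. The two Level-2 specialists are
#' trained on single-year samples: wetland-subtype pixel-years (codes
#' 7-9) and cropland/grassland pixel-years (codes 10-18), since those
#' labels change between years.
#'
#' @param scene output of [simulate_landscape()].
#' @param pixels pixel indices to use (default all).
#' @param level1_pixel_years build the Level-1 set from pixel-years (one
#'   single-year sample per pixel and year, the default) rather than one
#'   multi-year sample per pixel with a year drawn per epoch; the former
#'   gives the optimiser proportionally more steps on small scenes.
#' @return list of [make_training_set()]s: `level1`, `wetland`, `crop`.
#' @export
build_hierarchical_training <- function(scene, pixels = NULL,
                                        level1_pixel_years = TRUE) {
  tr <- scene$truth
  npix <- prod(dim(tr$values)[1:2])
  if (is.null(pixels)) pixels <- seq_len(npix)
  ny <- length(tr$years)
  lab1 <- level1_of(as.vector(tr$values[, , 1]))
  l1 <- if (level1_pixel_years) {
    make_training_set(
      rep(lab1[pixels], ny),
      unlist(lapply(seq_len(ny), function(k) {
        lapply(pixels, function(p) scene$series[[p]][k])
      }), recursive = FALSE))
  } else {
    make_training_set(lab1[pixels], scene$series[pixels])
  }
  wet_lab <- integer(0); wet_series <- list()
  crop_lab <- integer(0); crop_series <- list()
  for (k in seq_len(ny)) {
    labk <- as.vector(tr$values[, , k])[pixels]
    w <- which(labk %in% 7:9)
    if (length(w)) {
      wet_lab <- c(wet_lab, labk[w])
      wet_series <- c(wet_series,
                      lapply(pixels[w], function(p) scene$series[[p]][k]))
    }
    cr <- which(labk %in% 10:18)
    if (length(cr)) {
      crop_lab <- c(crop_lab, labk[cr])
      crop_series <- c(crop_series,
                       lapply(pixels[cr], function(p) scene$series[[p]][k]))
    }
  }
  list(level1 = l1,
       wetland = make_training_set(wet_lab, wet_series),
       crop = make_training_set(crop_lab, crop_series))
}

#' Train the full hierarchical classifier
#'
#' @param sets output of [build_hierarchical_training()].
#' @param model_args overrides passed to [cnn_spec()] for all three models.
#' @param seed integer seed (specialists get derived seeds).
#' @return an [hierarchy_spec()].
#' @export
train_hierarchy <- function(sets, model_args = list(), seed = 1L) {
  mk <- function(n) do.call(cnn_spec, c(list(n_classes = n), model_args))
  hierarchy_spec(
    train(mk(8), sets$level1, seed = seed),
    train(mk(3), sets$wetland, seed = seed + 1L),
    train(mk(9), sets$crop, seed = seed + 2L)
  )
}

#' Predict annual Level-2 maps for a whole scene
#'
#' @param h an [hierarchy_spec()].
#' @param scene output of [simulate_landscape()].
#' @return an [lc_cube()] of predicted codes.
#' @export
predict_scene <- function(h, scene) {
  tr <- scene$truth
  d <- dim(tr$values)
  pred <- array(0L, d)
  for (k in seq_len(d[3])) {
    X <- encode_weekly_batch(lapply(scene$series, `[[`, k))
    pred[, , k] <- matrix(hierarchical_predict(h, X), d[1], d[2])
  }
  lc_cube(pred, tr$years, xmin = tr$xmin, ymax = tr$ymax,
          pixel_size = tr$pixel_size, crs_code = tr$crs_code)
}

#' Pixel-year accuracy of predicted maps against truth
#'
#' @param pred,truth [lc_cube()]s on the same grid and years.
#' @param pixels pixel indices to score (default all).
#' @return list: `oa` (overall accuracy over pixel-years), `f1` (per-class
#'   F1), `confusion` (18 x 18 count matrix).
#' @export
scene_accuracy <- function(pred, truth, pixels = NULL) {
  stopifnot(identical(dim(pred$values), dim(truth$values)))
  d <- dim(pred$values)
  npix <- d[1] * d[2]
  if (is.null(pixels)) pixels <- seq_len(npix)
  p <- c(); t_ <- c()
  for (k in seq_len(d[3])) {
    p <- c(p, as.vector(pred$values[, , k])[pixels])
    t_ <- c(t_, as.vector(truth$values[, , k])[pixels])
  }
  keep <- t_ >= 1L & p >= 1L
  p <- p[keep]; t_ <- t_[keep]
  conf <- table(factor(p, levels = 1:18), factor(t_, levels = 1:18))
  conf <- matrix(as.numeric(conf), 18, 18, dimnames = list(map = 1:18,
                                                           reference = 1:18))
  em <- error_matrix(conf, mapped_areas = pmax(rowSums(conf), 1e-9),
                     classes = 1:18)
  list(oa = mean(p == t_), f1 = f1_scores(em), confusion = conf)
}
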
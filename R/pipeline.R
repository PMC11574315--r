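#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs. A single global seed fans
#' out to per-stage seeds (a stable hash of stage name + seed) so each
#' stage is independently reproducible.
#'
#' @param workdir directory for stage artifacts and manifests.
#' @param scene a [scene_config()].
#' @param invariant_cap,crop_cap sampling caps per class (10,000 for the
#'   rule-mined invariant classes, 50,000 for crops).
#' @param model_args list of overrides passed to [cnn_spec()] for all
#'   three models (e.g. `list(epochs = 10)` for quick runs).
#' @param filters apply the post-processing bundles.
#' @param val_n_per_stratum validation points per mapped class.
#' @param val_year year to validate (default last scene year).
#' @param seed global integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(workdir = tempfile("lcpipe"),
                            scene = scene_config(),
                            invariant_cap = 10000, crop_cap = 50000,
                            model_args = list(), filters = TRUE,
                            val_n_per_stratum = 50, val_year = NULL,
                            seed = 1L) {
  structure(list(workdir = workdir, scene = scene,
                 invariant_cap = invariant_cap, crop_cap = crop_cap,
                 model_args = model_args, filters = filters,
                 val_n_per_stratum = val_n_per_stratum,
                 val_year = if (is.null(val_year)) max(scene$years) else val_year,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# stable per-stage seed: polynomial string hash of the stage name folded
# with the global seed, kept inside 32-bit integer range
stage_seed <- function(name, seed) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((h * 7919 + seed) %% .Machine$integer.max)
}

stage_path <- function(config, name, ext = ".rds") {
  file.path(config$workdir, paste0(name, ext))
}

write_manifest <- function(config, name, info) {
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  info$stage <- name
  info$seed <- stage_seed(name, config$seed)
  info$global_seed <- config$seed
  info$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(info, stage_path(config, name, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

load_stage <- function(config, name, needed_by) {
  p <- stage_path(config, name)
  if (!file.exists(p)) {
    stop("stage '", needed_by, "' needs artifact of stage '", name,
         "': run run_stage(\"", name, "\", config) first")
  }
  readRDS(p)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic scene), `sample` (rule mining + crop
#' sampling), `encode` (training sets), `train` (the three hierarchical
#' models), `predict` (annual Level-2 maps), `postprocess` (filter
#' bundles), `validate` (stratified accuracy report). Each stage writes
#' its artifact and a JSON manifest (seed, parameters, counts) into
#' `config$workdir`.
#'
#' @param name stage name.
#' @param config a [pipeline_config()].
#' @return the stage output, invisibly.
#' @export
run_stage <- function(name = c("simulate", "sample", "encode", "train",
                               "predict", "postprocess", "validate"),
                      config) {
  name <- match.arg(name)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(name,
                simulate = stage_simulate(config),
                sample = stage_sample(config),
                encode = stage_encode(config),
                train = stage_train(config),
                predict = stage_predict(config),
                postprocess = stage_postprocess(config),
                validate = stage_validate(config))
  invisible(out)
}

stage_simulate <- function(config) {
  sc <- config$scene
  sc$seed <- stage_seed("simulate", config$seed)
  scene <- simulate_landscape(sc)
  saveRDS(scene, stage_path(config, "simulate"))
  write_manifest(config, "simulate",
                 list(rows = sc$rows, cols = sc$cols,
                      years = sc$years,
                      n_pixels = sc$rows * sc$cols,
                      n_series = length(scene$series) * length(sc$years)))
  scene
}

stage_sample <- function(config) {
  scene <- load_stage(config, "simulate", "sample")
  set.seed(stage_seed("sample", config$seed))
  stack <- simulate_reference_products(scene$truth,
                                       phenologies = config$scene$phenologies)
  rules <- builtin_rules()
  invariant <- list()
  for (rn in names(rules)) {
    mask <- evaluate_rule(stack, rules[[rn]])
    pts <- sample_points(mask, cap = config$invariant_cap,
                         code = rules[[rn]]$target_code,
                         pixel_size = scene$truth$pixel_size,
                         xmin = scene$truth$xmin, ymax = scene$truth$ymax)
    pts$rule <- rn
    pts$level <- rules[[rn]]$target_level
    invariant[[rn]] <- pts
  }
  invariant <- do.call(rbind, invariant)
  # crop reference: per-year labeled pixels (crop-parcel survey stand-in)
  crop <- list()
  tr <- scene$truth
  for (k in seq_along(tr$years)) {
    lab <- tr$values[, , k]
    for (code in 10:18) {
      idx <- which(lab == code)
      if (length(idx) == 0L) next
      if (length(idx) > config$crop_cap) idx <- sample(idx, config$crop_cap)
      row <- (idx - 1L) %% nrow(lab) + 1L
      col <- (idx - 1L) %/% nrow(lab) + 1L
      crop[[length(crop) + 1L]] <- data.frame(
        x = tr$xmin + (col - 0.5) * tr$pixel_size,
        y = tr$ymax - (row - 0.5) * tr$pixel_size,
        year = tr$years[k], code = code, row = row, col = col,
        rule = "crop_reference", level = 2L)
    }
  }
  crop <- do.call(rbind, crop)
  out <- list(invariant = invariant, crop = crop)
  saveRDS(out, stage_path(config, "sample"))
  write_manifest(config, "sample",
                 list(n_invariant = nrow(invariant), n_crop = nrow(crop),
                      invariant_cap = config$invariant_cap,
                      crop_cap = config$crop_cap))
  out
}

pixel_index <- function(scene, row, col) {
  (col - 1L) * scene$config$rows + row
}

stage_encode <- function(config) {
  scene <- load_stage(config, "simulate", "encode")
  pts <- load_stage(config, "sample", "encode")
  inv <- pts$invariant
  # Level-1 labels: wetland subtypes -> 7, cropland/grassland rule -> 8
  l1_label <- ifelse(inv$level == 1L, inv$code, level1_of(inv$code))
  pix <- pixel_index(scene, inv$row, inv$col)
  l1_set <- make_training_set(l1_label, scene$series[pix])
  wet <- inv[inv$code %in% 7:9 & inv$level == 2L, ]
  wet_set <- if (nrow(wet) > 0L) {
    make_training_set(wet$code, scene$series[pixel_index(scene, wet$row, wet$col)])
  } else NULL
  crop <- pts$crop
  ky <- match(crop$year, scene$truth$years)
  crop_series <- lapply(seq_len(nrow(crop)), function(r) {
    scene$series[[pixel_index(scene, crop$row[r], crop$col[r])]][ky[r]]
  })
  crop_set <- make_training_set(crop$code, crop_series)
  out <- list(level1 = l1_set, wetland = wet_set, crop = crop_set)
  saveRDS(out, stage_path(config, "encode"))
  write_manifest(config, "encode",
                 list(n_level1 = l1_set$n,
                      n_wetland = if (is.null(wet_set)) 0L else wet_set$n,
                      n_crop = crop_set$n))
  out
}

stage_train <- function(config) {
  sets <- load_stage(config, "encode", "train")
  mk <- function(n_classes) {
    do.call(cnn_spec, c(list(n_classes = n_classes), config$model_args))
  }
  seed <- stage_seed("train", config$seed)
  l1 <- train(mk(8), sets$level1, seed = seed)
  wet <- train(mk(3), sets$wetland, seed = seed + 1L)
  crop <- train(mk(9), sets$crop, seed = seed + 2L)
  h <- hierarchy_spec(l1, wet, crop)
  saveRDS(h, stage_path(config, "train"))
  write_manifest(config, "train",
                 list(epochs = l1$spec$epochs,
                      conv_filters = l1$spec$conv_filters))
  h
}

stage_predict <- function(config) {
  scene <- load_stage(config, "simulate", "predict")
  h <- load_stage(config, "train", "predict")
  tr <- scene$truth
  ny <- length(tr$years)
  rows <- config$scene$rows; cols <- config$scene$cols
  pred <- array(0L, c(rows, cols, ny))
  for (k in seq_len(ny)) {
    X <- encode_weekly_batch(lapply(scene$series, `[[`, k))
    pred[, , k] <- matrix(hierarchical_predict(h, X), rows, cols)
  }
  cube <- lc_cube(pred, tr$years, xmin = tr$xmin, ymax = tr$ymax,
                  pixel_size = tr$pixel_size, crs_code = tr$crs_code)
  saveRDS(cube, stage_path(config, "predict"))
  write_manifest(config, "predict",
                 list(n_pixel_years = rows * cols * ny))
  cube
}

stage_postprocess <- function(config) {
  cube <- load_stage(config, "predict", "postprocess")
  before <- cube$values
  if (config$filters) cube <- postprocess_level2(cube)
  saveRDS(cube, stage_path(config, "postprocess"))
  write_manifest(config, "postprocess",
                 list(filters = config$filters,
                      n_changed = sum(cube$values != before)))
  cube
}

stage_validate <- function(config) {
  scene <- load_stage(config, "simulate", "validate")
  cube <- load_stage(config, "postprocess", "validate")
  set.seed(stage_seed("validate", config$seed))
  y <- config$val_year
  mapr <- cube_year(cube, y)
  truthr <- cube_year(scene$truth, y)
  px_km2 <- (cube$pixel_size / 1000)^2
  present <- sort(unique(as.vector(mapr$values)))
  present <- present[present >= 1L]
  mapped_areas <- vapply(present, function(cc) sum(mapr$values == cc) * px_km2, 0)
  names(mapped_areas) <- present
  # stratified reference sample: up to n per mapped stratum, truth as reference
  ref <- list()
  for (cc in present) {
    idx <- which(mapr$values == cc)
    take <- idx[sample.int(length(idx),
                           min(config$val_n_per_stratum, length(idx)))]
    row <- (take - 1L) %% nrow(mapr$values) + 1L
    col <- (take - 1L) %/% nrow(mapr$values) + 1L
    ref[[length(ref) + 1L]] <- data.frame(
      x = mapr$xmin + (col - 0.5) * mapr$pixel_size,
      y = mapr$ymax - (row - 0.5) * mapr$pixel_size,
      code = truthr$values[cbind(row, col)])
  }
  ref <- do.call(rbind, ref)
  em <- build_error_matrix(ref, mapr, mapped_areas)
  report <- olofsson_estimates(em)
  out <- list(error_matrix = em, report = report, f1 = f1_scores(em),
              year = y)
  saveRDS(out, stage_path(config, "validate"))
  write_manifest(config, "validate",
                 list(year = y, n_points = sum(em$counts),
                      oa = report$oa))
  out
}
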
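#' Georeferenced raster container
#'
#' A light in-memory raster: a numeric/integer matrix (rows run north to
#' south) plus the georeference needed for point lookups and tiling.
#' Rasters are written as TIFF images with an ESRI world file (`.tfw`)
#' carrying the affine geotransform and a JSON sidecar carrying the CRS code
#' and nodata value, so every artifact on disk is either standard imagery or
#' plain text.
#'
#' @param values matrix of cell values; `values[1, 1]` is the north-west cell.
#' @param xmin,ymax projected coordinates (m) of the raster's north-west corner.
#' @param pixel_size cell edge length (m).
#' @param crs_code CRS identifier string.
#' @param nodata value marking missing cells (default [LC_NODATA] for labels).
#' @return An object of class `lc_raster`.
#' @export
lc_raster <- function(values, xmin = 0, ymax = nrow(values) * pixel_size,
                      pixel_size = 30, crs_code = "EPSG:3035",
                      nodata = LC_NODATA) {
  stopifnot(is.matrix(values))
  structure(list(values = values, xmin = xmin, ymax = ymax,
                 pixel_size = pixel_size, crs_code = crs_code,
                 nodata = nodata),
            class = "lc_raster")
}

#' @export
print.lc_raster <- function(x, ...) {
  cat(sprintf("lc_raster: %d x %d cells, %g m pixels, NW corner (%g, %g), %s\n",
              nrow(x$values), ncol(x$values), x$pixel_size, x$xmin, x$ymax,
              x$crs_code))
  invisible(x)
}

sidecar_paths <- function(path) {
  base <- sub("\\.tiff?$", "", path, ignore.case = TRUE)
  list(tfw = paste0(base, ".tfw"), meta = paste0(base, ".meta.json"))
}

write_geo_sidecars <- function(r, path) {
  sc <- sidecar_paths(path)
  ps <- r$pixel_size
  # world file lines: x-scale, rot, rot, -y-scale, x and y of the UL pixel center
  writeLines(format(c(ps, 0, 0, -ps, r$xmin + ps / 2, r$ymax - ps / 2),
                    digits = 15, scientific = FALSE, trim = TRUE), sc$tfw)
  jsonlite::write_json(list(crs_code = r$crs_code, nodata = r$nodata,
                            pixel_size = r$pixel_size),
                       sc$meta, auto_unbox = TRUE, digits = NA)
}

read_geo_sidecars <- function(path) {
  sc <- sidecar_paths(path)
  if (!file.exists(sc$tfw)) stop("missing world file: ", sc$tfw)
  if (!file.exists(sc$meta)) {
    stop("missing CRS metadata sidecar: ", sc$meta)
  }
  w <- as.numeric(readLines(sc$tfw))
  meta <- jsonlite::read_json(sc$meta, simplifyVector = TRUE)
  if (is.null(meta$crs_code) || !nzchar(meta$crs_code)) {
    stop("CRS missing in sidecar: ", sc$meta)
  }
  list(pixel_size = w[1], ulx_center = w[5], uly_center = w[6], meta = meta)
}

#' Write a single-year label raster
#'
#' Byte-typed single-band TIFF of legend codes (1-18) with 0 as nodata,
#' plus world-file and CRS/nodata sidecars.
#'
#' @param raster an [lc_raster()] of integer codes in 1..18 or nodata (0).
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_label_raster <- function(raster, path) {
  stopifnot(inherits(raster, "lc_raster"))
  v <- raster$values
  validate_codes(v)
  if (anyNA(v)) stop("NA codes: use the nodata code ", LC_NODATA)
  ok <- tryCatch(tiff::writeTIFF(v / 255, path, bits.per.sample = 8L),
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  write_geo_sidecars(raster, path)
  invisible(path)
}

#' Read a single-year label raster
#'
#' @param path path to a single-band integer TIFF written by
#'   [write_label_raster()] (or any byte/16-bit single-band TIFF with the
#'   world-file + JSON sidecars).
#' @return an [lc_raster()] of integer codes.
#' @export
read_label_raster <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  v <- suppressWarnings(tiff::readTIFF(path, as.is = TRUE, info = TRUE))
  bps <- attr(v, "bits.per.sample")
  if (!is.null(bps) && bps > 16) stop("non-integer band in ", path)
  attributes(v) <- list(dim = dim(v))
  if (!is.matrix(v)) stop("expected a single-band raster: ", path)
  if (!is.integer(v)) stop("non-integer band in ", path)
  geo <- read_geo_sidecars(path)
  nodata <- if (is.null(geo$meta$nodata)) LC_NODATA else as.integer(geo$meta$nodata)
  validate_codes(v)
  ps <- geo$pixel_size
  lc_raster(v, xmin = geo$ulx_center - ps / 2, ymax = geo$uly_center + ps / 2,
            pixel_size = ps, crs_code = geo$meta$crs_code, nodata = nodata)
}

#' Write a continuous (float) raster
#'
#' 32-bit float TIFF with georeference sidecars; used for
#' reference-product and spectral-temporal-metric layers. TIFF float
#' samples are stored normalised to `[0, 1]`; the affine value transform
#' (minimum and scale) is recorded in the JSON sidecar and undone on read.
#' NA cells are carried in an extra mask band.
#'
#' @param raster an [lc_raster()] with a single-band matrix of values.
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_float_raster <- function(raster, path) {
  stopifnot(inherits(raster, "lc_raster"), is.matrix(raster$values))
  v <- raster$values
  na_mask <- is.na(v) | is.nan(v)
  fin <- v[!na_mask]
  vmin <- if (length(fin)) min(fin) else 0
  vscale <- if (length(fin) && max(fin) > vmin) max(fin) - vmin else 1
  norm <- (v - vmin) / vscale
  norm[na_mask] <- 0
  payload <- if (any(na_mask)) {
    array(c(norm, 1 - na_mask), c(dim(v), 2))
  } else norm
  suppressWarnings(tiff::writeTIFF(payload, path, bits.per.sample = 32L,
                                   reduce = FALSE))
  sc <- sidecar_paths(path)
  write_geo_sidecars(raster, path)
  meta <- jsonlite::read_json(sc$meta, simplifyVector = TRUE)
  meta$value_min <- vmin
  meta$value_scale <- vscale
  meta$has_na_band <- any(na_mask)
  jsonlite::write_json(meta, sc$meta, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a continuous raster written by [write_float_raster()]
#'
#' @param path path to the TIFF.
#' @return an [lc_raster()] with a numeric matrix (NA where masked).
#' @export
read_float_raster <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  v <- suppressWarnings(tiff::readTIFF(path))
  geo <- read_geo_sidecars(path)
  meta <- geo$meta
  vmin <- if (is.null(meta$value_min)) 0 else meta$value_min
  vscale <- if (is.null(meta$value_scale)) 1 else meta$value_scale
  if (isTRUE(meta$has_na_band)) {
    mask <- v[, , 2] < 0.5
    v <- v[, , 1]
    v <- v * vscale + vmin
    v[mask] <- NA_real_
  } else {
    if (!is.matrix(v)) v <- v[, , 1]
    v <- v * vscale + vmin
  }
  ps <- geo$pixel_size
  nodata <- if (is.null(meta$nodata)) NA_real_ else meta$nodata
  lc_raster(v, xmin = geo$ulx_center - ps / 2, ymax = geo$uly_center + ps / 2,
            pixel_size = ps, crs_code = meta$crs_code, nodata = nodata)
}
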
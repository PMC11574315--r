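#' Multi-year label cube
#'
#' The annual map stack: one integer class grid per year on a shared
#' georeferenced grid.
#'
#' @param values integer array rows x cols x years.
#' @param years ordered integer years (length = 3rd dimension).
#' @param xmin,ymax,pixel_size,crs_code georeference as in [lc_raster()].
#' @param nodata nodata code.
#' @return object of class `lc_cube`.
#' @export
lc_cube <- function(values, years, xmin = 0,
                    ymax = dim(values)[1] * pixel_size, pixel_size = 30,
                    crs_code = "EPSG:3035", nodata = LC_NODATA) {
  stopifnot(length(dim(values)) == 3, dim(values)[3] == length(years),
            !is.unsorted(years, strictly = TRUE))
  structure(list(values = values, years = as.integer(years), xmin = xmin,
                 ymax = ymax, pixel_size = pixel_size, crs_code = crs_code,
                 nodata = nodata),
            class = "lc_cube")
}

#' @export
print.lc_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("lc_cube: %d x %d cells, years %d-%d (%d), %g m pixels\n",
              d[1], d[2], min(x$years), max(x$years), d[3], x$pixel_size))
  invisible(x)
}

#' Extract one year of a cube as a raster
#'
#' @param cube an [lc_cube()].
#' @param year the calendar year to extract.
#' @return an [lc_raster()].
#' @export
cube_year <- function(cube, year) {
  k <- match(year, cube$years)
  if (is.na(k)) stop("year ", year, " not in cube")
  lc_raster(cube$values[, , k], xmin = cube$xmin, ymax = cube$ymax,
            pixel_size = cube$pixel_size, crs_code = cube$crs_code,
            nodata = cube$nodata)
}

#' Write a label cube as one TIFF per year
#'
#' @param cube an [lc_cube()].
#' @param dir output directory.
#' @param prefix filename prefix; files are `<prefix>_<year>.tif`.
#' @return character vector of paths, invisibly.
#' @export
write_label_cube <- function(cube, dir, prefix = "lc") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cube$years, function(y) {
    write_label_raster(cube_year(cube, y),
                       file.path(dir, sprintf("%s_%d.tif", prefix, y)))
  }, "")
  invisible(paths)
}

#' Read a label cube from per-year TIFFs
#'
#' @param paths TIFF paths in year order.
#' @param years matching calendar years.
#' @return an [lc_cube()].
#' @export
read_label_cube <- function(paths, years) {
  stopifnot(length(paths) == length(years))
  rs <- lapply(paths, read_label_raster)
  v <- array(0L, c(dim(rs[[1]]$values), length(years)))
  for (k in seq_along(rs)) v[, , k] <- rs[[k]]$values
  r1 <- rs[[1]]
  lc_cube(v, years, xmin = r1$xmin, ymax = r1$ymax,
          pixel_size = r1$pixel_size, crs_code = r1$crs_code,
          nodata = r1$nodata)
}
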
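#' Read a labeled reference-point table
#'
#' Reads a CSV point table with columns `x`, `y` (projected coordinates, m),
#' `year`, and `code` (legend class code). The table's CRS may be declared
#' in a `crs` column or via `crs_code`; it must match the pipeline CRS
#' (CRS handling here is metadata-only).
#'
#' Points with a `year` outside 2000-2022 (the mapping period) are retained
#' with a warning.
#'
#' @param path CSV file path.
#' @param crs_code CRS the coordinates are expected in.
#' @return data.frame with columns `x`, `y`, `year`, `code`.
#' @export
read_points <- function(path, crs_code = "EPSG:3035") {
  if (!file.exists(path)) stop("missing file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "year", "code")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("missing columns: ", paste(miss, collapse = ", "))
  }
  if ("crs" %in% names(tab)) {
    declared <- unique(tab$crs)
    if (length(declared) > 1L || declared[1] != crs_code) {
      stop("point table CRS (", paste(declared, collapse = ","),
           ") differs from pipeline CRS (", crs_code,
           "); reproject externally")
    }
  }
  out_of_period <- tab$year < 2000 | tab$year > 2022
  if (any(out_of_period)) {
    warning(sum(out_of_period), " point(s) with year outside 2000-2022 retained")
  }
  tab[, need]
}

#' Write a labeled point table to CSV
#'
#' @param points data.frame with columns `x`, `y`, `year`, `code`.
#' @param path output CSV path.
#' @param crs_code CRS recorded in a `crs` column.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path, crs_code = "EPSG:3035") {
  stopifnot(all(c("x", "y", "year", "code") %in% names(points)))
  points$crs <- crs_code
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Look up raster cells at point locations
#'
#' Pixel-center convention: a point falls in the cell whose half-open
#' footprint `[xmin + j*ps, xmin + (j+1)*ps)` contains it.
#'
#' @param raster an [lc_raster()].
#' @param x,y projected coordinates.
#' @return vector of cell values; NA outside the raster.
#' @export
extract_at <- function(raster, x, y) {
  ps <- raster$pixel_size
  col <- floor((x - raster$xmin) / ps) + 1
  row <- floor((raster$ymax - y) / ps) + 1
  ok <- col >= 1 & col <= ncol(raster$values) & row >= 1 & row <= nrow(raster$values)
  out <- rep(NA, length(x))
  out[ok] <- raster$values[cbind(row[ok], col[ok])]
  out
}
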
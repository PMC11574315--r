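#' Processing tile grid
#'
#' A regular tiling of the projected plane, anchored at an origin. Defaults
#' follow the mapping setup: 30 km tiles of 30 m pixels in the
#' ETRS89-extended / LAEA Europe projection (EPSG:3035).
#'
#' @param origin numeric length-2, projected coordinates (m) of the grid
#'   anchor (lower-left corner of tile (0,0)).
#' @param tile_size tile edge length in metres; must be an integer multiple
#'   of `pixel_size`.
#' @param pixel_size pixel edge length in metres.
#' @param crs_code CRS identifier string.
#' @return An object of class `tile_grid`.
#' @export
tile_grid <- function(origin = c(0, 0), tile_size = 30000, pixel_size = 30,
                      crs_code = "EPSG:3035") {
  stopifnot(length(origin) == 2, is.numeric(origin),
            tile_size > 0, pixel_size > 0)
  if (abs(tile_size / pixel_size - round(tile_size / pixel_size)) > 1e-9) {
    stop("tile_size must be an integer multiple of pixel_size")
  }
  structure(list(origin = as.numeric(origin), tile_size = tile_size,
                 pixel_size = pixel_size, crs_code = crs_code),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile_grid: %g m tiles / %g m pixels, origin (%g, %g), %s\n",
              x$tile_size, x$pixel_size, x$origin[1], x$origin[2], x$crs_code))
  invisible(x)
}

#' Enumerate the tiles covering an extent
#'
#' Tiles align to the grid origin, are pairwise disjoint (half-open
#' intervals), and their union covers the requested extent.
#'
#' @param grid a [tile_grid()].
#' @param extent numeric length-4 `c(xmin, ymin, xmax, ymax)` in grid CRS.
#' @return data.frame with one row per tile: tile indices `ix`, `iy` and
#'   bounds `xmin`, `ymin`, `xmax`, `ymax`.
#' @export
tile_extent <- function(grid, extent) {
  stopifnot(inherits(grid, "tile_grid"), length(extent) == 4)
  if (extent[3] <= extent[1] || extent[4] <= extent[2]) {
    stop("extent is empty")
  }
  ts <- grid$tile_size
  ix0 <- floor((extent[1] - grid$origin[1]) / ts)
  ix1 <- ceiling((extent[3] - grid$origin[1]) / ts) - 1
  iy0 <- floor((extent[2] - grid$origin[2]) / ts)
  iy1 <- ceiling((extent[4] - grid$origin[2]) / ts) - 1
  if (max(abs(c(ix0, ix1, iy0, iy1))) > 1e7) stop("extent outside representable range")
  g <- expand.grid(ix = ix0:ix1, iy = iy0:iy1)
  data.frame(
    ix = g$ix, iy = g$iy,
    xmin = grid$origin[1] + g$ix * ts, ymin = grid$origin[2] + g$iy * ts,
    xmax = grid$origin[1] + (g$ix + 1) * ts, ymax = grid$origin[2] + (g$iy + 1) * ts
  )
}
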
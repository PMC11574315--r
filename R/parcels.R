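#' Rasterize crop reference parcels to labeled pixels
#'
#' Labels pixels whose centers fall inside a parcel (pixel-center-in-polygon
#' rule). Parcels are axis-aligned rectangles — the form the synthetic
#' parcel generator produces. Pixels covered by two or more parcels are
#' left unlabeled (nodata), so conflicting references never enter training.
#'
#' @param parcels data.frame with columns `xmin`, `ymin`, `xmax`, `ymax`,
#'   `year`, `code` (one of the nine cropland/grassland codes 10-18).
#' @param grid a [tile_grid()] providing pixel size and origin.
#' @param rows,cols raster extent in pixels (origin-anchored).
#' @return data.frame of labeled pixels: `x`, `y`, `year`, `code`, `row`,
#'   `col` (row 1 = northernmost).
#' @export
rasterize_crop_parcels <- function(parcels, grid, rows, cols) {
  stopifnot(inherits(grid, "tile_grid"))
  if (nrow(parcels) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), year = integer(0),
                      code = integer(0), row = integer(0), col = integer(0)))
  }
  bad <- setdiff(unique(parcels$code), 10:18)
  if (length(bad) > 0L) {
    stop("unknown crop label(s): ", paste(bad, collapse = ", "))
  }
  ps <- grid$pixel_size
  x0 <- grid$origin[1]
  ytop <- grid$origin[2] + rows * ps
  out <- list()
  for (yr in unique(parcels$year)) {
    sub <- parcels[parcels$year == yr, ]
    lab <- matrix(0L, rows, cols)
    hits <- matrix(0L, rows, cols)
    xc <- x0 + (seq_len(cols) - 0.5) * ps
    yc <- ytop - (seq_len(rows) - 0.5) * ps
    for (k in seq_len(nrow(sub))) {
      incol <- which(xc > sub$xmin[k] & xc < sub$xmax[k])
      inrow <- which(yc > sub$ymin[k] & yc < sub$ymax[k])
      if (length(incol) && length(inrow)) {
        lab[inrow, incol] <- sub$code[k]
        hits[inrow, incol] <- hits[inrow, incol] + 1L
      }
    }
    lab[hits > 1L] <- 0L
    sel <- which(lab > 0L)
    if (length(sel)) {
      row <- (sel - 1L) %% rows + 1L
      col <- (sel - 1L) %/% rows + 1L
      out[[length(out) + 1L]] <- data.frame(
        x = xc[col], y = yc[row], year = yr, code = lab[sel],
        row = row, col = col)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), year = integer(0),
                      code = integer(0), row = integer(0), col = integer(0)))
  }
  do.call(rbind, out)
}
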
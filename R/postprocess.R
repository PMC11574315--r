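#' Spatial majority filter (3 x 3)
#'
#' Single-pass salt-noise removal on one annual map: the center pixel is
#' replaced by the modal class of its eight neighbours only when its class
#' differs from all eight. Evaluation is on a frozen copy of the input (no
#' cascading), border pixels are unchanged, and any window containing
#' nodata is skipped. A tie between neighbour modes is broken by the
#' smallest class code.
#'
#' @param map integer class matrix (single year).
#' @param nodata nodata code.
#' @return filtered integer matrix.
#' @export
spatial_majority_filter <- function(map, nodata = LC_NODATA) {
  nr <- nrow(map); nc <- ncol(map)
  out <- map
  if (nr < 3L || nc < 3L) return(out)
  for (i in 2:(nr - 1L)) {
    for (j in 2:(nc - 1L)) {
      win <- map[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
      if (any(win == nodata)) next
      nb <- win[-5L]
      ctr <- win[5L]
      if (all(nb != ctr)) {
        tab <- tabulate(nb, nbins = max(nb))
        out[i, j] <- which.max(tab)  # ties -> smallest code
      }
    }
  }
  out
}

#' Temporal filter (3-year window, backward)
#'
#' Per pixel, a sliding 3-year window runs from the latest to the earliest
#' year: a pattern (X, Y, X) with Y != X becomes (X, X, X). Updates are
#' made in place so they are visible to the subsequent (earlier) windows;
#' the first and last years are never modified. Windows containing nodata
#' are skipped.
#'
#' @param cube an [lc_cube()] (>= 3 years) or a rows x cols x years array.
#' @param nodata nodata code.
#' @return filtered object of the same type.
#' @export
temporal_filter <- function(cube, nodata = LC_NODATA) {
  v <- if (inherits(cube, "lc_cube")) cube$values else cube
  ny <- dim(v)[3]
  stopifnot(ny >= 3L)
  for (k in (ny - 1L):2L) {
    a <- v[, , k - 1L]
    b <- v[, , k]
    c_ <- v[, , k + 1L]
    fix <- a == c_ & b != a & a != nodata & b != nodata & c_ != nodata
    b[fix] <- a[fix]
    v[, , k] <- b
  }
  if (inherits(cube, "lc_cube")) {
    cube$values <- v
    cube
  } else v
}

#' Spatio-temporal filter (3 x 3 x 3 cube window, backward)
#'
#' For each year t (latest to earliest) and each 3 x 3 spatial patch
#' (stride 1): if the same class fills all nine pixels of the patch in
#' years t-1 and t+1, and at least seven of the nine pixels of year t
#' already hold that class, the whole year-t patch is converted to it.
#' Within a year, all patch decisions are evaluated on a frozen snapshot
#' of that year and then applied (decisions on overlapping patches cannot
#' conflict, since the surrounding-year patches overlap too); across
#' years the updates propagate backward. First and last years are never
#' modified; windows containing nodata are skipped. The 7-of-9 trigger
#' removes up to two noisy pixels per patch while leaving genuine crop
#' rotations (which break the surrounding-year homogeneity) untouched.
#'
#' @param cube an [lc_cube()] (>= 3 years, grid >= 3 x 3) or an array.
#' @param nodata nodata code.
#' @return filtered object of the same type.
#' @export
spatiotemporal_filter <- function(cube, nodata = LC_NODATA) {
  v <- if (inherits(cube, "lc_cube")) cube$values else cube
  d <- dim(v)
  nr <- d[1]; nc <- d[2]; ny <- d[3]
  stopifnot(ny >= 3L, nr >= 3L, nc >= 3L)
  for (k in (ny - 1L):2L) {
    prev <- v[, , k - 1L]
    cur <- v[, , k]
    nxt <- v[, , k + 1L]
    snap <- cur
    for (i in 2:(nr - 1L)) {
      for (j in 2:(nc - 1L)) {
        ri <- (i - 1L):(i + 1L); rj <- (j - 1L):(j + 1L)
        pa <- prev[ri, rj]
        cl <- pa[1L]
        if (cl == nodata || any(pa != cl)) next
        na_ <- nxt[ri, rj]
        if (any(na_ != cl)) next
        cc <- snap[ri, rj]
        if (any(cc == nodata)) next
        if (sum(cc == cl) >= 7L) cur[ri, rj] <- cl
      }
    }
    v[, , k] <- cur
  }
  if (inherits(cube, "lc_cube")) {
    cube$values <- v
    cube
  } else v
}

#' Post-process a Level-1 map stack
#'
#' The Level-1 bundle: per-year spatial majority filtering followed by the
#' backward temporal filter.
#'
#' @param cube an [lc_cube()].
#' @return filtered [lc_cube()].
#' @export
postprocess_level1 <- function(cube) {
  for (k in seq_along(cube$years)) {
    cube$values[, , k] <- spatial_majority_filter(cube$values[, , k],
                                                  cube$nodata)
  }
  if (length(cube$years) >= 3L) cube <- temporal_filter(cube, cube$nodata)
  cube
}

#' Post-process a Level-2 map stack
#'
#' The Level-2 bundle: per-year spatial majority filtering followed by the
#' spatio-temporal filter (the plain temporal filter would erase genuine
#' crop rotations).
#'
#' @param cube an [lc_cube()].
#' @return filtered [lc_cube()].
#' @export
postprocess_level2 <- function(cube) {
  for (k in seq_along(cube$years)) {
    cube$values[, , k] <- spatial_majority_filter(cube$values[, , k],
                                                  cube$nodata)
  }
  d <- dim(cube$values)
  if (length(cube$years) >= 3L && d[1] >= 3L && d[2] >= 3L) {
    cube <- spatiotemporal_filter(cube, cube$nodata)
  }
  cube
}
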
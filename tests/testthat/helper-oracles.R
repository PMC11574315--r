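# Independent brute-force oracles used to verify the package's vectorised
# implementations. These deliberately use naive per-element loops and a
# different code path from the functions they check.

# weekly binning by direct per-week scan
oracle_encode <- function(series) {
  m <- matrix(0, 52, 9)
  for (w in 0:51) {
    lo <- w * 7 + 1
    hi <- if (w == 51) 366 else w * 7 + 7
    sel <- series$clear & series$doy >= lo & series$doy <= hi
    if (any(sel)) {
      for (b in 1:9) m[w + 1, b] <- mean(series$values[sel, b])
    }
  }
  m
}

# spatial majority filter by per-pixel scan
oracle_spatial <- function(map, nodata = 0L) {
  out <- map
  nr <- nrow(map); nc <- ncol(map)
  if (nr < 3 || nc < 3) return(out)
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    win <- as.vector(map[(i - 1):(i + 1), (j - 1):(j + 1)])
    if (any(win == nodata)) next
    ctr <- win[5]; nb <- win[-5]
    if (!any(nb == ctr)) {
      cnt <- table(nb)
      best <- as.integer(names(cnt)[cnt == max(cnt)])
      out[i, j] <- min(best)
    }
  }
  out
}

# temporal filter by per-pixel backward vector pass
oracle_temporal <- function(arr, nodata = 0L) {
  d <- dim(arr)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- arr[i, j, ]
    for (k in (d[3] - 1):2) {
      trip <- c(v[k - 1], v[k], v[k + 1])
      if (any(trip == nodata)) next
      if (v[k - 1] == v[k + 1] && v[k] != v[k - 1]) v[k] <- v[k - 1]
    }
    arr[i, j, ] <- v
  }
  arr
}

# spatio-temporal filter by direct window enumeration
oracle_st <- function(arr, nodata = 0L) {
  d <- dim(arr)
  for (k in (d[3] - 1):2) {
    snap <- arr[, , k]
    for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) {
      ri <- (i - 1):(i + 1); rj <- (j - 1):(j + 1)
      pa <- as.vector(arr[ri, rj, k - 1])
      nx <- as.vector(arr[ri, rj, k + 1])
      cc <- as.vector(snap[ri, rj])
      cl <- pa[1]
      if (cl == nodata) next
      if (length(unique(pa)) != 1 || length(unique(nx)) != 1) next
      if (nx[1] != cl) next
      if (any(cc == nodata)) next
      if (sum(cc == cl) >= 7) arr[ri, rj, k] <- cl
    }
  }
  arr
}

# rule evaluation by per-pixel explicit condition scan
oracle_rule <- function(stack, rule) {
  d <- stack$dim
  layer_val <- function(prod, year, i, j) {
    if (prod %in% names(stack$stm)) return(stack$stm[[prod]][i, j])
    stack$products[[prod]][[as.character(year)]][i, j]
  }
  cond_ok_px <- function(cond, year, i, j) {
    if (cond$op == "paired_in") {
      a <- layer_val("clc_code", year, i, j)
      b <- layer_val("n2k_code", year, i, j)
      ok <- FALSE
      for (k in seq_along(cond$value[[1]])) {
        if (!is.na(a) && !is.na(b) &&
            a == cond$value[[1]][k] && b == cond$value[[2]][k]) ok <- TRUE
      }
      return(ok)
    }
    v <- layer_val(cond$product, year, i, j)
    if (is.na(v)) return(FALSE)
    switch(cond$op,
           ">" = v > cond$value, ">=" = v >= cond$value,
           "<" = v < cond$value, "<=" = v <= cond$value,
           "==" = v == cond$value, "in" = v %in% cond$value)
  }
  out <- matrix(FALSE, d[1], d[2])
  h <- function(w) (w - 1) %/% 2
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ok_all <- TRUE
    for (cond in rule$conditions) {
      hw <- h(cond$window)
      if (i - hw < 1 || i + hw > d[1] || j - hw < 1 || j + hw > d[2]) {
        if (cond$window > 1) { ok_all <- FALSE; break }
      }
      years <- if (is.null(cond$years)) NA else cond$years
      cond_ok <- TRUE
      for (y in years) {
        if (cond$window == 1 || cond$quantifier == "center") {
          if (!cond_ok_px(cond, y, i, j)) cond_ok <- FALSE
        } else {
          for (ii in (i - hw):(i + hw)) for (jj in (j - hw):(j + hw)) {
            if (cond$quantifier == "ring" && ii == i && jj == j) next
            if (!cond_ok_px(cond, y, ii, jj)) cond_ok <- FALSE
          }
        }
      }
      if (!cond_ok) { ok_all <- FALSE; break }
    }
    out[i, j] <- ok_all
  }
  out
}

# masked nearest-centroid classifier against noise-free weekly signatures
oracle_centroids <- function(phenologies = default_phenologies()) {
  lapply(seq_along(phenologies), function(k) {
    m <- phenologies[[k]]
    v <- phenology_curve(m, 1:365)
    idx <- compute_indices(red = v[, 1], green = v[, 2], blue = v[, 3],
                           nir = v[, 4], swir1 = v[, 5], swir2 = v[, 6])
    vv <- cbind(v, idx$ndvi, idx$ndwi, idx$savi)
    apply(vv, 2, function(col) tapply(col, week_of_doy(1:365), mean))
  })
}

oracle_classify <- function(enc, centroids) {
  filled <- rowSums(abs(enc)) > 0
  if (!any(filled)) return(NA_integer_)
  d2 <- vapply(centroids, function(cm) {
    sum((enc[filled, ] - cm[filled, ])^2)
  }, 0)
  which.min(d2)
}

random_series <- function(n_obs, year = 2018) {
  doy <- sort(sample.int(365, n_obs))
  observation_series(year, doy, matrix(runif(n_obs * 6), n_obs, 6),
                     clear = runif(n_obs) < 0.8)
}
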
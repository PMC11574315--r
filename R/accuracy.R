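#' Build an error matrix from reference points and a predicted map
#'
#' Counts n_ij by (map class i, reference class j). Points falling on
#' nodata or outside the map are skipped and their count reported in the
#' `n_skipped` attribute. Reference points whose class is absent from the
#' map's class list are dropped (with their count logged the same way).
#'
#' @param reference data.frame with `x`, `y`, `code` (reference class).
#' @param map an [lc_raster()] of predicted classes.
#' @param mapped_areas named numeric vector: mapped area (km^2) per class
#'   code; the class list of the matrix.
#' @return object of class `error_matrix`: list with `classes`, `counts`
#'   (square matrix, rows = map, cols = reference), `mapped_areas`,
#'   `total_area`.
#' @export
build_error_matrix <- function(reference, map, mapped_areas) {
  stopifnot(inherits(map, "lc_raster"), length(mapped_areas) > 0,
            !is.null(names(mapped_areas)))
  classes <- as.integer(names(mapped_areas))
  pred <- extract_at(map, reference$x, reference$y)
  usable <- !is.na(pred) & pred != map$nodata &
    pred %in% classes & reference$code %in% classes
  if (!any(usable)) stop("no reference points fall on mapped classes")
  counts <- table(factor(pred[usable], levels = classes),
                  factor(reference$code[usable], levels = classes))
  counts <- matrix(as.numeric(counts), length(classes), length(classes),
                   dimnames = list(map = classes, reference = classes))
  structure(list(classes = classes, counts = counts,
                 mapped_areas = as.numeric(mapped_areas),
                 total_area = sum(mapped_areas),
                 n_skipped = sum(!usable)),
            class = "error_matrix")
}

#' Error matrix from raw count table
#'
#' @param counts square numeric matrix (rows = map class, cols = reference
#'   class), with class codes as dimnames or given via `classes`.
#' @param mapped_areas per-class mapped areas (same order as rows).
#' @param classes optional integer class codes.
#' @return an `error_matrix` object.
#' @export
error_matrix <- function(counts, mapped_areas, classes = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0),
            length(mapped_areas) == nrow(counts))
  if (is.null(classes)) {
    classes <- if (!is.null(rownames(counts))) {
      as.integer(rownames(counts))
    } else seq_len(nrow(counts))
  }
  dimnames(counts) <- list(map = classes, reference = classes)
  structure(list(classes = as.integer(classes), counts = counts,
                 mapped_areas = as.numeric(mapped_areas),
                 total_area = sum(mapped_areas), n_skipped = 0L),
            class = "error_matrix")
}

#' Per-class F1 scores from an error matrix
#'
#' Standard F1: `TP / (TP + 0.5 (FP + FN))`, equivalent to the harmonic
#' mean of user's accuracy (precision) and producer's accuracy (recall).
#' A class absent from both map and reference has an undefined F1 and is
#' returned as NA.
#'
#' @param em an [error_matrix()].
#' @return named numeric vector of F1 scores per class code.
#' @export
f1_scores <- function(em) {
  stopifnot(inherits(em, "error_matrix"))
  tp <- diag(em$counts)
  fp <- rowSums(em$counts) - tp
  fn <- colSums(em$counts) - tp
  f1 <- ifelse(tp + fp + fn == 0, NA_real_, tp / (tp + 0.5 * (fp + fn)))
  names(f1) <- em$classes
  f1
}

#' Stratified accuracy and area estimation
#'
#' Good-practice stratified estimators with the map classes as strata.
#' With stratum weights `W_i = A_i / A_total` and cell proportions
#' `p_ij = W_i n_ij / n_i.`: estimated area `A_j = A_total sum_i p_ij`
#' with standard error `A_total sqrt(sum_i W_i^2 (n_ij/n_i.)(1 - n_ij/n_i.)/(n_i. - 1))`;
#' overall accuracy `sum_j p_jj`; user's accuracy `n_ii / n_i.`;
#' producer's accuracy `p_jj / p_.j`; variances per the stratified
#' formulas. Confidence intervals use the normal approximation
#' (half-width = z * SE, z = 1.96 at 95%).
#'
#' @param em an [error_matrix()]; every stratum must hold at least one
#'   sample.
#' @param confidence confidence level for the intervals.
#' @return object of class `accuracy_report`: data.frame `by_class` with
#'   columns `code`, `mapped_area`, `estimated_area`, `area_ci`, `pa`,
#'   `pa_ci`, `ua`, `ua_ci`, plus `oa`, `oa_ci`, `confidence`.
#' @export
olofsson_estimates <- function(em, confidence = 0.95) {
  stopifnot(inherits(em, "error_matrix"))
  n <- em$counts
  ni <- rowSums(n)
  if (any(ni == 0)) {
    stop("stratum with zero samples: class ",
         paste(em$classes[ni == 0], collapse = ", "))
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  A <- em$mapped_areas
  At <- em$total_area
  W <- A / At
  p <- (W / ni) * n                         # p_ij = W_i * n_ij / n_i.
  # areas
  est_area <- At * colSums(p)
  se_prop <- sqrt(colSums(W^2 * (n / ni) * (1 - n / ni) /
                            pmax(ni - 1, 1)))
  area_ci <- z * At * se_prop
  # overall accuracy
  oa <- sum(diag(p))
  ua <- diag(n) / ni
  v_oa <- sum(W^2 * ua * (1 - ua) / pmax(ni - 1, 1))
  # user's accuracy
  v_ua <- ua * (1 - ua) / pmax(ni - 1, 1)
  # producer's accuracy
  k <- length(A)
  pa <- diag(p) / colSums(p)
  v_pa <- numeric(k)
  Nhat_j <- colSums(A * n / ni)             # estimated "area" of ref class j
  for (j in seq_len(k)) {
    term1 <- A[j]^2 * (1 - pa[j])^2 * ua[j] * (1 - ua[j]) /
      max(ni[j] - 1, 1)
    i_not <- setdiff(seq_len(k), j)
    term2 <- pa[j]^2 * sum(A[i_not]^2 * (n[i_not, j] / ni[i_not]) *
                             (1 - n[i_not, j] / ni[i_not]) /
                             pmax(ni[i_not] - 1, 1))
    v_pa[j] <- (term1 + term2) / Nhat_j[j]^2
  }
  by_class <- data.frame(
    code = em$classes,
    mapped_area = A,
    estimated_area = est_area,
    area_ci = area_ci,
    pa = pa, pa_ci = z * sqrt(v_pa),
    ua = ua, ua_ci = z * sqrt(v_ua)
  )
  structure(list(by_class = by_class, oa = oa, oa_ci = z * sqrt(v_oa),
                 confidence = confidence),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  b <- x$by_class
  fmt <- function(v) formatC(signif(v, 4), format = "g", width = 9)
  cat(sprintf("%-6s %10s %23s %15s %15s\n", "code", "mapped",
              "estimated(km2) +/- CI", "PA +/- CI", "UA +/- CI"))
  for (r in seq_len(nrow(b))) {
    cat(sprintf("%-6d %10s %11s +/- %8s %6.2f +/- %4.2f %6.2f +/- %4.2f\n",
                b$code[r], fmt(b$mapped_area[r]), fmt(b$estimated_area[r]),
                fmt(b$area_ci[r]), b$pa[r], b$pa_ci[r], b$ua[r], b$ua_ci[r]))
  }
  cat(sprintf("Overall accuracy %.3f +/- %.3f (%.0f%% CI)\n", x$oa, x$oa_ci,
              100 * x$confidence))
  invisible(x)
}

#' Annual mapped area of one class
#'
#' @param cube an [lc_cube()].
#' @param code class code.
#' @return data.frame `year`, `area_km2` (pixel count x pixel area).
#' @export
class_area_series <- function(cube, code) {
  stopifnot(inherits(cube, "lc_cube"))
  px_km2 <- (cube$pixel_size / 1000)^2
  data.frame(
    year = cube$years,
    area_km2 = vapply(seq_along(cube$years), function(k) {
      sum(cube$values[, , k] == code) * px_km2
    }, 0)
  )
}

#' Compare mapped area series with external statistics
#'
#' @param map_areas data.frame `class`, `year`, `area_km2` from the maps.
#' @param stats_table data.frame `class`, `year`, `area_km2` of official
#'   statistics.
#' @return data.frame per class and shared year: mapped and reference
#'   areas, `difference` (map minus statistics) and `relative_error`
#'   (difference / statistics).
#' @export
compare_area_series <- function(map_areas, stats_table) {
  shared <- merge(map_areas, stats_table, by = c("class", "year"),
                  suffixes = c("_map", "_stats"))
  if (nrow(shared) == 0L) stop("no shared class/year pairs")
  shared$difference <- shared$area_km2_map - shared$area_km2_stats
  shared$relative_error <- shared$difference / shared$area_km2_stats
  shared[order(shared$class, shared$year), ]
}
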
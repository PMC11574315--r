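test_that("error matrices tally map-reference pairs with conservation and skips", {
  v <- matrix(rep(1:3, each = 12), 6, 6)
  storage.mode(v) <- "integer"
  mapr <- lc_raster(v, xmin = 0, ymax = 180, pixel_size = 30)
  areas <- c(`1` = 10, `2` = 12, `3` = 14)
  # perfect prediction -> diagonal matrix
  xs <- rep(seq(15, 165, 30), 6); ys <- rep(seq(165, 15, -30), each = 6)
  ref <- data.frame(x = xs, y = ys, code = as.vector(t(v)))
  em <- build_error_matrix(ref, mapr, areas)
  expect_true(all(em$counts[upper.tri(em$counts)] == 0))
  expect_true(all(em$counts[lower.tri(em$counts)] == 0))
  expect_identical(sum(em$counts), 36)
  # random labels equal a hand tally on 20 points
  set.seed(461)
  ref2 <- data.frame(x = sample(xs, 20), y = sample(ys, 20),
                     code = sample(1:3, 20, TRUE))
  em2 <- build_error_matrix(ref2, mapr, areas)
  hand <- matrix(0, 3, 3)
  for (k in 1:20) {
    i <- extract_at(mapr, ref2$x[k], ref2$y[k])
    hand[i, ref2$code[k]] <- hand[i, ref2$code[k]] + 1
  }
  expect_equal(unname(em2$counts), hand)
  expect_identical(sum(em2$counts), 20)
  # points off the map are skipped and reported
  ref3 <- rbind(ref2, data.frame(x = -100, y = -100, code = 1L))
  em3 <- build_error_matrix(ref3, mapr, areas)
  expect_identical(em3$n_skipped, 1L)
  expect_error(build_error_matrix(data.frame(x = -1, y = -1, code = 1L),
                                  mapr, areas), "no reference points")
})

test_that("F1 equals the harmonic precision-recall mean on arbitrary matrices", {
  em <- error_matrix(diag(c(5, 9, 14)), c(1, 2, 3))
  expect_true(all(f1_scores(em) == 1))
  # TP = 50, FP = 50, FN = 0 -> 2/3
  em2 <- error_matrix(rbind(c(50, 0), c(50, 10)), c(1, 1))
  expect_equal(unname(f1_scores(em2)[1]), 50 / 75)
  set.seed(462)
  for (rep in 1:25) {
    n <- matrix(rpois(16, 8), 4, 4)
    emr <- error_matrix(n, runif(4, 1, 10))
    f <- f1_scores(emr)
    prec <- diag(n) / rowSums(n)
    rec <- diag(n) / colSums(n)
    expect_equal(unname(f), 2 * prec * rec / (prec + rec), tolerance = 1e-12)
  }
  # class absent from map and reference -> NA
  n0 <- diag(c(4, 0, 6)); n0[2, ] <- 0; n0[, 2] <- 0
  expect_true(is.na(f1_scores(error_matrix(n0, c(1, 1, 1)))[2]))
})

test_that("stratified estimates reproduce an independently hand-worked example", {
  # 3-class example computed by hand from the stratified formulas before
  # this function was written; frozen expected values
  n <- rbind(c(97, 3, 2), c(5, 90, 5), c(8, 2, 90))
  em <- error_matrix(n, c(22000, 35000, 43000))
  rep_ <- olofsson_estimates(em)
  expect_equal(rep_$by_class$estimated_area,
               c(26111.568627, 33007.058824, 40881.372549), tolerance = 1e-6)
  expect_equal(rep_$by_class$area_ci,
               c(2897.668369, 2491.929935, 3011.452329), tolerance = 1e-6)
  expect_equal(rep_$oa, 0.9112156862745098, tolerance = 1e-12)
  expect_equal(rep_$oa_ci, 0.0340489031, tolerance = 1e-7)
  expect_equal(rep_$by_class$ua, c(0.95098039, 0.9, 0.9), tolerance = 1e-7)
  expect_equal(rep_$by_class$ua_ci, c(0.0421074, 0.0590951, 0.0590951),
               tolerance = 1e-5)
  expect_equal(rep_$by_class$pa, c(0.801238, 0.954341, 0.946641),
               tolerance = 1e-6)
  expect_equal(rep_$by_class$pa_ci, c(0.0845438, 0.0402873, 0.0375682),
               tolerance = 1e-5)
})

test_that("estimated areas always sum to the total area and respect limits", {
  set.seed(463)
  for (rep in 1:30) {
    k <- sample(3:6, 1)
    n <- matrix(rpois(k * k, 6) + 1, k, k)
    A <- runif(k, 100, 5000)
    r <- olofsson_estimates(error_matrix(n, A))
    expect_equal(sum(r$by_class$estimated_area), sum(A), tolerance = 1e-9)
    expect_true(all(r$by_class$pa >= 0 & r$by_class$pa <= 1))
    expect_true(all(r$by_class$ua >= 0 & r$by_class$ua <= 1))
  }
  # perfect map under any allocation: exact accuracies, zero widths,
  # estimated areas = mapped areas
  d <- olofsson_estimates(error_matrix(diag(c(50, 50, 50)),
                                       c(1000, 2000, 3000)))
  expect_equal(d$oa, 1)
  expect_equal(d$oa_ci, 0)
  expect_equal(d$by_class$estimated_area, d$by_class$mapped_area)
  expect_true(all(d$by_class$area_ci == 0))
  # a stratum without samples is a named error
  n0 <- rbind(c(5, 1, 0), c(0, 0, 0), c(1, 0, 7))
  expect_error(olofsson_estimates(error_matrix(n0, c(1, 1, 1))), "2")
  # OA reduces to trace/total under proportional allocation
  set.seed(464)
  n <- matrix(rpois(9, 20) + 5, 3, 3)
  r2 <- olofsson_estimates(error_matrix(n, rowSums(n)))
  expect_equal(r2$oa, sum(diag(n)) / sum(n), tolerance = 1e-12)
})

test_that("class area series track pixel counts and generator dynamics", {
  cube <- lc_cube(array(3L, c(10, 10, 2)), 2017:2018, pixel_size = 30)
  a <- class_area_series(cube, 3L)
  expect_equal(a$area_km2, c(0.09, 0.09))   # 100 x 900 m^2
  expect_equal(class_area_series(cube, 9L)$area_km2, c(0, 0))
  cfg <- scene_config(rows = 20, cols = 20, years = 2014:2018,
                      rotation_matrix = diag(9), peat_expansion_rate = 2,
                      seed = 17)
  sc <- simulate_landscape(cfg, observations = FALSE)
  series <- class_area_series(sc$truth, 8L)
  expect_true(all(diff(series$area_km2) >= 0))
  expect_gt(series$area_km2[5], series$area_km2[1])
})

test_that("map-vs-statistics comparison reports exact differences and errors", {
  mapa <- data.frame(class = rep(c("wheat", "barley"), each = 3),
                     year = rep(2016:2018, 2),
                     area_km2 = c(110, 120, 130, 50, 55, 60))
  stats <- mapa; names(stats)[3] <- "area_km2"
  cmp <- compare_area_series(mapa, stats)
  expect_true(all(cmp$difference == 0))
  stats2 <- stats; stats2$area_km2 <- c(100, 120, 130, 50, 55, 60)
  cmp2 <- compare_area_series(mapa, stats2)
  expect_equal(cmp2$relative_error[cmp2$class == "wheat" &
                                     cmp2$year == 2016], 0.1)
  expect_error(compare_area_series(mapa, transform(stats, year = year + 10)),
               "shared")
  # self-consistency: mapped areas of the truth equal the truth's areas
  cube <- lc_cube(array(sample(10:12, 75, TRUE), c(5, 5, 3)), 2016:2018)
  m <- do.call(rbind, lapply(10:12, function(cc) {
    cbind(class = cc, class_area_series(cube, cc))
  }))
  s <- m
  cmp3 <- compare_area_series(m, s)
  expect_true(all(cmp3$difference == 0))
})
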
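test_that("zero-noise phenology reproduces the closed-form curve exactly", {
  m <- phenology_model(6, base = rep(0.1, 6), amplitude = rep(0.3, 6),
                       greenup_doy = 120, senescence_doy = 280,
                       noise_sd = 0)
  dates <- c(30L, 150L, 200L, 300L)
  s <- simulate_phenology(m, dates, 2018)
  expect_equal(s$values[, 1:6], phenology_curve(m, dates),
               ignore_attr = TRUE)
  # amplitude 0 -> constant series at base
  flat <- phenology_model(3, base = rep(0.2, 6), amplitude = rep(0, 6),
                          greenup_doy = 100, senescence_doy = 300,
                          noise_sd = 0)
  sf <- simulate_phenology(flat, dates, 2018)
  expect_true(all(abs(sf$values[, 1:6] - 0.2) < 1e-12))
  # empty date list -> empty series, not an error
  expect_identical(length(simulate_phenology(m, integer(0))$doy), 0L)
  # two seeds differ when noise is present, dates are identical
  m$noise_sd <- 0.05
  a <- simulate_phenology(m, dates, 2018, seed = 1)
  b <- simulate_phenology(m, dates, 2018, seed = 2)
  expect_identical(a$doy, b$doy)
  expect_false(identical(a$values, b$values))
  # values stay in the reflectance range
  expect_true(all(a$values[, 1:6] >= 0 & a$values[, 1:6] <= 1))
})

test_that("default phenologies satisfy their constructor constraints for all 18 classes", {
  ph <- default_phenologies()
  expect_identical(length(ph), 18L)
  expect_identical(as.integer(names(ph)), 1:18)
  for (m in ph) {
    expect_true(all(m$base >= 0 & m$base <= 1))
    expect_true(all(m$base + m$amplitude >= 0 & m$base + m$amplitude <= 1))
    expect_lt(m$greenup_doy, m$senescence_doy)
  }
})

test_that("acquisition draws follow the configured Poisson rate and seasonal weights", {
  # near-zero rate: usually empty
  set.seed(421)
  tiny <- acquisition_profile(2010, 0.001)
  expect_true(mean(vapply(1:200, function(i) {
    length(simulate_acquisitions(tiny))
  }, 0L) == 0L) > 0.99)
  # Monte-Carlo mean within 5% of the configured rate
  prof <- acquisition_profile(2018, 12)
  counts <- vapply(1:1000, function(i) length(simulate_acquisitions(prof)), 0L)
  expect_lt(abs(mean(counts) - 12) / 12, 0.05)
  # uniform weights -> uniform week histogram by chi-squared GOF
  set.seed(422)
  wk <- unlist(lapply(1:400, function(i) {
    week_of_doy(simulate_acquisitions(acquisition_profile(2018, 25)))
  }))
  expect_gt(length(wk), 9000)
  tab <- table(factor(wk, levels = 0:51))
  p <- tabulate(week_of_doy(1:365) + 1L, 52) / 365
  pv <- suppressWarnings(chisq.test(as.vector(tab), p = p)$p.value)
  expect_gt(pv, 0.001)
  # dates are distinct, sorted, in range, and all flagged clear downstream
  d <- simulate_acquisitions(prof, seed = 9)
  expect_identical(d, sort(unique(d)))
  expect_true(all(d >= 1 & d <= 365))
})

test_that("landscape truth follows rotation, persistence and peat-expansion settings", {
  # identity rotation: every pixel keeps its class through all years
  cfg_id <- scene_config(rows = 15, cols = 15, years = 2014:2017,
                         rotation_matrix = diag(9),
                         peat_expansion_rate = 0, seed = 5)
  sc <- simulate_landscape(cfg_id, observations = FALSE)
  for (k in 2:4) {
    expect_identical(sc$truth$values[, , k], sc$truth$values[, , 1])
  }
  # zero expansion keeps exploited-bog area constant; positive grows it
  a0 <- class_area_series(sc$truth, 8)
  expect_true(all(a0$area_km2 == a0$area_km2[1]))
  cfg_x <- scene_config(rows = 15, cols = 15, years = 2014:2017,
                        rotation_matrix = diag(9),
                        peat_expansion_rate = 3, seed = 5)
  # a rate outgrowing the remaining bog is capped with a warning
  expect_warning(scx <- simulate_landscape(cfg_x, observations = FALSE),
                 "capped")
  ax <- class_area_series(scx$truth, 8)
  expect_true(all(diff(ax$area_km2) >= 0))
  expect_gt(ax$area_km2[4], ax$area_km2[1])
  # non-crop classes persist even under rotation (no peat conversion)
  cfg_rot <- scene_config(rows = 15, cols = 15, years = 2014:2017,
                          peat_expansion_rate = 0, seed = 5)
  scr <- simulate_landscape(cfg_rot, observations = FALSE)
  noncrop <- scr$truth$values[, , 1] < 10
  for (k in 2:4) {
    expect_identical(scr$truth$values[, , k][noncrop],
                     scr$truth$values[, , 1][noncrop])
  }
})

test_that("observed crop transitions match the configured matrix within two standard errors", {
  # rotation is drawn once per field, so the unit of observation is the
  # patch, not the pixel
  rot <- default_rotation_matrix(p_stay = 0.7)
  cfg <- scene_config(rows = 100, cols = 100, years = 2017:2018,
                      mean_patch_pixels = 10, rotation_matrix = rot,
                      peat_expansion_rate = 0, seed = 31)
  sc <- simulate_landscape(cfg, observations = FALSE)
  y1 <- as.vector(sc$truth$values[, , 1])
  y2 <- as.vector(sc$truth$values[, , 2])
  pm <- as.vector(sc$patch_map)
  first <- !duplicated(pm)
  p1 <- y1[first]; p2 <- y2[first]
  arable <- p1 >= 10L & p1 <= 17L
  n <- sum(arable)
  expect_gt(n, 200)
  stay <- mean(p2[arable] == p1[arable])
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(stay - 0.7), 2 * se + 1e-9)
  # rotations never leave the cropland/grassland class set
  expect_true(all(p2[arable] %in% 10:18))
})

test_that("stochastic scene outputs are reproducible bit-exactly under a fixed seed", {
  cfg <- scene_config(rows = 8, cols = 8, years = 2017:2018, seed = 77)
  a <- simulate_landscape(cfg)
  b <- simulate_landscape(cfg)
  expect_identical(a$truth$values, b$truth$values)
  expect_identical(a$series[[10]][[2]]$values, b$series[[10]][[2]]$values)
})

test_that("reference products agree with relabeled truth at zero rates and deviate at stated rates", {
  cfg <- scene_config(rows = 40, cols = 40, years = 2016:2018,
                      rotation_matrix = diag(9), peat_expansion_rate = 0,
                      mean_patch_pixels = 50, seed = 13)
  sc <- simulate_landscape(cfg, observations = FALSE)
  stack0 <- simulate_reference_products(sc$truth, seed = 1)
  truth <- sc$truth$values[, , 1]
  # zero contamination: every built-up pixel >= 51% impervious in all years
  for (y in names(stack0$products$imperviousness)) {
    expect_true(all(stack0$products$imperviousness[[y]][truth == 1L] >= 51))
    expect_true(all(stack0$products$imperviousness[[y]][truth != 1L] == 0))
  }
  # zero disagreement: the categorical product is the truth relabeled
  tabs <- reference_code_tables()
  expect_identical(stack0$products$clc_code[["2012"]],
                   matrix(tabs$clc[truth], 40, 40))
  # disagreement rate 0.1: mismatch fraction ~ 0.1 (binomial, 1600*3 draws)
  set.seed(55)
  stack1 <- simulate_reference_products(sc$truth, disagreement = 0.1)
  mism <- mean(unlist(lapply(stack1$products$clc_code, function(m) {
    m != matrix(tabs$clc[truth], 40, 40)
  })))
  expect_lt(abs(mism - 0.1), 0.015)
})

test_that("default phenologies are class-separable for a masked nearest-centroid oracle", {
  set.seed(423)
  cents <- oracle_centroids()
  ph <- default_phenologies()
  prof <- acquisition_profile(2018, 20)
  n_per <- 25
  truth <- rep(1:18, each = n_per)
  pred <- integer(length(truth))
  i <- 0
  for (cc in 1:18) for (r in seq_len(n_per)) {
    i <- i + 1
    s <- simulate_phenology(ph[[as.character(cc)]],
                            simulate_acquisitions(prof), 2018)
    pred[i] <- oracle_classify(encode_weekly(s), cents)
  }
  expect_gte(mean(pred == truth), 0.95)
})
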
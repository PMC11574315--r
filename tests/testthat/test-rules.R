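make_test_scene <- function(rows = 30, cols = 30, seed = 61) {
  cfg <- scene_config(rows = rows, cols = cols, years = 2016:2018,
                      rotation_matrix = diag(9), peat_expansion_rate = 0,
                      mean_patch_pixels = 60, seed = seed)
  simulate_landscape(cfg, observations = FALSE)
}

test_that("spectral-temporal percentiles use linear interpolation and respect nodata", {
  # constant series: any percentile equals the constant
  s <- observation_series(2018, c(10L, 100L, 200L),
                          matrix(rep(c(0.2, 0.2, 0.2, 0.3, 0.2, 0.2),
                                     each = 3), 3, 6))
  series <- list(list(s), list(NULL))
  m10 <- compute_stm(series, 1, 2, "nir", 10)
  m90 <- compute_stm(series, 1, 2, "nir", 90)
  expect_equal(m10[1, 1], 0.3)
  expect_equal(m90[1, 1], 0.3)
  expect_true(is.na(m10[1, 2]))   # no observations -> nodata
  # {0.1, 0.2, 0.3, 0.4} p90 -> 0.37 under linear interpolation
  vals <- c(0.1, 0.2, 0.3, 0.4)
  b <- matrix(0.2, 4, 6); b[, 4] <- vals; b[, 1] <- 0  # ndvi = 1? no:
  # use nir directly to keep the values exact
  s2 <- observation_series(2018, c(5L, 50L, 150L, 250L), b)
  expect_equal(compute_stm(list(list(s2)), 1, 1, "nir", 90)[1, 1], 0.37)
  # p10 <= p90 everywhere
  set.seed(431)
  sl <- lapply(1:12, function(i) list(random_series(sample(1:15, 1))))
  p10 <- compute_stm(sl, 3, 4, "ndvi", 10)
  p90 <- compute_stm(sl, 3, 4, "ndvi", 90)
  expect_true(all(p10 <= p90, na.rm = TRUE))
})

test_that("there are ten built-in rules transcribing the published thresholds", {
  rules <- builtin_rules()
  expect_identical(length(rules), 10L)
  expect_setequal(vapply(rules, function(r) r$target_name, ""),
                  c("Built-up", "Bareland", "Water", "Shrubland",
                    "Coniferous forest", "Broadleaf forest", "Wetland marsh",
                    "Exploited peat bog", "Unexploited peat bog",
                    "Cropland and Grassland"))
  # built-up: strict > 50 at the center, > 20 on the 24 surrounding pixels,
  # all five reference years
  bu <- rules$builtup
  expect_identical(bu$conditions[[2]]$op, ">")
  expect_identical(bu$conditions[[2]]$value, 50)
  expect_identical(bu$conditions[[1]]$quantifier, "ring")
  expect_identical(bu$conditions[[1]]$years,
                   as.integer(c(2006, 2009, 2012, 2015, 2018)))
  # water thresholds as printed
  expect_identical(rules$water$conditions[[1]]$product, "ndwi_p10")
  expect_identical(rules$water$conditions[[1]]$value, 0.3)
  expect_identical(rules$bareland$conditions[[1]]$op, "<")
  # the two bog rules share the coarse peat-bog code and differ only in
  # the finer product's exploited/unexploited code, all of 2006/2012/2018
  ex <- rules$exploited_bog; un <- rules$unexploited_bog
  expect_identical(ex$conditions[[1]]$value, un$conditions[[1]]$value)
  expect_false(identical(ex$conditions[[2]]$value, un$conditions[[2]]$value))
  expect_identical(ex$conditions[[2]]$years, as.integer(c(2006, 2012, 2018)))
  # tree-density thresholds: > 75 forest, < 30 shrubland
  expect_identical(rules$coniferous$conditions[[3]]$value, 75)
  expect_identical(rules$shrubland$conditions[[2]]$value, 30)
})

test_that("worked water-rule examples: eligible pixel, then one violated condition", {
  # 3 x 3 stack, center pixel satisfies every water condition
  mk <- function(v) matrix(v, 3, 3)
  years5 <- as.character(c(2006, 2009, 2012, 2015, 2018))
  imp <- lapply(years5, function(y) mk(0)); names(imp) <- years5
  stack <- reference_stack(
    products = list(imperviousness = imp),
    stm = list(ndwi_p10 = mk(0.4), ndvi_p90 = mk(0.1)))
  mask <- evaluate_rule(stack, builtin_rules()$water)
  expect_true(all(mask))
  # imperviousness 5 in a single year breaks eligibility
  stack$products$imperviousness[["2012"]][2, 2] <- 5
  mask2 <- evaluate_rule(stack, builtin_rules()$water)
  expect_false(mask2[2, 2])
  expect_true(mask2[1, 1])
  # missing product year is an explicit, named error
  stack$products$imperviousness[["2009"]] <- NULL
  expect_error(evaluate_rule(stack, builtin_rules()$water), "2009")
})

test_that("rule evaluation equals the exhaustive per-pixel oracle on random stacks", {
  set.seed(433)
  for (rep in 1:6) {
    d <- c(9, 9)
    years <- as.character(2016:2018)
    mkp <- function(gen) {
      out <- lapply(years, function(y) gen())
      names(out) <- years
      out
    }
    stack <- reference_stack(
      products = list(
        imperviousness = mkp(function() matrix(sample(c(0, 0, 30, 80), 81,
                                                      TRUE), 9, 9)),
        tree_density = mkp(function() matrix(runif(81, 0, 100), 9, 9)),
        forest_type = mkp(function() matrix(sample(0:2, 81, TRUE), 9, 9)),
        clc_code = mkp(function() matrix(sample(c(311L, 312L, 412L, 211L),
                                                81, TRUE), 9, 9)),
        n2k_code = mkp(function() matrix(sample(c(3110L, 3120L, 4120L,
                                                  4130L, 2110L), 81, TRUE),
                                         9, 9))),
      stm = list(ndvi_p90 = matrix(runif(81, -1, 1), 9, 9),
                 ndwi_p10 = matrix(runif(81, -1, 1), 9, 9)))
    rule <- rule_spec("random", 5L, list(
      rule_condition("clc_code", "==", 312L, 2016:2018, 5L, "all"),
      rule_condition("tree_density", ">", 40, 2017:2018, 5L, "all"),
      rule_condition("imperviousness", ">", 10, 2016L, 5L, "ring"),
      rule_condition("ndvi_p90", "<", 0.5),
      rule_condition("n2k_code", "in", c(3120L, 4130L), 2018L)
    ))
    expect_identical(evaluate_rule(stack, rule), oracle_rule(stack, rule))
    # anti-monotonicity: a rule with fewer conditions is never smaller
    sub <- rule_spec("sub", 5L, rule$conditions[1:2])
    expect_true(all(evaluate_rule(stack, sub) | !evaluate_rule(stack, rule)))
  }
})

test_that("on clean synthetic stacks every mined point carries its rule's target class", {
  sc <- make_test_scene()
  stack <- simulate_reference_products(sc$truth)
  truth <- sc$truth$values[, , 1]
  rules <- builtin_rules()
  found <- 0L
  for (rn in names(rules)) {
    mask <- evaluate_rule(stack, rules[[rn]])
    if (!any(mask)) next
    found <- found + 1L
    got <- truth[mask]
    if (rules[[rn]]$target_level == 1L) {
      expect_true(all(level1_of(got) == rules[[rn]]$target_code),
                  label = paste("rule", rn))
    } else {
      expect_true(all(got == rules[[rn]]$target_code),
                  label = paste("rule", rn))
    }
  }
  expect_gte(found, 6L)
})

test_that("point sampling honours caps, reproducibility, and empty masks", {
  set.seed(434)
  mask <- matrix(runif(150 * 110) < 0.95, 150, 110)  # ~15,680 eligible
  expect_gt(sum(mask), 15000)
  pts <- sample_points(mask, cap = 10000, code = 3L, seed = 8)
  expect_identical(nrow(pts), 10000L)
  expect_true(all(mask[cbind(pts$row, pts$col)]))
  small <- matrix(FALSE, 50, 50); small[sample(2500, 200)] <- TRUE
  expect_identical(nrow(sample_points(small, cap = 10000, seed = 8)), 200L)
  # same seed -> same set; different seed -> different set
  a <- sample_points(mask, 500, seed = 1)
  b <- sample_points(mask, 500, seed = 1)
  c_ <- sample_points(mask, 500, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a, c_))
  expect_warning(out <- sample_points(matrix(FALSE, 4, 4), 10), "empty")
  expect_identical(nrow(out), 0L)
})

test_that("crop parcels rasterize by pixel center with overlap conflicts dropped", {
  g <- tile_grid(origin = c(0, 0), tile_size = 3000, pixel_size = 30)
  # one 90 m x 90 m parcel aligned to the grid -> 9 pixels
  p1 <- data.frame(xmin = 60, ymin = 60, xmax = 150, ymax = 150,
                   year = 2019L, code = 10L)
  lab <- rasterize_crop_parcels(p1, g, rows = 10, cols = 10)
  expect_identical(nrow(lab), 9L)
  expect_true(all(lab$code == 10L))
  # overlapping parcels: the 3-pixel overlap column is unlabeled
  p2 <- rbind(p1, data.frame(xmin = 120, ymin = 60, xmax = 210, ymax = 150,
                             year = 2019L, code = 11L))
  lab2 <- rasterize_crop_parcels(p2, g, rows = 10, cols = 10)
  expect_identical(nrow(lab2), 12L)   # 9 + 9 - 2*3 overlap
  expect_false(any(lab2$x > 120 & lab2$x < 150 & lab2$code == 10L))
  # empty input and unknown labels
  expect_identical(nrow(rasterize_crop_parcels(p1[0, ], g, 10, 10)), 0L)
  p_bad <- p1; p_bad$code <- 7L
  expect_error(rasterize_crop_parcels(p_bad, g, 10, 10), "7")
})

test_that("rule sets round trip through the YAML schema with identical behaviour", {
  td <- withr::local_tempdir()
  rules <- builtin_rules()
  f <- file.path(td, "rules.yaml")
  write_rules_yaml(rules, f)
  back <- read_rules_yaml(f)
  expect_identical(names(back), names(rules))
  sc <- make_test_scene(seed = 63)
  stack <- simulate_reference_products(sc$truth)
  for (rn in names(rules)) {
    expect_identical(evaluate_rule(stack, back[[rn]]),
                     evaluate_rule(stack, rules[[rn]]),
                     label = rn)
  }
})
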
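#' Rule-based training-pixel mining
#'
#' A rule is a conjunction of conditions on reference products; a pixel is
#' eligible for the rule's target class only if every condition holds.
#' Focal conditions ("all" / "ring" quantifiers) require every pixel of
#' the window (resp. every surrounding pixel) to satisfy the per-pixel
#' predicate; windows touching the raster edge or nodata are ineligible.
#'
#' @param target_name target class name.
#' @param target_code legend code the rule mines points for (Level-2 code,
#'   or the Level-1 code 8 for the joint cropland-and-grassland rule).
#' @param target_level 1 or 2.
#' @param conditions list of [rule_condition()]s.
#' @return object of class `rule_spec`.
#' @export
rule_spec <- function(target_name, target_code, conditions, target_level = 2L) {
  stopifnot(length(conditions) >= 1)
  structure(list(target_name = target_name,
                 target_code = as.integer(target_code),
                 target_level = as.integer(target_level),
                 conditions = conditions),
            class = "rule_spec")
}

#' One condition of a sampling rule
#'
#' @param product product name: a per-year product of the reference stack
#'   (`imperviousness`, `tree_density`, `forest_type`, `clc_code`,
#'   `n2k_code`), a period STM layer (`ndvi_p10`, `ndvi_p90`, `ndwi_p10`,
#'   `ndwi_p90`), or `"clc+n2k"` for paired-agreement conditions.
#' @param op one of `">"`, `">="`, `"<"`, `"<="`, `"=="`, `"in"`,
#'   `"paired_in"`.
#' @param value threshold, code set, or (for `paired_in`) a list of two
#'   parallel vectors `list(clc, n2k)` of agreeing code pairs.
#' @param years integer years the condition must hold in (NULL for period
#'   STM layers).
#' @param window focal window edge (1 = center pixel only, or 5).
#' @param quantifier `"center"`, `"all"` (every window pixel) or `"ring"`
#'   (every surrounding pixel, center excluded).
#' @return object of class `rule_condition`.
#' @export
rule_condition <- function(product, op, value, years = NULL, window = 1L,
                           quantifier = c("center", "all", "ring")) {
  quantifier <- match.arg(quantifier)
  stopifnot(op %in% c(">", ">=", "<", "<=", "==", "in", "paired_in"),
            window %% 2 == 1)
  if (window == 1L) quantifier <- "center"
  structure(list(product = product, op = op, value = value,
                 years = if (is.null(years)) NULL else as.integer(years),
                 window = as.integer(window), quantifier = quantifier),
            class = "rule_condition")
}

# integral-image box sum of a 0/1 matrix; returns matrix of full-window
# sums (NA where the window leaves the grid)
box_sum <- function(m, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  if (nr < w || nc < w) return(out)
  ii <- rbind(0, apply(m, 2, cumsum))
  ii <- cbind(0, t(apply(ii, 1, cumsum)))
  r <- 1:(nr - w + 1L); cc <- 1:(nc - w + 1L)
  band <- ii[r + w, cc + w, drop = FALSE] - ii[r, cc + w, drop = FALSE] -
    ii[r + w, cc, drop = FALSE] + ii[r, cc, drop = FALSE]
  out[(h + 1L):(nr - h), (h + 1L):(nc - h)] <- band
  out
}

fetch_layer <- function(stack, product, year = NULL) {
  if (product %in% names(stack$stm)) return(stack$stm[[product]])
  if (!product %in% names(stack$products)) {
    stop("reference stack has no product '", product, "'")
  }
  layers <- stack$products[[product]]
  if (is.null(year)) stop("condition on '", product, "' must state years")
  y <- as.character(year)
  if (!y %in% names(layers)) {
    stop("product '", product, "' missing year ", year)
  }
  layers[[y]]
}

pixel_predicate <- function(stack, cond, year) {
  if (cond$op == "paired_in") {
    a <- fetch_layer(stack, "clc_code", year)
    b <- fetch_layer(stack, "n2k_code", year)
    ok <- matrix(FALSE, nrow(a), ncol(a))
    for (k in seq_along(cond$value[[1]])) {
      ok <- ok | (a == cond$value[[1]][k] & b == cond$value[[2]][k])
    }
    return(ok)
  }
  m <- fetch_layer(stack, cond$product, year)
  out <- switch(cond$op,
                ">" = m > cond$value,
                ">=" = m >= cond$value,
                "<" = m < cond$value,
                "<=" = m <= cond$value,
                "==" = m == cond$value,
                "in" = matrix(m %in% cond$value, nrow(m), ncol(m)))
  out[is.na(out)] <- FALSE
  out
}

apply_quantifier <- function(ok, window, quantifier) {
  if (quantifier == "center" || window == 1L) return(ok)
  s <- box_sum(ok * 1, window)
  full <- window^2
  res <- if (quantifier == "all") s == full else s - ok >= full - 1
  res[is.na(res)] <- FALSE
  res
}

#' Evaluate a sampling rule over a reference stack
#'
#' @param stack a [reference_stack()].
#' @param rule a [rule_spec()].
#' @return logical eligibility matrix (TRUE = pixel eligible).
#' @export
evaluate_rule <- function(stack, rule) {
  stopifnot(inherits(stack, "reference_stack"), inherits(rule, "rule_spec"))
  mask <- matrix(TRUE, stack$dim[1], stack$dim[2])
  for (cond in rule$conditions) {
    years <- if (is.null(cond$years)) list(NULL) else as.list(cond$years)
    ok <- matrix(TRUE, stack$dim[1], stack$dim[2])
    for (y in years) {
      ok <- ok & pixel_predicate(stack, cond, y)
    }
    mask <- mask & apply_quantifier(ok, cond$window, cond$quantifier)
  }
  mask
}

#' Built-in sampling rules for the ten non-crop-specific classes
#'
#' Transcribes the ten rule-based mining procedures: thresholds, strict/
#' non-strict inequalities, focal window sizes and reference epochs
#' ({2006, 2009, 2012, 2015, 2018} for imperviousness; {2006, 2012, 2018}
#' for the categorical products; {2012, 2015, 2018} for tree density) as
#' published, against the synthetic product dictionaries of
#' [reference_code_tables()]. The built-up rule requires the 24
#' surrounding pixels above 20% imperviousness and the center strictly
#' above 50% in all five years.
#'
#' @return named list of 10 [rule_spec()]s.
#' @export
builtin_rules <- function() {
  tb <- reference_code_tables()
  y5 <- c(2006, 2009, 2012, 2015, 2018)
  y3c <- c(2006, 2012, 2018)       # categorical products
  y3d <- c(2012, 2015, 2018)       # tree density
  rules <- list(
    builtup = rule_spec("Built-up", 1L, list(
      rule_condition("imperviousness", ">", 20, y5, 5L, "ring"),
      rule_condition("imperviousness", ">", 50, y5, 1L)
    )),
    bareland = rule_spec("Bareland", 2L, list(
      rule_condition("ndvi_p90", "<", 0.3),
      rule_condition("ndwi_p90", "<", 0),
      rule_condition("imperviousness", "==", 0, y5)
    )),
    water = rule_spec("Water", 3L, list(
      rule_condition("ndwi_p10", ">", 0.3),
      rule_condition("ndvi_p90", "<", 0.3),
      rule_condition("imperviousness", "==", 0, y5)
    )),
    shrubland = rule_spec("Shrubland", 4L, list(
      rule_condition("clc+n2k", "paired_in",
                     list(tb$clc_shrub, tb$n2k_shrub), y3c),
      rule_condition("tree_density", "<", 30, y3d),
      rule_condition("imperviousness", "==", 0, y5)
    )),
    coniferous = rule_spec("Coniferous forest", 5L, list(
      rule_condition("clc_code", "==", 312L, y3c, 5L, "all"),
      rule_condition("forest_type", "==", tb$forest_type[["coniferous"]],
                     y3d, 5L, "all"),
      rule_condition("tree_density", ">", 75, y3d, 5L, "all")
    )),
    broadleaf = rule_spec("Broadleaf forest", 6L, list(
      rule_condition("clc_code", "==", 311L, y3c, 5L, "all"),
      rule_condition("forest_type", "==", tb$forest_type[["broadleaf"]],
                     y3c, 5L, "all"),
      rule_condition("tree_density", ">", 75, y3d, 5L, "all")
    )),
    wetland_marsh = rule_spec("Wetland marsh", 7L, list(
      rule_condition("clc_code", "in", tb$clc_marsh, y3c, 5L, "all"),
      rule_condition("n2k_code", "in", tb$n2k_marsh, y3c, 5L, "all")
    )),
    exploited_bog = rule_spec("Exploited peat bog", 8L, list(
      rule_condition("clc_code", "==", tb$clc_bog, y3c, 5L, "all"),
      rule_condition("n2k_code", "==", tb$n2k_exploited, y3c, 5L, "all")
    )),
    unexploited_bog = rule_spec("Unexploited peat bog", 9L, list(
      rule_condition("clc_code", "==", tb$clc_bog, y3c, 5L, "all"),
      rule_condition("n2k_code", "==", tb$n2k_unexploited, y3c, 5L, "all")
    )),
    cropland_grassland = rule_spec("Cropland and Grassland", 8L, list(
      rule_condition("clc+n2k", "paired_in",
                     list(tb$clc_cropgrass, tb$n2k_cropgrass), y3c, 5L, "all"),
      rule_condition("tree_density", "==", 0, y3d, 5L, "all"),
      rule_condition("imperviousness", "==", 0, y5, 5L, "all")
    ), target_level = 1L)
  )
  rules
}

#' Sample training points from an eligibility mask
#'
#' Draws `min(cap, eligible)` pixels uniformly without replacement and
#' returns their pixel-center coordinates. The invariant-class cap is
#' 10,000 points per class; crop sampling uses 50,000.
#'
#' @param mask logical eligibility matrix.
#' @param cap maximum number of points (> 0).
#' @param code class code attached to the points.
#' @param year year attached to the points (NA for period-invariant points).
#' @param seed optional integer seed.
#' @param pixel_size,xmin,ymax georeference of the mask grid.
#' @return data.frame `x`, `y`, `year`, `code`, `row`, `col`.
#' @export
sample_points <- function(mask, cap = 10000, code = NA_integer_,
                          year = NA_integer_, seed = NULL,
                          pixel_size = 30, xmin = 0,
                          ymax = nrow(mask) * pixel_size) {
  stopifnot(cap > 0)
  if (!is.null(seed)) set.seed(seed)
  idx <- which(mask)
  if (length(idx) == 0L) {
    warning("empty eligibility mask: no points sampled")
    return(data.frame(x = numeric(0), y = numeric(0), year = integer(0),
                      code = integer(0), row = integer(0), col = integer(0)))
  }
  take <- if (length(idx) > cap) sample(idx, cap) else idx[sample.int(length(idx))]
  row <- (take - 1L) %% nrow(mask) + 1L
  col <- (take - 1L) %/% nrow(mask) + 1L
  data.frame(x = xmin + (col - 0.5) * pixel_size,
             y = ymax - (row - 0.5) * pixel_size,
             year = year, code = code, row = row, col = col)
}

#' Write sampling rules to a YAML file
#'
#' Serialises rules in a flat product/op/value/years/window/quantifier
#' schema so rule sets can be reviewed and edited outside R.
#'
#' @param rules named list of [rule_spec()]s.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_rules_yaml <- function(rules, path) {
  ser <- lapply(rules, function(r) {
    list(target_name = r$target_name, target_code = r$target_code,
         target_level = r$target_level,
         conditions = lapply(r$conditions, function(cond) {
           out <- list(product = cond$product, op = cond$op,
                       window = cond$window, quantifier = cond$quantifier)
           if (cond$op == "paired_in") {
             out$value_clc <- cond$value[[1]]
             out$value_n2k <- cond$value[[2]]
           } else {
             out$value <- cond$value
           }
           if (!is.null(cond$years)) out$years <- cond$years
           out
         }))
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read sampling rules from a YAML file
#'
#' @param path YAML path written by [write_rules_yaml()] (or hand-edited
#'   in the same schema).
#' @return named list of [rule_spec()]s.
#' @export
read_rules_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    conds <- lapply(r$conditions, function(cond) {
      value <- if (cond$op == "paired_in") {
        list(as.integer(cond$value_clc), as.integer(cond$value_n2k))
      } else cond$value
      rule_condition(cond$product, cond$op, value,
                     years = cond$years, window = cond$window,
                     quantifier = cond$quantifier)
    })
    rule_spec(r$target_name, r$target_code, conds,
              target_level = r$target_level)
  })
}
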
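#' Land-cover legend
#'
#' The hierarchical legend used throughout the pipeline: eight general
#' Level-1 classes, of which Wetland is subdivided into three subtypes and
#' Cropland & Grassland into nine (eight crop types plus grassland), giving
#' eighteen final Level-2 map codes (1-18).
#'
#' Level-1 prediction uses codes 1-6 for the six non-subdivided classes plus
#' two parent codes (see [level1_legend()]); the final maps carry only the
#' eighteen Level-2 codes.
#'
#' @return A data.frame with columns `code` (integer 1-18), `name`,
#'   `level1` (the Level-1 parent class name) and `level1_code`.
#' @examples
#' lc_legend()
#' @export
lc_legend <- function() {
  data.frame(
    code = 1:18,
    name = c(
      "Built-up", "Bareland", "Water", "Shrubland", "Coniferous forest",
      "Broadleaf forest", "Wetland marsh", "Exploited peat bog",
      "Unexploited peat bog", "Wheat", "Barley", "Rye", "Oats", "Maize",
      "Seed crops", "Root crops", "Pulses, vegetables", "Grassland"
    ),
    level1 = c(
      "Built-up", "Bareland", "Water", "Shrubland", "Coniferous forest",
      "Broadleaf forest", rep("Wetland", 3), rep("Cropland and Grassland", 9)
    ),
    level1_code = c(1:6, rep(7L, 3), rep(8L, 9)),
    stringsAsFactors = FALSE
  )
}

#' Level-1 legend (eight general classes)
#'
#' @return A data.frame with columns `code` (1-8) and `name`.
#' @export
level1_legend <- function() {
  data.frame(
    code = 1:8,
    name = c(
      "Built-up", "Bareland", "Water", "Shrubland", "Coniferous forest",
      "Broadleaf forest", "Wetland", "Cropland and Grassland"
    ),
    stringsAsFactors = FALSE
  )
}

#' Nodata code used in label rasters
#'
#' Label rasters are byte-typed with legal codes 1-18; 0 marks nodata,
#' consistent with the zero-fill convention of the temporal encoder.
#' @export
LC_NODATA <- 0L

#' Map Level-2 codes to Level-1 codes
#'
#' @param codes integer vector of Level-2 codes (1-18); 0/nodata passes through.
#' @return integer vector of Level-1 codes (1-8), nodata preserved.
#' @export
level1_of <- function(codes) {
  lut <- c(1:6, rep(7L, 3), rep(8L, 9))
  out <- rep(LC_NODATA, length(codes))
  ok <- !is.na(codes) & codes >= 1L & codes <= 18L
  out[ok] <- lut[codes[ok]]
  out[is.na(codes)] <- NA_integer_
  out
}

#' Validate a vector or grid of map codes against the legend
#'
#' @param codes integer codes (matrix or vector); 0 is accepted as nodata.
#' @param allow_nodata accept code 0.
#' @return invisibly `TRUE`; stops with a message listing offending codes.
#' @export
validate_codes <- function(codes, allow_nodata = TRUE) {
  legal <- 1:18
  if (allow_nodata) legal <- c(LC_NODATA, legal)
  bad <- setdiff(unique(as.vector(codes[!is.na(codes)])), legal)
  if (length(bad) > 0L) {
    stop("codes outside legend (1-18): ", paste(sort(bad), collapse = ", "))
  }
  invisible(TRUE)
}

#' Print the legend with Level-1 grouping
#'
#' Prints the eighteen code-name pairs grouped under their Level-1 parents.
#'
#' @return the legend data.frame, invisibly.
#' @export
describe_legend <- function() {
  leg <- lc_legend()
  for (l1 in unique(leg$level1)) {
    cat(l1, "\n")
    sub <- leg[leg$level1 == l1, ]
    for (k in seq_len(nrow(sub))) {
      cat(sprintf("  %2d  %s\n", sub$code[k], sub$name[k]))
    }
  }
  invisible(leg)
}
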
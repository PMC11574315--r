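#' Assemble a training set of labeled pixel series
#'
#' Each sample carries one label and one or more annual observation series.
#' Period-invariant samples (mined by the sampling rules) carry the series
#' of every simulated year, and training draws one year per epoch; crop
#' samples carry only their labeled year.
#'
#' @param labels integer class labels (any coding; the model records the
#'   sorted unique codes).
#' @param series_list list (parallel to `labels`) of lists of
#'   [observation_series()].
#' @return object of class `lc_training_set`: pooled observation arrays
#'   for fast per-epoch augmentation and encoding.
#' @export
make_training_set <- function(labels, series_list) {
  stopifnot(length(labels) == length(series_list), length(labels) > 0)
  n <- length(labels)
  blocks <- list()
  doy <- list(); val <- list()
  sample_blocks <- vector("list", n)
  pos <- 0L
  bid <- 0L
  for (i in seq_len(n)) {
    sl <- series_list[[i]]
    stopifnot(length(sl) >= 1)
    ids <- integer(length(sl))
    for (j in seq_along(sl)) {
      s <- sl[[j]]
      keep <- s$clear
      bid <- bid + 1L
      m <- sum(keep)
      blocks[[bid]] <- c(start = pos + 1L, len = m)
      if (m > 0L) {
        doy[[bid]] <- s$doy[keep]
        val[[bid]] <- s$values[keep, , drop = FALSE]
      }
      pos <- pos + m
      ids[j] <- bid
    }
    sample_blocks[[i]] <- ids
  }
  bt <- do.call(rbind, blocks)
  structure(list(
    n = n, labels = as.integer(labels),
    classes = sort(unique(as.integer(labels))),
    doy = unlist(doy, use.names = FALSE),
    values = do.call(rbind, val),
    block_start = bt[, "start"], block_len = bt[, "len"],
    sample_blocks = sample_blocks
  ), class = "lc_training_set")
}

#' @export
print.lc_training_set <- function(x, ...) {
  cat(sprintf("lc_training_set: %d samples, %d classes, %d observations\n",
              x$n, length(x$classes), length(x$doy)))
  invisible(x)
}

# one epoch's encoded design matrix: draw a year block per sample, apply
# day shifting and observation selection, bin into 52 weeks
epoch_encode <- function(ts, augment) {
  n <- ts$n
  pick <- vapply(ts$sample_blocks, function(b) {
    if (length(b) == 1L) b else b[sample.int(length(b), 1L)]
  }, 0L)
  starts <- ts$block_start[pick]
  lens <- ts$block_len[pick]
  X <- array(0, c(n, 52, 9))
  if (sum(lens) == 0L) return(X)
  rows <- sequence(lens, from = starts)
  ids <- rep.int(seq_len(n), lens)
  doy <- ts$doy[rows]
  keep <- rep(TRUE, length(rows))
  if (!is.null(augment$max_shift) && augment$max_shift > 0) {
    off <- sample.int(2L * augment$max_shift + 1L, n, replace = TRUE) -
      augment$max_shift - 1L
    doy <- doy + off[ids]
    keep <- doy >= 1L & doy <= 365L
  }
  if (!is.null(augment$keep_range)) {
    p <- stats::runif(n, augment$keep_range[1], augment$keep_range[2])
    sel <- stats::runif(length(rows)) < p[ids]
    # retain at least one in-range observation per sample
    cnt <- tabulate(ids[keep & sel], n)
    short <- which(cnt == 0L & tabulate(ids[keep], n) > 0L)
    for (i in short) {
      cand <- which(ids == i & keep)
      sel[cand[sample.int(length(cand), 1L)]] <- TRUE
    }
    keep <- keep & sel
  }
  if (!any(keep)) return(X)
  ids <- ids[keep]; doy <- doy[keep]
  vals <- ts$values[rows[keep], , drop = FALSE]
  key <- (ids - 1L) * 52L + week_of_doy(doy)
  sums <- rowsum(vals, key)
  cnt <- as.vector(table(factor(key, levels = sort(unique(key)))))
  k <- as.integer(rownames(sums))
  samp <- k %/% 52L + 1L
  week <- k %% 52L + 1L
  for (b in 1:9) X[cbind(samp, week, b)] <- sums[, b] / cnt
  X
}

#' Train the temporal-convolution classifier
#'
#' Deterministic given `(spec, samples, seed)` on one device. Both
#' augmentations are applied on the fly each epoch, and samples holding
#' several annual series get one drawn uniformly per epoch.
#'
#' @param spec a [cnn_spec()]; its `n_classes` must equal the number of
#'   distinct labels.
#' @param samples an [make_training_set()] object.
#' @param seed integer seed.
#' @param verbose print per-epoch loss.
#' @return object of class `lc_model`.
#' @export
train <- function(spec, samples, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "cnn_spec"), inherits(samples, "lc_training_set"))
  if (length(samples$classes) < 2L) stop("training needs at least 2 classes")
  if (length(samples$classes) != spec$n_classes) {
    stop("spec expects ", spec$n_classes, " classes; training set has ",
         length(samples$classes))
  }
  if (anyNA(samples$values) || any(!is.finite(samples$values))) {
    stop("NaN/Inf in training features")
  }
  set.seed(seed)
  params <- cnn_init(spec)
  state <- adam_init(params)
  n <- samples$n
  y <- match(samples$labels, samples$classes)
  w_class <- if (spec$class_weights) {
    cw <- n / (spec$n_classes * tabulate(y, spec$n_classes))
    cw / mean(cw)
  } else rep(1, spec$n_classes)
  t_step <- 0L
  for (ep in seq_len(spec$epochs)) {
    X <- epoch_encode(samples, spec$augment)
    ord <- sample.int(n)
    loss_sum <- 0
    for (b0 in seq(1L, n, by = spec$batch_size)) {
      idx <- ord[b0:min(b0 + spec$batch_size - 1L, n)]
      Xb <- X[idx, , , drop = FALSE]
      yb <- y[idx]
      fw <- cnn_forward(params, Xb, spec, train = TRUE)
      P <- fw$prob
      wb <- w_class[yb]
      picked <- P[cbind(seq_along(yb), yb)]
      loss_sum <- loss_sum + sum(-wb * log(pmax(picked, 1e-12)))
      dlogits <- P
      dlogits[cbind(seq_along(yb), yb)] <-
        dlogits[cbind(seq_along(yb), yb)] - 1
      dlogits <- dlogits * (wb / sum(wb))
      g <- cnn_backward(params, spec, fw$cache, dlogits)
      t_step <- t_step + 1L
      res <- adam_step(params, g, state, spec$lr, t_step)
      params <- res$p
      state <- res$s
    }
    if (verbose) {
      message(sprintf("epoch %d/%d  weighted loss %.4f", ep, spec$epochs,
                      loss_sum / n))
    }
  }
  structure(list(spec = spec, params = params, classes = samples$classes,
                 seed = seed),
            class = "lc_model")
}

#' @export
print.lc_model <- function(x, ...) {
  cat(sprintf("lc_model: %d classes (%s), %s conv filters\n",
              length(x$classes), paste(x$classes, collapse = ","),
              paste(x$spec$conv_filters, collapse = "/")))
  invisible(x)
}

#' Class-probability prediction
#'
#' @param model an [train()]ed `lc_model`.
#' @param X encoded samples: array N x 52 x 9 (see [encode_weekly_batch()])
#'   or a single 52 x 9 matrix.
#' @param chunk prediction batch size.
#' @return N x n_classes matrix of probabilities (rows sum to 1), columns
#'   named by class code.
#' @export
predict_proba <- function(model, X, chunk = 1024L) {
  stopifnot(inherits(model, "lc_model"))
  if (is.matrix(X)) X <- array(X, c(1, dim(X)))
  d <- dim(X)
  if (length(d) != 3 || d[2] != model$spec$weeks || d[3] != model$spec$bands) {
    stop("sample shape mismatch: expected N x ", model$spec$weeks, " x ",
         model$spec$bands)
  }
  out <- matrix(0, d[1], model$spec$n_classes,
                dimnames = list(NULL, model$classes))
  for (b0 in seq(1L, d[1], by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, d[1])
    out[idx, ] <- cnn_forward(model$params, X[idx, , , drop = FALSE],
                              model$spec, train = FALSE)$prob
  }
  out
}

#' Hard class prediction
#'
#' @inheritParams predict_proba
#' @return integer vector of class codes (argmax).
#' @export
predict_class <- function(model, X, chunk = 1024L) {
  p <- predict_proba(model, X, chunk)
  model$classes[max.col(p, ties.method = "first")]
}

#' Hierarchical model specification
#'
#' Bundles the Level-1 model (8 general classes) with the two Level-2
#' specialists: the wetland model (codes 7, 8, 9) and the cropland/
#' grassland model (codes 10-18). Level-1 classes 1-6 pass through to the
#' final legend unchanged.
#'
#' @param level1 `lc_model` over Level-1 codes 1-8.
#' @param level2_wetland `lc_model` over codes 7-9.
#' @param level2_crop `lc_model` over codes 10-18.
#' @return object of class `lc_hierarchy`.
#' @export
hierarchy_spec <- function(level1, level2_wetland, level2_crop) {
  stopifnot(identical(level1$classes, 1:8),
            identical(level2_wetland$classes, 7:9),
            identical(level2_crop$classes, 10:18))
  structure(list(level1 = level1, level2_wetland = level2_wetland,
                 level2_crop = level2_crop),
            class = "lc_hierarchy")
}

#' Hierarchical Level-1 then Level-2 prediction
#'
#' Argmax of the Level-1 model per sample; samples mapped to Wetland get
#' the wetland specialist's argmax (codes 7-9), samples mapped to Cropland
#' and Grassland get the crop specialist's argmax (codes 10-18); the six
#' remaining Level-1 classes pass through as final codes 1-6.
#'
#' @param h an [hierarchy_spec()].
#' @param X encoded samples, array N x 52 x 9.
#' @return integer vector of final legend codes (1-18).
#' @export
hierarchical_predict <- function(h, X) {
  stopifnot(inherits(h, "lc_hierarchy"))
  if (is.matrix(X)) X <- array(X, c(1, dim(X)))
  l1 <- predict_class(h$level1, X)
  out <- l1
  wet <- which(l1 == 7L)
  if (length(wet) > 0L) {
    out[wet] <- predict_class(h$level2_wetland, X[wet, , , drop = FALSE])
  }
  crop <- which(l1 == 8L)
  if (length(crop) > 0L) {
    out[crop] <- predict_class(h$level2_crop, X[crop, , , drop = FALSE])
  }
  out
}
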
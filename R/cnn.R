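#' Temporal-convolution model specification
#'
#' Reference architecture for classifying 52 x 9 weekly-encoded samples:
#' convolution blocks applied along the temporal (week) dimension, each
#' followed by ReLU and max-pooling, then a dense ReLU layer with dropout
#' and a softmax head. Missing weeks enter as zeros (no mask channel).
#' Training uses Adam, weighted cross-entropy (inverse-frequency class
#' weights), and both augmentations (random observation selection, random
#' day shifting) applied on the fly; samples carrying several annual
#' series get one drawn uniformly per epoch.
#'
#' @param n_classes number of classes (8 for Level 1, 3 and 9 for the two
#'   Level-2 specialists).
#' @param conv_filters filters per convolution block.
#' @param kernel temporal kernel length (weeks), `<= 52`.
#' @param pool max-pooling length per block.
#' @param dense width of the fully-connected layer.
#' @param dropout dropout probability on the dense layer during training.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param class_weights use inverse-frequency class weights.
#' @param augment list: `keep_range` for random observation selection
#'   (NULL disables), `max_shift` days for random day shifting (0 disables).
#' @param weeks,bands input shape (fixed by the encoder).
#' @return object of class `cnn_spec`.
#' @export
cnn_spec <- function(n_classes, conv_filters = c(32, 64, 64), kernel = 5,
                     pool = 2, dense = 128, dropout = 0.3, lr = 1e-3,
                     batch_size = 256, epochs = 30, class_weights = TRUE,
                     augment = list(keep_range = c(0.25, 1), max_shift = 7),
                     weeks = 52, bands = 9) {
  stopifnot(n_classes >= 2, kernel <= weeks, all(conv_filters > 0),
            dense > 0, dropout >= 0, dropout < 1, batch_size > 0, epochs > 0)
  # check the temporal dimension survives the conv/pool stack
  L <- weeks
  for (f in conv_filters) {
    L <- L - kernel + 1
    if (L < 1) stop("kernel too long for ", length(conv_filters), " blocks")
    L <- L %/% pool
    if (L < 1) stop("temporal dimension exhausted by pooling")
  }
  structure(list(n_classes = as.integer(n_classes),
                 conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 dense = as.integer(dense), dropout = dropout, lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), class_weights = class_weights,
                 augment = augment, weeks = as.integer(weeks),
                 bands = as.integer(bands), flat = L * utils::tail(conv_filters, 1)),
            class = "cnn_spec")
}

cnn_init <- function(spec) {
  he <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  }
  cin <- spec$bands
  conv <- list()
  for (f in spec$conv_filters) {
    conv[[length(conv) + 1L]] <- list(W = he(spec$kernel * cin, f),
                                      b = numeric(f))
    cin <- f
  }
  list(conv = conv,
       dense = list(W = he(spec$flat, spec$dense), b = numeric(spec$dense)),
       out = list(W = he(spec$dense, spec$n_classes),
                  b = numeric(spec$n_classes)))
}

# im2col: X (N, L, C) -> matrix (N*Lout, K*C), rows ordered n fastest then t
im2col <- function(X, K) {
  d <- dim(X)
  N <- d[1]; L <- d[2]; C <- d[3]
  Lout <- L - K + 1L
  A <- array(0, c(N, Lout, K * C))
  for (k in seq_len(K)) {
    A[, , ((k - 1L) * C + 1L):(k * C)] <- X[, k:(k + Lout - 1L), , drop = FALSE]
  }
  dim(A) <- c(N * Lout, K * C)
  A
}

col2im <- function(dM, N, L, C, K) {
  Lout <- L - K + 1L
  dim(dM) <- c(N, Lout, K * C)
  dX <- array(0, c(N, L, C))
  for (k in seq_len(K)) {
    dX[, k:(k + Lout - 1L), ] <- dX[, k:(k + Lout - 1L), , drop = FALSE] +
      dM[, , ((k - 1L) * C + 1L):(k * C), drop = FALSE]
  }
  dX
}

cnn_forward <- function(params, X, spec, train = FALSE) {
  N <- dim(X)[1]
  cache <- list(conv = list())
  A <- X
  C <- spec$bands
  for (l in seq_along(params$conv)) {
    L <- dim(A)[2]
    M <- im2col(A, spec$kernel)
    Z <- M %*% params$conv[[l]]$W
    Z <- Z + rep(params$conv[[l]]$b, each = nrow(Z))
    R <- Z * (Z > 0)
    Fl <- ncol(Z)
    Lout <- L - spec$kernel + 1L
    dim(R) <- c(N, Lout, Fl)
    Lp <- Lout %/% spec$pool
    i1 <- seq(1L, by = spec$pool, length.out = Lp)
    P <- R[, i1, , drop = FALSE]
    argmax <- array(1L, dim(P))
    if (spec$pool > 1L) {
      for (j in 2:spec$pool) {
        cand <- R[, i1 + j - 1L, , drop = FALSE]
        better <- cand > P
        P[better] <- cand[better]
        argmax[better] <- j
      }
    }
    cache$conv[[l]] <- list(M = M, Z = Z, Lin = L, Lout = Lout, Lp = Lp,
                            argmax = argmax, Cin = C)
    A <- P
    C <- Fl
  }
  dP <- dim(A)
  Flat <- A
  dim(Flat) <- c(N, dP[2] * dP[3])
  Zd <- Flat %*% params$dense$W
  Zd <- Zd + rep(params$dense$b, each = N)
  H <- Zd * (Zd > 0)
  drop_mask <- NULL
  if (train && spec$dropout > 0) {
    drop_mask <- matrix(stats::runif(length(H)) >= spec$dropout,
                        nrow(H), ncol(H)) / (1 - spec$dropout)
    H <- H * drop_mask
  }
  logits <- H %*% params$out$W
  logits <- logits + rep(params$out$b, each = N)
  mx <- apply(logits, 1, max)
  E <- exp(logits - mx)
  P <- E / rowSums(E)
  cache$Flat <- Flat
  cache$Zd <- Zd
  cache$H <- H
  cache$drop_mask <- drop_mask
  cache$pool_dim <- dP
  list(prob = P, cache = cache)
}

cnn_backward <- function(params, spec, cache, dlogits) {
  N <- nrow(dlogits)
  g <- list(conv = vector("list", length(params$conv)))
  g$out <- list(W = crossprod(cache$H, dlogits), b = colSums(dlogits))
  dH <- tcrossprod(dlogits, params$out$W)
  if (!is.null(cache$drop_mask)) dH <- dH * cache$drop_mask
  dZd <- dH * (cache$Zd > 0)
  g$dense <- list(W = crossprod(cache$Flat, dZd), b = colSums(dZd))
  dFlat <- tcrossprod(dZd, params$dense$W)
  dA <- dFlat
  dim(dA) <- cache$pool_dim
  for (l in rev(seq_along(params$conv))) {
    cc <- cache$conv[[l]]
    Fl <- ncol(cc$Z)
    # un-pool: route each pooled gradient to its argmax time position
    dR <- numeric(N * cc$Lout * Fl)
    i1 <- seq(1L, by = spec$pool, length.out = cc$Lp)
    tpos <- rep(i1, each = N) + (as.vector(cc$argmax) - 1L)  # recycles over f
    flat <- rep.int(seq_len(N), cc$Lp * Fl) +
      (tpos - 1L) * N +
      rep(0:(Fl - 1L), each = N * cc$Lp) * (N * cc$Lout)
    dR[flat] <- as.vector(dA)
    dim(dR) <- c(N * cc$Lout, Fl)
    dZ <- dR * (cc$Z > 0)
    g$conv[[l]] <- list(W = crossprod(cc$M, dZ), b = colSums(dZ))
    if (l > 1L) {
      dM <- tcrossprod(dZ, params$conv[[l]]$W)
      dA <- col2im(dM, N, cc$Lin, cc$Cin, spec$kernel)
    }
  }
  g
}

adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p) && !is.null(p$W)) {
      list(W = list(m = p$W * 0, v = p$W * 0),
           b = list(m = p$b * 0, v = p$b * 0))
    } else {
      lapply(p, walk)
    }
  }
  walk(params)
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  walk <- function(p, g, s) {
    if (is.list(p) && !is.null(p$W)) {
      rW <- upd(p$W, g$W, s$W); rb <- upd(p$b, g$b, s$b)
      list(p = list(W = rW$p, b = rb$p), s = list(W = rW$s, b = rb$s))
    } else {
      if (!is.null(names(p))) {
        g <- g[names(p)]
        s <- s[names(p)]
      }
      ps <- Map(walk, p, g, s)
      list(p = lapply(ps, `[[`, "p"), s = lapply(ps, `[[`, "s"))
    }
  }
  walk(params, grads, state)
}
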
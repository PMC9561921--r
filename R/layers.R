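# Low-level neural-network primitives for the STA-CNN.
#
# Feature maps are stored as 4-d arrays with dim (C, B, T, F): channel
# (fastest), batch, time, filter. With this layout a time convolution is a
# zero-copy reshape to a (C*B) x (T*Fin) matrix times one dense banded
# (Toeplitz-structured) kernel matrix -- a single BLAS GEMM with no
# permutation -- and per-filter batch-norm statistics collapse over the
# leading dims. Backward passes are exact and are verified against finite
# differences in the test suite.

# cache for shape-dependent index vectors
.idx_cache <- new.env(parent = emptyenv())

.cache_get <- function(key, build) {
  if (is.null(.idx_cache[[key]])) .idx_cache[[key]] <- build()
  .idx_cache[[key]]
}

# Toeplitz index set for a time convolution: input length Tp (post-padding),
# kernel K, Fin -> Fout maps. Returns positions of the kernel entries inside
# the (Tp*Fin) x (Tout*Fout) matrix plus the map into the (K,Fin,Fout)
# weight array. Entry order is `to` fastest, then (k, fi, fo) in the weight
# array's own order, so weight gradients fold back with one colSums.
.toeplitz_idx <- function(Tp, K, Fin, Fout) {
  key <- paste("toep", Tp, K, Fin, Fout, sep = "_")
  .cache_get(key, function() {
    Tout <- Tp - K + 1L
    g <- expand.grid(to = seq_len(Tout), k = seq_len(K), fi = seq_len(Fin),
                     fo = seq_len(Fout))
    rows <- g$to + g$k - 1L + (g$fi - 1L) * Tp
    cols <- g$to + (g$fo - 1L) * Tout
    list(idx = rows + (cols - 1L) * (Tp * Fin),
         wmap = g$k + (g$fi - 1L) * K + (g$fo - 1L) * K * Fin,
         Tout = Tout, nrow = Tp * Fin, ncol = Tout * Fout)
  })
}

.band_matrix <- function(W, ti) {
  Kmat <- matrix(0, ti$nrow, ti$ncol)
  Kmat[ti$idx] <- W[ti$wmap]
  Kmat
}

# ---------------------------------------------------------------- conv time

# X: (C, B, T, Fin); W: (K, Fin, Fout); pad = c(left, right) zeros on time.
# No bias: every convolution here feeds a batch-norm layer, which makes a
# conv bias exactly redundant (its gradient is identically zero).
conv_time_forward <- function(X, W, pad = c(0L, 0L)) {
  d <- dim(X); C <- d[1]; B <- d[2]; Tt <- d[3]; Fin <- d[4]
  K <- dim(W)[1]; Fout <- dim(W)[3]
  Tp <- Tt + pad[1] + pad[2]
  if (pad[1] > 0 || pad[2] > 0) {
    Xp <- array(0, c(C, B, Tp, Fin))
    Xp[, , pad[1] + seq_len(Tt), ] <- X
  } else {
    Xp <- X
  }
  dim(Xp) <- c(C * B, Tp * Fin)
  ti <- .toeplitz_idx(Tp, K, Fin, Fout)
  Kmat <- .band_matrix(W, ti)
  Tout <- ti$Tout
  Y <- Xp %*% Kmat
  dim(Y) <- c(C, B, Tout, Fout)
  list(Y = Y, cache = list(Xm = Xp, Kmat = Kmat, dims = d, pad = pad,
                           K = K, Fin = Fin, Fout = Fout, Tp = Tp,
                           Tout = Tout))
}

conv_time_backward <- function(dY, cache) {
  d <- cache$dims; C <- d[1]; B <- d[2]; Tt <- d[3]; Fin <- d[4]
  Tout <- cache$Tout; Fout <- cache$Fout; Tp <- cache$Tp; K <- cache$K
  dim(dY) <- c(C * B, Tout * Fout)
  dXm <- tcrossprod(dY, cache$Kmat)              # (CB, Tp*Fin)
  dKmat <- crossprod(cache$Xm, dY)               # (Tp*Fin, Tout*Fout)
  ti <- .toeplitz_idx(Tp, K, Fin, Fout)
  dW <- array(colSums(matrix(dKmat[ti$idx], nrow = Tout)), c(K, Fin, Fout))
  dim(dXm) <- c(C, B, Tp, Fin)
  dX <- if (cache$pad[1] > 0 || cache$pad[2] > 0) {
    dXm[, , cache$pad[1] + seq_len(Tt), , drop = FALSE]
  } else dXm
  list(dX = dX, dW = dW)
}

# ------------------------------------------------------------- conv spatial

# Full-height spatial filter contracting channels and input filters.
# X: (C, B, T, Fin); W: (C, Fin, Fout) -> Y: (1, B, T, Fout)
conv_spatial_forward <- function(X, W) {
  d <- dim(X); C <- d[1]; B <- d[2]; Tt <- d[3]; Fin <- d[4]
  Fout <- dim(W)[3]
  Xm <- aperm(X, c(1L, 4L, 2L, 3L))              # (C, Fin, B, T)
  dim(Xm) <- c(C * Fin, B * Tt)
  Wm <- W
  dim(Wm) <- c(C * Fin, Fout)
  Ym <- crossprod(Wm, Xm)                        # (Fout, B*T)
  Y <- array(aperm(array(Ym, c(Fout, B, Tt)), c(2L, 3L, 1L)),
             c(1L, B, Tt, Fout))
  list(Y = Y, cache = list(Xm = Xm, Wm = Wm, dims = d, Fout = Fout))
}

conv_spatial_backward <- function(dY, cache) {
  d <- cache$dims; C <- d[1]; B <- d[2]; Tt <- d[3]; Fin <- d[4]
  Fout <- cache$Fout
  dYm <- matrix(aperm(array(dY, c(B, Tt, Fout)), c(3L, 1L, 2L)),
                nrow = Fout)                     # (Fout, B*T)
  dW <- array(tcrossprod(cache$Xm, dYm), c(C, Fin, Fout))
  dXm <- cache$Wm %*% dYm                        # (C*Fin, B*T)
  dim(dXm) <- c(C, Fin, B, Tt)
  dX <- aperm(dXm, c(1L, 3L, 4L, 2L))            # (C, B, T, Fin)
  list(dX = dX, dW = dW)
}

# ---------------------------------------------------------------- batchnorm

# Per-filter batch normalisation over all leading dims; the filter axis must
# be last. eps/momentum follow the usual framework defaults; the running
# variance stores the unbiased batch variance while normalisation uses the
# biased one.
bn_forward <- function(X, gamma, beta, running, mode, eps = 1e-5,
                       momentum = 0.1) {
  d <- dim(X); Ff <- d[length(d)]; n1 <- prod(d) / Ff
  if (mode == "train") {
    st <- cpp_colstats(X, n1)
    m <- st[, 1L]
    v <- pmax(st[, 2L] - m^2, 0)
    running$mean <- (1 - momentum) * running$mean + momentum * m
    running$var <- (1 - momentum) * running$var +
      momentum * v * n1 / max(n1 - 1L, 1)
  } else {
    m <- running$mean
    v <- running$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  a <- gamma * inv_sd
  Y <- cpp_affine_cols(X, a, beta - m * a, n1)
  dim(Y) <- d
  list(Y = Y, running = running,
       cache = list(X = X, m = m, inv_sd = inv_sd, gamma = gamma,
                    dims = d, n1 = n1, mode = mode))
}

bn_backward <- function(dY, cache) {
  r <- cpp_bn_backward(cache$X, dY, cache$m, cache$inv_sd, cache$gamma,
                       cache$n1, cache$mode == "train")
  dX <- r$dX
  dim(dX) <- cache$dims
  list(dX = dX, dgamma = r$dgamma, dbeta = r$dbeta)
}

# --------------------------------------------------------------------- misc

# ELU with alpha = 1: y = x (x > 0), exp(x) - 1 (x <= 0); the cached
# derivative is 1 (x > 0), exp(x) (x <= 0).
elu_forward <- function(X) {
  r <- cpp_elu(X)
  Y <- r$Y
  dim(Y) <- dim(X)
  list(Y = Y, cache = r$D)
}

elu_backward <- function(dY, cache) {
  dY * cache
}

dropout_forward <- function(X, p, mode) {
  if (mode != "train" || p <= 0) {
    return(list(Y = X, cache = NULL))
  }
  r <- cpp_dropout(X, p)
  Y <- r$Y
  dim(Y) <- dim(X)
  list(Y = Y, cache = r$mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

# Max-pool along time with equal size and stride; expects C == 1.
# X: (1, B, T, F) -> (1, B, T %/% pool, F)
maxpool_time_forward <- function(X, pool) {
  d <- dim(X); B <- d[2]; Tt <- d[3]; Ff <- d[4]
  Tout <- Tt %/% pool
  Xr <- array(X, c(B, Tt, Ff))[, seq_len(Tout * pool), , drop = FALSE]
  Xr <- matrix(aperm(array(Xr, c(B, pool, Tout, Ff)), c(2L, 1L, 3L, 4L)),
               nrow = pool)                      # (pool, B*Tout*F)
  am <- max.col(t(Xr), ties.method = "first")
  n <- ncol(Xr)
  Y <- array(Xr[cbind(am, seq_len(n))], c(1L, B, Tout, Ff))
  list(Y = Y, cache = list(am = am, pool = pool, dims = d, Tout = Tout))
}

maxpool_time_backward <- function(dY, cache) {
  d <- cache$dims; B <- d[2]; Tt <- d[3]; Ff <- d[4]
  pool <- cache$pool; Tout <- cache$Tout
  n <- length(cache$am)
  dXr <- matrix(0, nrow = pool, ncol = n)
  dXr[cbind(cache$am, seq_len(n))] <- as.vector(dY)
  dX <- array(0, c(B, Tt, Ff))
  dX[, seq_len(Tout * pool), ] <-
    aperm(array(dXr, c(pool, B, Tout, Ff)), c(2L, 1L, 3L, 4L))
  array(dX, d)
}

# ---------------------------------------------------------------- attention

# Shared two-layer bottleneck: A = softmax(W2 tanh(W1 x + b1) + b2) applied
# to each (filter, sample) pooled vector. Pm: (axis_len, F*B).
attn_forward <- function(Pm, W1, b1, W2, b2) {
  Z1 <- tanh(W1 %*% Pm + b1)
  Z2 <- W2 %*% Z1 + b2
  A <- softmax_cols(Z2)
  list(A = A, cache = list(Pm = Pm, Z1 = Z1, A = A, W1 = W1, W2 = W2))
}

attn_backward <- function(dA, cache) {
  A <- cache$A
  s <- colSums(dA * A)
  dZ2 <- A * sweep(dA, 2L, s, "-")
  dW2 <- tcrossprod(dZ2, cache$Z1)
  db2 <- rowSums(dZ2)
  dZ1 <- crossprod(cache$W2, dZ2) * (1 - cache$Z1^2)
  dW1 <- tcrossprod(dZ1, cache$Pm)
  db1 <- rowSums(dZ1)
  dPm <- crossprod(cache$W1, dZ1)
  list(dPm = dPm, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# sum over the time axis per (c, b, f): X (C, B, T, F) -> (C*B, F) matrix
.sum_over_time <- function(X) {
  d <- dim(X)
  matrix(cpp_sum_time(X, d[1] * d[2], d[3], d[4]), nrow = d[1] * d[2])
}
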
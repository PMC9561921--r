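#' STA-CNN model configuration
#'
#' Hyperparameters of the spatial-temporal attention CNN. The defaults
#' reproduce the published architecture for 62-channel, 100-sample epochs:
#' module 1 band-filters time with 16 kernels of length 50 (time padding
#' 24 left / 25 right, output length still 100); module 2 applies temporal
#' attention then 32 kernels of length 51 (no padding, output length 50);
#' module 3 applies spatial (channel) attention then a full-height (62, 1)
#' spatial filter to 4 maps and max-pools time by 5; module 4 flattens the
#' 40 features into a 2-class dense layer with softmax probabilities.
#'
#' @param n_channels,n_time Epoch geometry.
#' @param n_filters Integer triple: maps of the three convolutions.
#' @param kernel_times Integer pair: time-kernel lengths of modules 1 and 2.
#' @param pad1 Left/right zero padding on time in module 1.
#' @param pool Max-pool size (= stride) on time in module 3.
#' @param dropout_p Dropout probability in modules 2 and 3.
#' @param attn_hidden_t,attn_hidden_s Bottleneck sizes of the attention
#'   blocks; default is half the attended axis, rounded up (50 and 31).
#' @param n_classes Output classes (2: target/nontarget).
#' @param bn_eps Batch-norm stability constant. Note that a nonzero value
#'   breaks the exact scale invariance of batch normalisation; set it to 0
#'   to make uniform attention weights exactly equivalent to removing the
#'   attention layers.
#' @param variant One of "STA-CNN", "TA-CNN" (no spatial attention),
#'   "SA-CNN" (no temporal attention), "CNN" (neither).
#' @param seed Seed for weight initialisation.
#' @return Object of class `stacnn_config`.
#' @export
model_config <- function(n_channels = 62L, n_time = 100L,
                         n_filters = c(16L, 32L, 4L),
                         kernel_times = c(50L, 51L), pad1 = c(24L, 25L),
                         pool = 5L, dropout_p = 0.5,
                         attn_hidden_t = NULL, attn_hidden_s = NULL,
                         n_classes = 2L, bn_eps = 1e-5,
                         variant = c("STA-CNN", "TA-CNN", "SA-CNN", "CNN"),
                         seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(n_channels > 0, n_time > 0, all(n_filters > 0), pool > 0,
            dropout_p >= 0, dropout_p < 1, bn_eps >= 0)
  t1 <- n_time + sum(pad1) - kernel_times[1] + 1L
  if (t1 < kernel_times[2]) {
    stop("module-2 kernel longer than the module-1 output", call. = FALSE)
  }
  t2 <- t1 - kernel_times[2] + 1L
  if (t2 < pool) stop("pool size exceeds the module-3 time axis",
                      call. = FALSE)
  if (is.null(attn_hidden_t)) attn_hidden_t <- ceiling(t1 / 2)
  if (is.null(attn_hidden_s)) attn_hidden_s <- ceiling(n_channels / 2)
  structure(
    list(n_channels = as.integer(n_channels), n_time = as.integer(n_time),
         n_filters = as.integer(n_filters),
         kernel_times = as.integer(kernel_times), pad1 = as.integer(pad1),
         pool = as.integer(pool), dropout_p = dropout_p,
         attn_hidden_t = as.integer(attn_hidden_t),
         attn_hidden_s = as.integer(attn_hidden_s),
         n_classes = as.integer(n_classes), bn_eps = bn_eps,
         variant = variant, seed = as.integer(seed),
         t_after_conv1 = as.integer(t1), t_after_conv2 = as.integer(t2),
         t_after_pool = as.integer(t2 %/% pool),
         n_flat = as.integer(n_filters[3] * (t2 %/% pool))),
    class = "stacnn_config"
  )
}

.unif_init <- function(dims, fan_in) {
  bound <- sqrt(1 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dims)
}

#' Instantiate an STA-CNN (or ablation variant)
#'
#' Builds seeded fan-in uniform initial weights for the four modules. The
#' attention blocks' output layers start at zero, so the initial attention
#' is exactly uniform over its axis; the blocks are present only in
#' variants that use them, so parameter counts are strictly ordered
#' CNN < TA-CNN, SA-CNN < STA-CNN.
#'
#' @param config A [model_config()].
#' @return Object of class `sta_cnn` with `config`, `params` (named list of
#'   arrays) and `running` (batch-norm running statistics).
#' @export
sta_cnn <- function(config = model_config()) {
  stopifnot(inherits(config, "stacnn_config"))
  cf <- config
  f <- cf$n_filters
  k <- cf$kernel_times
  params <- list()
  with_seed(cf$seed, {
    params$conv1_W <- .unif_init(c(k[1], 1L, f[1]), k[1])
    params$bn1_gamma <- rep(1, f[1]); params$bn1_beta <- rep(0, f[1])
    if (cf$variant %in% c("STA-CNN", "TA-CNN")) {
      params$ta_W1 <- .unif_init(c(cf$attn_hidden_t, cf$t_after_conv1),
                                 cf$t_after_conv1)
      params$ta_b1 <- as.vector(.unif_init(cf$attn_hidden_t,
                                           cf$t_after_conv1))
      # zero-init output layer: initial attention is exactly uniform, so
      # every deviation is driven by the data (and the full model starts
      # out equivalent to the attention-free CNN variant)
      params$ta_W2 <- array(0, c(cf$t_after_conv1, cf$attn_hidden_t))
      params$ta_b2 <- rep(0, cf$t_after_conv1)
    }
    params$conv2_W <- .unif_init(c(k[2], f[1], f[2]), k[2] * f[1])
    params$bn2_gamma <- rep(1, f[2]); params$bn2_beta <- rep(0, f[2])
    if (cf$variant %in% c("STA-CNN", "SA-CNN")) {
      params$sa_W1 <- .unif_init(c(cf$attn_hidden_s, cf$n_channels),
                                 cf$n_channels)
      params$sa_b1 <- as.vector(.unif_init(cf$attn_hidden_s, cf$n_channels))
      params$sa_W2 <- array(0, c(cf$n_channels, cf$attn_hidden_s))
      params$sa_b2 <- rep(0, cf$n_channels)
    }
    params$conv3_W <- .unif_init(c(cf$n_channels, f[2], f[3]),
                                 cf$n_channels * f[2])
    params$bn3_gamma <- rep(1, f[3]); params$bn3_beta <- rep(0, f[3])
    params$dense_W <- .unif_init(c(cf$n_classes, cf$n_flat), cf$n_flat)
    params$dense_b <- as.vector(.unif_init(cf$n_classes, cf$n_flat))
  })
  running <- list(
    bn1 = list(mean = rep(0, f[1]), var = rep(1, f[1])),
    bn2 = list(mean = rep(0, f[2]), var = rep(1, f[2])),
    bn3 = list(mean = rep(0, f[3]), var = rep(1, f[3]))
  )
  structure(list(config = cf, params = params, running = running),
            class = "sta_cnn")
}

#' Build an ablation variant of the STA-CNN
#'
#' @param name "CNN" (no attention), "TA-CNN" (temporal only), "SA-CNN"
#'   (spatial only) or "STA-CNN" (both).
#' @param config Base [model_config()]; its `variant` field is replaced.
#' @return An `sta_cnn` model.
#' @export
make_variant <- function(name, config = model_config()) {
  name <- match.arg(name, c("CNN", "TA-CNN", "SA-CNN", "STA-CNN"))
  config$variant <- name
  sta_cnn(config)
}

#' Number of trainable parameters
#' @param model An `sta_cnn`.
#' @return Integer count over all weight arrays.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "sta_cnn"))
  sum(vapply(model$params, length, 0L))
}

#' @export
print.sta_cnn <- function(x, ...) {
  cf <- x$config
  cat(sprintf("%s: input (%d, %d), %s filters, %d parameters\n",
              cf$variant, cf$n_channels, cf$n_time,
              paste(cf$n_filters, collapse = "/"), n_params(x)))
  invisible(x)
}



#' Forward pass of the STA-CNN
#'
#' @param model An [sta_cnn()].
#' @param X Input batch: `n_channels x n_time x B` array (a single
#'   `n_channels x n_time` matrix is promoted to B = 1), in microvolts.
#' @param mode "train" (batch-norm batch statistics, dropout active, running
#'   statistics updated) or "eval" (running statistics, no dropout,
#'   deterministic).
#' @param keep_cache Keep layer caches for [backward()].
#' @param uniform_attention Force both attention blocks to emit constant
#'   uniform weights (1/axis length); relates the full model to the
#'   attention-free CNN variant.
#' @return List with `logits` (`n_classes x B`), `probs` (softmax of
#'   logits), `attention` (`A_t`: `t_after_conv1 x F1 x B` or NULL, `A_s`:
#'   `n_channels x F2 x B` or NULL), `shapes` (named per-layer
#'   (filters, channels, time) output sizes, matching the published
#'   architecture table), `model` (with updated running statistics when
#'   `mode = "train"`), and `cache` when requested.
#' @export
forward <- function(model, X, mode = c("eval", "train"), keep_cache = FALSE,
                    uniform_attention = FALSE) {
  stopifnot(inherits(model, "sta_cnn"))
  mode <- match.arg(mode)
  cf <- model$config
  p <- model$params
  if (length(dim(X)) == 2L) X <- array(X, c(dim(X), 1L))
  d <- dim(X)
  if (d[1] != cf$n_channels || d[2] != cf$n_time) {
    stop(sprintf("input must be (%d, %d[, B]); got (%d, %d)",
                 cf$n_channels, cf$n_time, d[1], d[2]), call. = FALSE)
  }
  B <- d[3]
  C <- cf$n_channels
  shapes <- list(input = c(cf$n_channels, cf$n_time))

  # module 1: reshape -> temporal conv -> BN -> ELU
  X0 <- array(aperm(X, c(1L, 3L, 2L)), c(C, B, cf$n_time, 1L))
  shapes$reshape <- c(1L, cf$n_channels, cf$n_time)
  c1 <- conv_time_forward(X0, p$conv1_W, cf$pad1)
  shapes$conv1 <- dim(c1$Y)[c(4L, 1L, 3L)]
  b1 <- bn_forward(c1$Y, p$bn1_gamma, p$bn1_beta, model$running$bn1, mode,
                   eps = cf$bn_eps)
  model$running$bn1 <- b1$running
  e1 <- elu_forward(b1$Y)
  A1 <- e1$Y                                   # (C, B, T1, F1)

  # module 2: temporal attention -> temporal conv -> BN -> ELU -> dropout
  use_ta <- cf$variant %in% c("STA-CNN", "TA-CNN")
  A_t <- NULL
  ta <- NULL
  Tt <- dim(A1)[3]
  if (use_ta) {
    if (uniform_attention) {
      A_t <- array(1 / Tt, c(Tt, cf$n_filters[1], B))
      T2in <- A1 / Tt
    } else {
      pooled <- array(cpp_colsum_groups(A1, C) / C,
                      c(B, Tt, cf$n_filters[1]))
      Pm <- matrix(aperm(pooled, c(2L, 3L, 1L)), nrow = Tt)  # (T1, F1*B)
      ta <- attn_forward(Pm, p$ta_W1, p$ta_b1, p$ta_W2, p$ta_b2)
      A_t <- array(ta$A, c(Tt, cf$n_filters[1], B))
      T2in <- cpp_scale_cols(A1, aperm(A_t, c(3L, 1L, 2L)), C)
      dim(T2in) <- dim(A1)
    }
  } else {
    T2in <- A1
  }
  shapes$temporal_attention <- c(cf$n_filters[1], cf$n_channels, Tt)
  c2 <- conv_time_forward(T2in, p$conv2_W, c(0L, 0L))
  shapes$conv2 <- dim(c2$Y)[c(4L, 1L, 3L)]
  b2 <- bn_forward(c2$Y, p$bn2_gamma, p$bn2_beta, model$running$bn2, mode,
                   eps = cf$bn_eps)
  model$running$bn2 <- b2$running
  e2 <- elu_forward(b2$Y)
  dr2 <- dropout_forward(e2$Y, cf$dropout_p, mode)
  A2 <- dr2$Y                                  # (C, B, T2, F2)

  # module 3: spatial attention -> spatial conv -> BN -> ELU -> maxpool
  #           -> dropout
  use_sa <- cf$variant %in% c("STA-CNN", "SA-CNN")
  A_s <- NULL
  sa <- NULL
  T2 <- dim(A2)[3]
  if (use_sa) {
    if (uniform_attention) {
      A_s <- array(1 / C, c(C, cf$n_filters[2], B))
      S3in <- A2 / C
    } else {
      pooled_s <- array(.sum_over_time(A2) / T2, c(C, B, cf$n_filters[2]))
      Pm <- matrix(aperm(pooled_s, c(1L, 3L, 2L)), nrow = C)  # (C, F2*B)
      sa <- attn_forward(Pm, p$sa_W1, p$sa_b1, p$sa_W2, p$sa_b2)
      A_s <- array(sa$A, c(C, cf$n_filters[2], B))
      A3 <- aperm(A_s, c(1L, 3L, 2L))          # (C, B, F2)
      S3in <- cpp_scale_rf(A2, A3, C * B, T2, cf$n_filters[2])
      dim(S3in) <- dim(A2)
    }
  } else {
    S3in <- A2
  }
  shapes$spatial_attention <- c(cf$n_filters[2], cf$n_channels, T2)
  c3 <- conv_spatial_forward(S3in, p$conv3_W)
  shapes$conv3 <- dim(c3$Y)[c(4L, 1L, 3L)]
  b3 <- bn_forward(c3$Y, p$bn3_gamma, p$bn3_beta, model$running$bn3, mode,
                   eps = cf$bn_eps)
  model$running$bn3 <- b3$running
  e3 <- elu_forward(b3$Y)
  mp <- maxpool_time_forward(e3$Y, cf$pool)
  shapes$maxpool <- dim(mp$Y)[c(4L, 1L, 3L)]
  dr3 <- dropout_forward(mp$Y, cf$dropout_p, mode)

  # module 4: flatten -> dense -> softmax
  Tp <- cf$t_after_pool
  F3 <- cf$n_filters[3]
  Xf <- matrix(aperm(array(dr3$Y, c(B, Tp, F3)), c(2L, 3L, 1L)),
               nrow = cf$n_flat)               # (flat, B)
  shapes$flatten <- cf$n_flat
  logits <- p$dense_W %*% Xf + p$dense_b
  shapes$dense <- cf$n_classes
  probs <- softmax_cols(logits)

  cache <- NULL
  if (keep_cache) {
    cache <- list(B = B, c1 = c1$cache, b1 = b1$cache, e1 = e1$cache,
                  A1 = A1, ta = ta, A_t = A_t, use_ta = use_ta,
                  c2 = c2$cache, b2 = b2$cache, e2 = e2$cache,
                  dr2 = dr2$cache, A2 = A2, sa = sa, A_s = A_s,
                  use_sa = use_sa, c3 = c3$cache, b3 = b3$cache,
                  e3 = e3$cache, mp = mp$cache, dr3 = dr3$cache, Xf = Xf,
                  uniform = uniform_attention)
  }
  list(logits = logits, probs = probs,
       attention = list(A_t = A_t, A_s = A_s), shapes = shapes,
       model = model, cache = cache)
}

#' Backward pass: gradients of the mean cross-entropy loss
#'
#' @param model The `sta_cnn` used in the forward pass.
#' @param fwd Result of [forward()] with `keep_cache = TRUE` in "train"
#'   mode.
#' @param y Integer class labels (1 = nontarget, 2 = target) of length B,
#'   or a one-hot `n_classes x B` matrix.
#' @return List with `loss` (mean categorical cross-entropy) and `grads`
#'   (named like `model$params`).
#' @export
backward <- function(model, fwd, y) {
  stopifnot(inherits(model, "sta_cnn"), !is.null(fwd$cache))
  cf <- model$config
  p <- model$params
  ca <- fwd$cache
  B <- ca$B
  C <- cf$n_channels
  Y <- if (is.matrix(y)) y else {
    m <- matrix(0, cf$n_classes, B)
    m[cbind(as.integer(y), seq_len(B))] <- 1
    m
  }
  probs <- fwd$probs
  loss <- -mean(colSums(Y * log(pmax(probs, 1e-12))))
  g <- list()

  dlogits <- (probs - Y) / B
  g$dense_W <- tcrossprod(dlogits, ca$Xf)
  g$dense_b <- rowSums(dlogits)
  dXf <- crossprod(p$dense_W, dlogits)         # (flat, B)
  Tp <- cf$t_after_pool
  F3 <- cf$n_filters[3]
  dmp <- array(aperm(array(dXf, c(Tp, F3, B)), c(3L, 1L, 2L)),
               c(1L, B, Tp, F3))
  dmp <- dropout_backward(dmp, ca$dr3)
  de3 <- maxpool_time_backward(dmp, ca$mp)
  db3 <- elu_backward(de3, ca$e3)
  bb3 <- bn_backward(db3, ca$b3)
  g$bn3_gamma <- bb3$dgamma; g$bn3_beta <- bb3$dbeta
  cc3 <- conv_spatial_backward(bb3$dX, ca$c3)
  g$conv3_W <- cc3$dW
  dS3in <- cc3$dX                              # (C, B, T2, F2)

  T2 <- dim(dS3in)[3]
  if (ca$use_sa) {
    if (ca$uniform) {
      dA2 <- dS3in / C
    } else {
      F2 <- cf$n_filters[2]
      A3 <- aperm(ca$A_s, c(1L, 3L, 2L))       # (C, B, F2)
      dA3 <- array(cpp_mul_sum_time(dS3in, ca$A2, C * B, T2, F2),
                   c(C, B, F2))
      ab <- attn_backward(matrix(aperm(dA3, c(1L, 3L, 2L)), nrow = C),
                          ca$sa$cache)
      g$sa_W1 <- ab$dW1; g$sa_b1 <- ab$db1
      g$sa_W2 <- ab$dW2; g$sa_b2 <- ab$db2
      dPool <- aperm(array(ab$dPm, c(C, F2, B)), c(1L, 3L, 2L)) / T2
      dA2 <- cpp_axpb_rf(dS3in, A3, dPool, C * B, T2, F2)
      dim(dA2) <- dim(dS3in)
    }
  } else {
    dA2 <- dS3in
  }
  dA2 <- dropout_backward(dA2, ca$dr2)
  de2 <- elu_backward(dA2, ca$e2)
  bb2 <- bn_backward(de2, ca$b2)
  g$bn2_gamma <- bb2$dgamma; g$bn2_beta <- bb2$dbeta
  cc2 <- conv_time_backward(bb2$dX, ca$c2)
  g$conv2_W <- cc2$dW
  dT2in <- cc2$dX                              # (C, B, T1, F1)

  Tt <- dim(dT2in)[3]
  if (ca$use_ta) {
    if (ca$uniform) {
      dA1 <- dT2in / Tt
    } else {
      F1 <- cf$n_filters[1]
      dAt_btf <- array(cpp_mul_colsum_groups(dT2in, ca$A1, C),
                       c(B, Tt, F1))
      ab <- attn_backward(matrix(aperm(dAt_btf, c(2L, 3L, 1L)), nrow = Tt),
                          ca$ta$cache)
      g$ta_W1 <- ab$dW1; g$ta_b1 <- ab$db1
      g$ta_W2 <- ab$dW2; g$ta_b2 <- ab$db2
      dPool <- aperm(array(ab$dPm, c(Tt, F1, B)), c(3L, 1L, 2L)) / C
      dA1 <- cpp_axpb_cols(dT2in, aperm(ca$A_t, c(3L, 1L, 2L)), dPool, C)
      dim(dA1) <- dim(dT2in)
    }
  } else {
    dA1 <- dT2in
  }
  de1 <- elu_backward(dA1, ca$e1)
  bb1 <- bn_backward(de1, ca$b1)
  g$bn1_gamma <- bb1$dgamma; g$bn1_beta <- bb1$dbeta
  cc1 <- conv_time_backward(bb1$dX, ca$c1)
  g$conv1_W <- cc1$dW

  list(loss = loss, grads = g)
}

#' Cross-entropy loss of a forward result
#' @param fwd A [forward()] result.
#' @param y Labels as in [backward()].
#' @return Mean categorical cross-entropy.
#' @export
ce_loss <- function(fwd, y) {
  B <- ncol(fwd$probs)
  Y <- if (is.matrix(y)) y else {
    m <- matrix(0, nrow(fwd$probs), B)
    m[cbind(as.integer(y), seq_len(B))] <- 1
    m
  }
  -mean(colSums(Y * log(pmax(fwd$probs, 1e-12))))
}
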
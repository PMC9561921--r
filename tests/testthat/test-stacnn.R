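test_that("forward pass reproduces every published layer shape", {
  m <- sta_cnn(model_config(seed = 2))
  set.seed(1)
  X <- array(rnorm(62 * 100 * 3), c(62, 100, 3))
  fw <- forward(m, X, "eval")
  sh <- fw$shapes
  expect_identical(unname(sh$input), c(62L, 100L))
  expect_identical(unname(sh$reshape), c(1L, 62L, 100L))
  expect_identical(unname(sh$conv1), c(16L, 62L, 100L))
  expect_identical(unname(sh$temporal_attention), c(16L, 62L, 100L))
  expect_identical(unname(sh$conv2), c(32L, 62L, 50L))
  expect_identical(unname(sh$spatial_attention), c(32L, 62L, 50L))
  expect_identical(unname(sh$conv3), c(4L, 1L, 50L))
  expect_identical(unname(sh$maxpool), c(4L, 1L, 10L))
  expect_identical(unname(sh$flatten), 40L)
  expect_identical(unname(sh$dense), 2L)
  expect_identical(dim(fw$logits), c(2L, 3L))
  expect_equal(colSums(fw$probs), rep(1, 3))
  # a single matrix input is promoted to a batch of one
  fw1 <- forward(m, X[, , 1], "eval")
  expect_identical(dim(fw1$logits), c(2L, 1L))
  expect_error(forward(m, X[1:10, , ]), "input must be")
})

test_that("attention weights are probability vectors over their axis", {
  m <- sta_cnn(model_config(seed = 4))
  set.seed(2)
  X <- array(rnorm(62 * 100 * 5, sd = 10), c(62, 100, 5))
  fw <- forward(m, X, "eval")
  At <- fw$attention$A_t   # (100, 16, B)
  As <- fw$attention$A_s   # (62, 32, B)
  expect_identical(dim(At), c(100L, 16L, 5L))
  expect_identical(dim(As), c(62L, 32L, 5L))
  expect_true(all(At >= 0) && all(As >= 0))
  expect_equal(colSums(matrix(At, nrow = 100)), rep(1, 16 * 5),
               tolerance = 1e-6)
  expect_equal(colSums(matrix(As, nrow = 62)), rep(1, 32 * 5),
               tolerance = 1e-6)
  # softmax is computed with max subtraction: huge inputs do not overflow
  fw_big <- forward(m, X * 1e3, "eval")
  expect_true(all(is.finite(fw_big$probs)))
  expect_true(all(is.finite(fw_big$attention$A_t)))
})

test_that("constant input with zeroed attention layers gives uniform A_t", {
  m <- sta_cnn(tiny_config())
  for (nm in c("ta_W1", "ta_b1", "ta_W2", "ta_b2")) {
    m$params[[nm]][] <- 0
  }
  X <- array(1, c(6, 20, 2))
  fw <- forward(m, X, "eval")
  Tt <- m$config$t_after_conv1
  expect_equal(as.vector(fw$attention$A_t), rep(1 / Tt, Tt * 3 * 2))
})

test_that("analytic gradients match finite differences everywhere", {
  m <- sta_cnn(tiny_config())
  # move every tensor off its initialisation (the attention output layers
  # start at zero) so no gradient is trivially zero by structure
  set.seed(31)
  for (nm in names(m$params)) {
    m$params[[nm]][] <- m$params[[nm]] +
      rnorm(length(m$params[[nm]]), sd = 0.05)
  }
  set.seed(5)
  X <- array(rnorm(6 * 20 * 4), c(6, 20, 4))
  y <- c(1L, 2L, 2L, 1L)
  fw <- forward(m, X, "train", keep_cache = TRUE)
  bw <- backward(m, fw, y)
  lossfn <- function(mm) ce_loss(forward(mm, X, "train"), y)
  h <- 1e-5
  set.seed(9)
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(4L, length(p)))) {
      mp <- m; mp$params[[nm]][i] <- p[i] + h
      mn <- m; mn$params[[nm]][i] <- p[i] - h
      num <- (lossfn(mp) - lossfn(mn)) / (2 * h)
      expect_equal(bw$grads[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("uniform attention collapses the STA-CNN onto the CNN variant", {
  # batch-norm scale invariance: multiplying a filter map by a constant
  # (uniform attention = 1/N) is removed by the following normalisation, so
  # with shared weights, no dropout and eps = 0 the logits must agree.
  cfg <- model_config(dropout_p = 0, bn_eps = 0, seed = 3)
  sta <- sta_cnn(cfg)
  cnn <- make_variant("CNN", cfg)
  for (nm in names(cnn$params)) cnn$params[[nm]] <- sta$params[[nm]]
  set.seed(1)
  X <- array(rnorm(62 * 100 * 8, sd = 5), c(62, 100, 8))
  f_sta <- forward(sta, X, "train", uniform_attention = TRUE)
  f_cnn <- forward(cnn, X, "train")
  expect_lt(max(abs(f_sta$logits - f_cnn$logits)), 1e-4)
})

test_that("ablation variants expose the expected structure", {
  cfg <- model_config(seed = 6)
  models <- lapply(c("CNN", "TA-CNN", "SA-CNN", "STA-CNN"), make_variant,
                   config = cfg)
  names(models) <- c("CNN", "TA-CNN", "SA-CNN", "STA-CNN")
  set.seed(3)
  X <- array(rnorm(62 * 100 * 2), c(62, 100, 2))
  for (nm in names(models)) {
    fw <- forward(models[[nm]], X, "eval")
    expect_identical(dim(fw$logits), c(2L, 2L))
    expect_identical(is.null(fw$attention$A_t),
                     nm %in% c("CNN", "SA-CNN"))
    expect_identical(is.null(fw$attention$A_s),
                     nm %in% c("CNN", "TA-CNN"))
  }
  np <- vapply(models, n_params, 0)
  expect_lt(np[["CNN"]], np[["TA-CNN"]])
  expect_lt(np[["CNN"]], np[["SA-CNN"]])
  expect_lt(np[["TA-CNN"]], np[["STA-CNN"]])
  expect_lt(np[["SA-CNN"]], np[["STA-CNN"]])
  expect_error(make_variant("LSTM", cfg))
})

test_that("eval mode is deterministic; train mode is seed-controlled", {
  m <- sta_cnn(tiny_config(dropout_p = 0.5))
  set.seed(8)
  X <- array(rnorm(6 * 20 * 3), c(6, 20, 3))
  e1 <- forward(m, X, "eval")
  e2 <- forward(m, X, "eval")
  expect_identical(e1$logits, e2$logits)
  set.seed(123); t1 <- forward(m, X, "train")
  set.seed(123); t2 <- forward(m, X, "train")
  set.seed(124); t3 <- forward(m, X, "train")
  expect_identical(t1$logits, t2$logits)
  expect_false(identical(t1$logits, t3$logits))
})
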
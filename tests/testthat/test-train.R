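test_that("splits follow the character blocks and stage-2 oversampling", {
  # 320 characters, 5 stage-2 epochs each: first 300 chars train+val
  ep <- fake_epochs(320, stage = 2)
  tc <- train_config(n_train_chars = 300, seed = 2)
  sp <- split_and_oversample(ep, tc)
  expect_identical(dim(sp$test$data)[3], 20L * 5L)
  expect_true(all(sp$test$info$char_index > 300))
  n_val <- dim(sp$val$data)[3]
  expect_equal(n_val, 150L, tolerance = 1)  # 10% of 1500
  # validation is stratified: ~10% of each class
  expect_equal(sum(sp$val$labels == "target"), 30L, tolerance = 1)
  # train targets are duplicated 3 extra times (class balance 1200/1200-ish)
  tab <- table(sp$train$labels)
  expect_equal(unname(tab["target"]) / 4, 300 - sum(sp$val$labels == "target"))
  expect_identical(unname(tab["target"]), unname(tab["nontarget"]))
  # no oversampling leaves counts unchanged
  sp0 <- split_and_oversample(ep, train_config(n_train_chars = 300, seed = 2,
                                               oversample_extra_copies = 0))
  tab0 <- table(sp0$train$labels)
  expect_equal(unname(tab0["nontarget"] / tab0["target"]), 4, tolerance = 0.1)
  expect_error(split_and_oversample(fake_epochs(100), tc), "more than")
})

test_that("the full-protocol split yields 300/1200 then 1200/1200 epochs", {
  ep <- fake_epochs(467, stage = 2)
  tc <- train_config(n_train_chars = 300, seed = 1)
  # before oversampling and validation: 300 targets, 1200 nontargets
  in_train <- ep$info$char_index <= 300
  expect_identical(sum(ep$labels[in_train] == "target"), 300L)
  expect_identical(sum(ep$labels[in_train] == "nontarget"), 1200L)
  sp <- split_and_oversample(ep, tc)
  # after stratified validation and 3 extra target copies: balanced classes
  tab <- table(sp$train$labels)
  expect_identical(unname(tab["target"]), unname(tab["nontarget"]))
  expect_identical(dim(sp$test$data)[3], 167L * 5L)
})

test_that("stage-1 decoding equals exhaustive code-likelihood matching", {
  cb <- default_cb
  expect_identical(decode_stage1(c(0.9, 0.1, 0.9), cb),
                   which(cb$codes == "101"))
  expect_identical(decode_stage1(c(0.1, 0.1, 0.1), cb),
                   which(cb$codes == "000"))
  # brute-force oracle over all 8 codes
  oracle <- function(p, cb) {
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    ll <- vapply(cb$codes, function(cd) {
      b <- code_bits(cd)
      sum(b * log(p) + (1 - b) * log(1 - p))
    }, 0)
    which.max(ll)
  }
  set.seed(14)
  for (i in 1:500) {
    p <- runif(3)
    expect_identical(decode_stage1(p, cb), unname(oracle(p, cb)))
  }
  # scores outside [0,1] are clipped rather than producing NaN
  expect_identical(decode_stage1(c(1, 0, 1), cb), which(cb$codes == "101"))
  # hamming rule agrees with likelihood on confident scores
  expect_identical(decode_stage1(c(0.9, 0.1, 0.9), cb, rule = "hamming"),
                   which(cb$codes == "101"))
})

test_that("stage-2 decoding is argmax with lowest-index ties", {
  expect_identical(decode_stage2(c(0.1, 0.9, 0.2, 0.3, 0.1)), 2L)
  expect_identical(decode_stage2(rep(0.5, 5)), 1L)
  set.seed(3)
  for (i in 1:100) {
    s <- runif(5)
    expect_identical(decode_stage2(s), which.max(s))
  }
  expect_error(decode_stage2(c(0.2, 0.4)))
})

test_that("session decoding scores characters by both stages", {
  ses <- small_session()
  ep <- preprocess_pipeline(as_recording(ses))
  ep1 <- subset_epochs(ep, which(ep$info$stage == 1))
  ep2 <- subset_epochs(ep, which(ep$info$stage == 2))
  # oracle scores from ground truth: a perfect classifier
  s1 <- as.numeric(ep1$labels == "target")
  s2 <- as.numeric(ep2$labels == "target")
  res <- decode_session(s1, s2, ep1, ep2, ses$truth, default_cb)
  expect_s3_class(res, "decoding_result")
  expect_identical(nrow(res), nrow(ses$truth))
  expect_true(all(res$correct))
  rep <- evaluate_decoding(res, s1, s2, ep1, ep2)
  expect_equal(rep$total_accuracy, 1)
  expect_equal(rep$epoch_stage2$f1, 1)
  # character correctness requires both stages
  s1_bad <- 1 - s1
  res_bad <- decode_session(s1_bad, s2, ep1, ep2, ses$truth, default_cb)
  expect_true(all(!res_bad$stage1_correct))
  expect_true(all(!res_bad$correct))
  expect_true(all(res_bad$stage2_correct))
})

test_that("epoch metrics use target as the positive class", {
  labels <- factor(c("target", "target", "nontarget", "nontarget"),
                   levels = c("nontarget", "target"))
  m <- epoch_metrics(c(0.9, 0.2, 0.1, 0.8), labels)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
  perfect <- epoch_metrics(c(0.9, 0.8, 0.1, 0.2), labels)
  expect_equal(perfect$f1, 1)
})

test_that("paired t-test matches the closed form and rejects degeneracy", {
  r <- paired_ttest(c(1, 2, 3), c(0, 2, 2))
  expect_equal(r$t, 2)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * stats::pt(-2, df = 2))
  expect_error(paired_ttest(c(1, 2, 3), c(0, 1, 2)), "zero variance")
})

test_that("training checkpoints the lowest validation loss and is seeded", {
  # linearly separable two-class toy problem on the tiny geometry
  set.seed(21)
  n <- 80
  lab <- rep(c("nontarget", "target"), n / 2)
  X <- array(rnorm(6 * 20 * n), c(6, 20, n))
  X[2, 8:12, lab == "target"] <- X[2, 8:12, lab == "target"] + 4
  ep <- structure(
    list(data = X,
         labels = factor(lab, levels = c("nontarget", "target")),
         info = data.frame(sample = seq_len(n), char_index = seq_len(n),
                           position = 1L, stage = 2L,
                           attended = lab == "target"),
         channels = paste0("c", 1:6), fs = 200,
         times = (0:19) * 5, n_skipped = 0L),
    class = "epoch_set")
  tr_idx <- 1:60
  va_idx <- 61:70
  te_idx <- 71:80
  tc <- train_config(max_passes = 40, batch_size = 10, seed = 7, lr = 1e-2)
  m <- sta_cnn(tiny_config(seed = 7, dropout_p = 0.25))
  fit <- train_decoder(m, subset_epochs(ep, tr_idx), subset_epochs(ep, va_idx),
                       tc)
  expect_identical(nrow(fit$history), 40L)
  # returned checkpoint is the minimum validation loss over the history
  expect_equal(min(fit$history$val_loss),
               fit$history$val_loss[fit$best_pass])
  pv <- stacnn:::predict_epochs(fit$model, subset_epochs(ep, te_idx))
  expect_gt(pv$acc, 0.95)
  # scores are softmax target probabilities
  sc <- score_epochs(fit$model, subset_epochs(ep, te_idx))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(sc, pv$probs[2, ])
  expect_equal(pv$probs[1, ] + pv$probs[2, ], rep(1, 10))
  # identical seed and data reproduce the history exactly
  fit2 <- train_decoder(sta_cnn(tiny_config(seed = 7, dropout_p = 0.25)),
                        subset_epochs(ep, tr_idx), subset_epochs(ep, va_idx),
                        tc)
  expect_identical(fit$history, fit2$history)
  expect_error(train_decoder(m, subset_epochs(ep, integer(0)),
                             subset_epochs(ep, va_idx), tc), "empty")
})

test_that("attention reports average to probability vectors", {
  m <- sta_cnn(tiny_config(seed = 2))
  ep <- fake_epochs(6, stage = 1, n_channels = 6, n_time = 20)
  ar <- attention_report(m, ep)
  expect_equal(sum(ar$A_t), 1, tolerance = 1e-8)
  expect_equal(sum(ar$A_s), 1, tolerance = 1e-8)
  expect_length(ar$A_t, m$config$t_after_conv1)
  expect_length(ar$A_s, 6L)
  expect_error(attention_report(m, subset_epochs(ep, integer(0))), "empty")
})

test_that("find_peaks orders strict local maxima by height", {
  x <- c(0, 1, 0, 3, 0, 2, 0)
  pk <- find_peaks(x, smooth = 0)
  expect_identical(pk, c(4L, 6L, 2L))
})
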
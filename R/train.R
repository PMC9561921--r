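#' Training configuration
#'
#' @param max_passes Full passes over the training set (the published
#'   protocol runs 300 with validation checkpointing).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param val_fraction Fraction of training epochs held out (stratified by
#'   label) as the validation set.
#' @param oversample_extra_copies Extra copies of each target training
#'   epoch (stage 2 uses 3, balancing 300 targets against 1200 nontargets).
#' @param n_train_chars Characters whose epochs form train+validation; the
#'   remainder are the test set.
#' @param seed Seed for the validation split, shuffling and dropout.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @return Object of class `train_config`.
#' @export
train_config <- function(max_passes = 300L, lr = 1e-3, batch_size = 64L,
                         val_fraction = 0.10, oversample_extra_copies = 3L,
                         n_train_chars = 300L, seed = 1L, beta1 = 0.9,
                         beta2 = 0.999, adam_eps = 1e-8) {
  stopifnot(val_fraction > 0, val_fraction < 1, oversample_extra_copies >= 0,
            max_passes >= 1, batch_size >= 1)
  structure(list(max_passes = as.integer(max_passes), lr = lr,
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction,
                 oversample_extra_copies = as.integer(oversample_extra_copies),
                 n_train_chars = as.integer(n_train_chars),
                 seed = as.integer(seed), beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps),
            class = "train_config")
}

#' Split epochs by character block and oversample training targets
#'
#' Spelling integrity: epochs of the first `n_train_chars` characters form
#' train+validation, the remaining characters form the test set. The
#' validation set is a seeded stratified `val_fraction` of the training
#' epochs; target epochs of the remaining training set are then duplicated
#' `oversample_extra_copies` times to balance the classes.
#'
#' @param epochs An `epoch_set` whose `info` has `char_index`.
#' @param cfg A [train_config()].
#' @param oversample Apply target oversampling to the training split.
#' @return List of `epoch_set`s: `train`, `val`, `test`.
#' @export
split_and_oversample <- function(epochs, cfg = train_config(),
                                 oversample = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"),
            "char_index" %in% names(epochs$info))
  chars <- sort(unique(epochs$info$char_index))
  if (length(chars) <= cfg$n_train_chars) {
    stop(sprintf("need more than %d characters, have %d",
                 cfg$n_train_chars, length(chars)), call. = FALSE)
  }
  train_chars <- chars[seq_len(cfg$n_train_chars)]
  in_train <- epochs$info$char_index %in% train_chars
  test <- subset_epochs(epochs, which(!in_train))
  tr_idx <- which(in_train)
  lab <- epochs$labels[tr_idx]
  val_idx <- with_seed(cfg$seed, {
    unlist(lapply(levels(lab), function(lv) {
      pool <- tr_idx[lab == lv]
      sample(pool, round(cfg$val_fraction * length(pool)))
    }))
  })
  val <- subset_epochs(epochs, sort(val_idx))
  core_idx <- setdiff(tr_idx, val_idx)
  if (oversample && cfg$oversample_extra_copies > 0) {
    tgt <- core_idx[epochs$labels[core_idx] == "target"]
    core_idx <- c(core_idx, rep(tgt, cfg$oversample_extra_copies))
  }
  train <- subset_epochs(epochs, core_idx)
  list(train = train, val = val, test = test)
}

.adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * gr
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * gr^2
    params[[nm]] <- params[[nm]] - cfg$lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + cfg$adam_eps)
  }
  list(params = params, state = state)
}

.labels_int <- function(epochs) {
  # class 1 = nontarget, class 2 = target
  as.integer(epochs$labels)
}

#' Train a decoder with Adam, cross-entropy and validation checkpointing
#'
#' Runs up to `max_passes` full passes; after each pass the validation loss
#' is evaluated (eval mode) and the weights with the lowest validation loss
#' seen so far are retained -- checkpointing, not early termination.
#'
#' @param model An [sta_cnn()].
#' @param train,val `epoch_set`s with target/nontarget labels.
#' @param cfg A [train_config()].
#' @param verbose Print per-pass losses.
#' @return List with `model` (best checkpoint), `history` (data frame:
#'   pass, train_loss, val_loss, val_acc), `best_pass`.
#' @export
train_decoder <- function(model, train, val, cfg = train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(model, "sta_cnn"), inherits(train, "epoch_set"),
            inherits(val, "epoch_set"))
  n <- dim(train$data)[3]
  if (n == 0 || dim(val$data)[3] == 0) {
    stop("empty training or validation split", call. = FALSE)
  }
  y <- .labels_int(train)
  if (anyNA(y)) stop("training epochs must be labelled", call. = FALSE)
  state <- list(t = 0L,
                m = lapply(model$params, function(p) p * 0),
                v = lapply(model$params, function(p) p * 0))
  best <- list(loss = Inf, params = model$params, running = model$running,
               pass = 0L)
  history <- vector("list", cfg$max_passes)
  with_seed(cfg$seed, {
    for (pass in seq_len(cfg$max_passes)) {
      ord <- sample.int(n)
      tot_loss <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        ib <- ord[start:min(start + cfg$batch_size - 1L, n)]
        fw <- forward(model, train$data[, , ib, drop = FALSE], "train",
                      keep_cache = TRUE)
        model <- fw$model
        bw <- backward(model, fw, y[ib])
        upd <- .adam_step(model$params, bw$grads, state, cfg)
        model$params <- upd$params
        state <- upd$state
        tot_loss <- tot_loss + bw$loss * length(ib)
      }
      vs <- predict_epochs(model, val)
      if (vs$loss < best$loss) {
        best <- list(loss = vs$loss, params = model$params,
                     running = model$running, pass = pass)
      }
      history[[pass]] <- data.frame(pass = pass, train_loss = tot_loss / n,
                                    val_loss = vs$loss, val_acc = vs$acc)
      if (verbose) {
        message(sprintf("pass %3d  train %.4f  val %.4f  val acc %.3f",
                        pass, tot_loss / n, vs$loss, vs$acc))
      }
    }
  })
  model$params <- best$params
  model$running <- best$running
  gc(FALSE)
  cpp_malloc_trim()
  list(model = model, history = do.call(rbind, history),
       best_pass = best$pass)
}

# eval-mode probabilities, loss and accuracy over an epoch set, in batches
predict_epochs <- function(model, epochs, batch_size = 256L) {
  n <- dim(epochs$data)[3]
  probs <- matrix(0, model$config$n_classes, n)
  for (start in seq(1L, n, by = batch_size)) {
    ib <- start:min(start + batch_size - 1L, n)
    fw <- forward(model, epochs$data[, , ib, drop = FALSE], "eval")
    probs[, ib] <- fw$probs
  }
  y <- .labels_int(epochs)
  loss <- acc <- NA_real_
  if (!anyNA(y)) {
    loss <- -mean(log(pmax(probs[cbind(y, seq_len(n))], 1e-12)))
    acc <- mean(max.col(t(probs)) == y)
  }
  list(probs = probs, p_target = probs[2L, ], loss = loss, acc = acc)
}

#' Target probability of each epoch
#'
#' @param model A trained `sta_cnn`.
#' @param epochs An `epoch_set`.
#' @return Numeric vector: eval-mode softmax probability of the target
#'   class per epoch.
#' @export
score_epochs <- function(model, epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (dim(epochs$data)[3] == 0) stop("empty epoch set", call. = FALSE)
  predict_epochs(model, epochs)$p_target
}

#' Stage-1 group decision from three sub-trial scores
#'
#' Chooses the group whose 3-bit code best explains the three classifier
#' outputs under a Bernoulli log-likelihood: argmax over groups g of
#' sum_k bit_k(g) log p_k + (1 - bit_k(g)) log(1 - p_k). Ties resolve to
#' the lowest group index. Scores are clipped to `[eps, 1 - eps]` before
#' the logs. With `rule = "hamming"` the scores are thresholded at 0.5 and
#' the nearest code in Hamming distance wins instead.
#'
#' @param scores Numeric length-3 vector of target probabilities for the
#'   three stage-1 sub-trials, in sub-trial order.
#' @param codebook A [build_codebook()].
#' @param rule "likelihood" (default) or "hamming".
#' @param eps Clipping bound.
#' @return Chosen group index (1-8).
#' @export
decode_stage1 <- function(scores, codebook, rule = c("likelihood", "hamming"),
                          eps = 1e-9) {
  stopifnot(length(scores) == 3L, inherits(codebook, "speller_codebook"))
  rule <- match.arg(rule)
  p <- pmin(pmax(scores, eps), 1 - eps)
  bits <- vapply(codebook$codes, code_bits, integer(3))  # 3 x 8
  stat <- if (rule == "likelihood") {
    colSums(bits * log(p) + (1 - bits) * log(1 - p))
  } else {
    -colSums(bits != (p >= 0.5))
  }
  unname(which.max(stat))
}

#' Stage-2 character decision from five slot scores
#'
#' @param scores Numeric length-5 vector of target probabilities, in slot
#'   order.
#' @return Chosen slot index (1-5); ties resolve to the lowest index.
#' @export
decode_stage2 <- function(scores) {
  stopifnot(length(scores) == 5L)
  which.max(scores)
}

#' Decode every character of a session from per-epoch scores
#'
#' Offline copy-spelling scoring: both stages are decoded for every
#' character (stage 2 against the true group's five presented characters),
#' and a character is correct iff both stage decisions are correct.
#'
#' @param scores1,scores2 Target probabilities for the stage-1 / stage-2
#'   epochs (aligned with `epochs1$info` / `epochs2$info`).
#' @param epochs1,epochs2 The corresponding `epoch_set`s (need
#'   `info$char_index`, `info$position`, and `info$shown` for stage 2).
#' @param truth Per-character truth data frame (`char_index`, `char`,
#'   `group`, `within`) as produced by [simulate_session()].
#' @param codebook A [build_codebook()].
#' @return Object of class `decoding_result`: data frame with one row per
#'   character: predicted/true group, predicted/true character, and
#'   stage1_correct / stage2_correct / correct flags.
#' @export
decode_session <- function(scores1, scores2, epochs1, epochs2, truth,
                           codebook) {
  stopifnot(length(scores1) == dim(epochs1$data)[3],
            length(scores2) == dim(epochs2$data)[3])
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    ci <- truth$char_index[i]
    i1 <- which(epochs1$info$char_index == ci)
    i2 <- which(epochs2$info$char_index == ci)
    if (length(i1) != 3L || length(i2) != 5L) {
      return(NULL)  # character lost epochs at a recording edge
    }
    s1 <- scores1[i1][order(epochs1$info$position[i1])]
    s2 <- scores2[i2][order(epochs2$info$position[i2])]
    pred_group <- decode_stage1(s1, codebook)
    slot <- decode_stage2(s2)
    pred_char <- epochs2$info$shown[i2][order(epochs2$info$position[i2])][slot]
    data.frame(
      char_index = ci, true_char = truth$char[i],
      true_group = truth$group[i], pred_group = pred_group,
      pred_char = pred_char,
      stage1_correct = pred_group == truth$group[i],
      stage2_correct = pred_char == truth$char[i]
    )
  })
  out <- do.call(rbind, rows)
  out$correct <- out$stage1_correct & out$stage2_correct
  class(out) <- c("decoding_result", class(out))
  out
}

#' Binary classification metrics with target as the positive class
#'
#' @param p_target Target probabilities.
#' @param labels Factor with levels nontarget/target.
#' @param threshold Decision threshold.
#' @return List with `accuracy`, `f1`, `precision`, `recall`.
#' @export
epoch_metrics <- function(p_target, labels, threshold = 0.5) {
  pred <- p_target >= threshold
  truth <- labels == "target"
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(accuracy = mean(pred == truth), f1 = f1, precision = precision,
       recall = recall)
}

#' Paired two-sided t-test between two per-subject metric vectors
#'
#' Thin wrapper over [stats::t.test()] that turns the degenerate
#' zero-variance case into an explicit error instead of NaN.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `t`, `df`, `p_value`, `mean_diff`.
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("paired differences have zero variance; t statistic undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = mean(d))
}

#' Summarise decoding performance
#'
#' @param result A [decode_session()] result.
#' @param scores1,scores2,epochs1,epochs2 Optional per-epoch scores and
#'   sets; when given, epoch-level accuracy/F1 per stage are included.
#' @return Object of class `eval_report`: list with `stage1_accuracy`,
#'   `stage2_accuracy`, `total_accuracy`, `n_characters` and (optionally)
#'   `epoch_stage1` / `epoch_stage2` metric lists.
#' @export
evaluate_decoding <- function(result, scores1 = NULL, scores2 = NULL,
                              epochs1 = NULL, epochs2 = NULL) {
  stopifnot(inherits(result, "decoding_result"))
  rep <- list(
    stage1_accuracy = mean(result$stage1_correct),
    stage2_accuracy = mean(result$stage2_correct),
    total_accuracy = mean(result$correct),
    n_characters = nrow(result)
  )
  if (!is.null(scores1) && !is.null(epochs1)) {
    rep$epoch_stage1 <- epoch_metrics(scores1, epochs1$labels)
  }
  if (!is.null(scores2) && !is.null(epochs2)) {
    rep$epoch_stage2 <- epoch_metrics(scores2, epochs2$labels)
  }
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report (%d characters): stage1 %.1f%%, stage2 %.1f%%, total %.1f%%\n",
    x$n_characters, 100 * x$stage1_accuracy, 100 * x$stage2_accuracy,
    100 * x$total_accuracy))
  invisible(x)
}

#' Average attention weights over a set of epochs
#'
#' Runs the model in eval mode and averages the temporal and spatial
#' attention probability vectors over epochs and filters, as used to relate
#' the learned weights to ERP component latencies and active channels.
#'
#' @param model A trained `sta_cnn` (a variant with at least one attention
#'   block).
#' @param epochs An `epoch_set`.
#' @param batch_size Forward batch size.
#' @return List with `A_t` (length `t_after_conv1`, mean temporal weights,
#'   sums to 1), `times_ms` (epoch latencies of the temporal axis), `A_s`
#'   (length `n_channels`, mean spatial weights), `channels`.
#' @export
attention_report <- function(model, epochs, batch_size = 256L) {
  stopifnot(inherits(model, "sta_cnn"), inherits(epochs, "epoch_set"))
  n <- dim(epochs$data)[3]
  if (n == 0) stop("empty epoch set", call. = FALSE)
  at_sum <- NULL
  as_sum <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    ib <- start:min(start + batch_size - 1L, n)
    fw <- forward(model, epochs$data[, , ib, drop = FALSE], "eval")
    if (!is.null(fw$attention$A_t)) {
      s <- rowSums(matrix(fw$attention$A_t, nrow = dim(fw$attention$A_t)[1]))
      at_sum <- if (is.null(at_sum)) s else at_sum + s
    }
    if (!is.null(fw$attention$A_s)) {
      s <- rowSums(matrix(fw$attention$A_s, nrow = dim(fw$attention$A_s)[1]))
      as_sum <- if (is.null(as_sum)) s else as_sum + s
    }
  }
  nf <- model$config$n_filters
  out <- list(times_ms = epochs$times, channels = epochs$channels)
  if (!is.null(at_sum)) out$A_t <- at_sum / (n * nf[1])
  if (!is.null(as_sum)) out$A_s <- as_sum / (n * nf[2])
  out
}

#' Local maxima of a weight curve
#'
#' Utility for reading attention curves: indices that are strict local
#' maxima after light smoothing, ordered by height.
#'
#' @param x Numeric vector.
#' @param smooth Half-width of a moving-average smoother (0 = none).
#' @return Integer indices of local maxima, highest first.
#' @export
find_peaks <- function(x, smooth = 2L) {
  if (smooth > 0) {
    k <- rep(1 / (2 * smooth + 1), 2 * smooth + 1)
    x <- as.numeric(stats::filter(x, k, sides = 2))
    x[is.na(x)] <- -Inf
  }
  n <- length(x)
  is_pk <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n],
             FALSE)
  pk <- which(is_pk)
  pk[order(x[pk], decreasing = TRUE)]
}
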
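# Shared fixtures. Everything is generated in code; sizes are kept small so
# the default run stays fast.

default_cb <- build_codebook()

# tiny model geometry used for gradient checks and fast training tests
tiny_config <- function(seed = 11L, dropout_p = 0, ...) {
  model_config(n_channels = 6L, n_time = 20L, n_filters = c(3L, 4L, 2L),
               kernel_times = c(7L, 11L), pad1 = c(3L, 3L), pool = 5L,
               dropout_p = dropout_p, attn_hidden_t = 5L, attn_hidden_s = 3L,
               seed = seed, ...)
}

# small simulated session shared across tests (built once per run)
small_session <- local({
  ses <- NULL
  function() {
    if (is.null(ses)) {
      set.seed(401)
      text <- paste(sample(default_cb$charset, 12, replace = TRUE),
                    collapse = "")
      ses <<- simulate_session(text, default_cb,
                               sim_config(noise_amplitude = 2,
                                          snr_scale = 3, seed = 401))
    }
    ses
  }
})

# epoch_set with synthetic metadata (no signal provenance) for split tests
fake_epochs <- function(n_chars, stage = 2L, n_channels = 4L, n_time = 10L,
                        seed = 1L) {
  per <- if (stage == 2L) 5L else 3L
  n <- n_chars * per
  info <- data.frame(
    sample = seq_len(n) * 100L,
    stage = stage,
    char_index = rep(seq_len(n_chars), each = per),
    position = rep(seq_len(per), n_chars)
  )
  attended <- if (stage == 2L) {
    as.vector(vapply(seq_len(n_chars), function(i) {
      a <- rep(FALSE, 5L)
      a[1L + (i %% 5L)] <- TRUE
      a
    }, logical(5L)))
  } else rep(c(TRUE, FALSE, TRUE), n_chars)
  info$attended <- attended
  set.seed(seed)
  structure(
    list(data = array(stats::rnorm(n_channels * n_time * n),
                      c(n_channels, n_time, n)),
         labels = factor(ifelse(attended, "target", "nontarget"),
                         levels = c("nontarget", "target")),
         info = info, channels = paste0("ch", seq_len(n_channels)),
         fs = 200, times = (seq_len(n_time) - 1) * 5, n_skipped = 0L),
    class = "epoch_set"
  )
}
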
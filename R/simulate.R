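#' Simulation configuration
#'
#' @param fs Sampling rate in Hz (the recording hardware rate).
#' @param noise_amplitude RMS of the 1/f^alpha background noise per channel,
#'   in microvolts.
#' @param spectral_exponent alpha of the 1/f^alpha noise power spectrum.
#' @param snr_scale Multiplier applied to all evoked-component amplitudes.
#' @param latency_jitter_sd Trial-to-trial latency variability: each evoked
#'   response is shifted by a zero-mean Gaussian delay (ms, truncated at
#'   2.5 sd). 0 disables; ERP latencies vary across trials in real
#'   recordings, so the ablation experiments enable it.
#' @param amplitude_jitter_sd Trial-to-trial relative amplitude variability
#'   (Gaussian around 1, truncated below at 0.2). 0 disables.
#' @param seed Master seed; all session randomness (noise, stage-2 orders,
#'   jitter) derives from it.
#' @param lead_in Seconds of plain background before the first stimulus.
#' @param gap Seconds of background between stages and between characters.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(fs = 1000, noise_amplitude = 10,
                       spectral_exponent = 1, snr_scale = 1,
                       latency_jitter_sd = 0, amplitude_jitter_sd = 0,
                       seed = 1L, lead_in = 0.6, gap = 0.5) {
  stopifnot(fs > 0, noise_amplitude >= 0, gap >= 0.2, lead_in >= 0.2,
            latency_jitter_sd >= 0, amplitude_jitter_sd >= 0)
  structure(list(fs = fs, noise_amplitude = noise_amplitude,
                 spectral_exponent = spectral_exponent,
                 snr_scale = snr_scale,
                 latency_jitter_sd = latency_jitter_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 seed = as.integer(seed),
                 lead_in = lead_in, gap = gap),
            class = "sim_config")
}

# shift a channels x samples waveform along time by k samples (zero-fill)
.shift_waveform <- function(w, k) {
  if (k == 0) return(w)
  out <- matrix(0, nrow(w), ncol(w))
  n <- ncol(w)
  if (k > 0) {
    out[, (k + 1):n] <- w[, 1:(n - k)]
  } else {
    out[, 1:(n + k)] <- w[, (1 - k):n]
  }
  out
}

#' Simulate 1/f^alpha background noise
#'
#' White Gaussian noise is shaped in the frequency domain so its power
#' spectral density is proportional to 1/f^alpha, then scaled to the
#' requested RMS. Channels are independent. Deterministic given the seed.
#'
#' @param cfg A [sim_config()].
#' @param n_channels,n_samples Output dimensions.
#' @param seed Seed for this draw (defaults to `cfg$seed`).
#' @return `n_channels x n_samples` matrix in microvolts (zero mean).
#' @export
simulate_noise <- function(cfg, n_channels, n_samples, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), n_samples > 1)
  if (cfg$noise_amplitude == 0) {
    return(matrix(0, n_channels, n_samples))
  }
  # pad to a highly composite FFT length, then truncate
  nfft <- stats::nextn(n_samples, c(2L, 3L, 5L))
  alpha <- cfg$spectral_exponent
  # |H(f)|^2 ~ 1/f^alpha -> scale amplitudes by f^(-alpha/2); DC removed
  freqs <- seq_len(nfft %/% 2) * (cfg$fs / nfft)
  gain_half <- freqs^(-alpha / 2)
  gain <- c(0, gain_half,
            rev(gain_half[seq_len(nfft - 1L - length(gain_half))]))
  out <- matrix(0, n_channels, n_samples)
  with_seed(seed, {
    for (ch in seq_len(n_channels)) {
      w <- stats::rnorm(nfft)
      x <- Re(stats::fft(stats::fft(w) * gain, inverse = TRUE)) / nfft
      x <- x[seq_len(n_samples)]
      x <- x - mean(x)
      out[ch, ] <- x * (cfg$noise_amplitude / stats::sd(x))
    }
  })
  out
}

#' Simulate a complete two-stage spelling session
#'
#' Concatenates per-character stimulus schedules at the recording rate,
#' inserts the target ERP template at every marker where the attended
#' location is stimulated (stage 1: the attended group's code bit is 1;
#' stage 2: the presented character is the target) and the nontarget
#' template elsewhere, adds 1/f background noise, and records markers and
#' ground truth. The signal has 64 rows: the 62 scalp channels plus the
#' mastoids M1/M2 (noise only), so the result feeds the full preprocessing
#' chain including re-referencing.
#'
#' @param text Character string (or vector of single symbols) to spell; all
#'   symbols must be in the codebook charset.
#' @param codebook A [build_codebook()].
#' @param cfg A [sim_config()].
#' @param templates Optional list with `stage1` and `stage2`, each a
#'   target/nontarget pair as returned by [default_templates()].
#' @return Object of class `eeg_session`: list with `signal` (64 x N matrix,
#'   microvolts), `fs`, `labels`, `events` (data frame: `sample` 1-based,
#'   `time`, `stage`, `char_index`, `position` (sub-trial 1-3 or slot 1-5),
#'   `attended`, `flashed` (stage-1 bit pattern over groups, "" in stage 2),
#'   `shown` (stage-2 presented character, NA in stage 1)), `truth` (data
#'   frame per character), `montage`, `config`, `text`, `templates`.
#' @export
simulate_session <- function(text, codebook, cfg = sim_config(),
                             templates = NULL) {
  stopifnot(inherits(codebook, "speller_codebook"),
            inherits(cfg, "sim_config"))
  chars <- if (length(text) == 1L && nchar(text) > 1L) {
    strsplit(text, "")[[1]]
  } else as.character(text)
  n_char <- length(chars)
  if (n_char < 1L) stop("`text` is empty", call. = FALSE)
  bad <- setdiff(unique(chars), codebook$charset)
  if (length(bad)) {
    stop(sprintf("characters not in charset: %s",
                 paste(bad, collapse = " ")), call. = FALSE)
  }

  montage62 <- default_montage()
  if (is.null(templates)) {
    templates <- list(stage1 = default_templates(1, montage62),
                      stage2 = default_templates(2, montage62))
  }
  fs <- cfg$fs
  epoch_dur <- 0.5
  tgt1 <- render_template(templates$stage1$target, fs, epoch_dur) *
    cfg$snr_scale
  non1 <- render_template(templates$stage1$nontarget, fs, epoch_dur) *
    cfg$snr_scale
  tgt2 <- render_template(templates$stage2$target, fs, epoch_dur) *
    cfg$snr_scale
  non2 <- render_template(templates$stage2$nontarget, fs, epoch_dur) *
    cfg$snr_scale
  epoch_len <- ncol(tgt1)

  char_span <- 3 * 0.5 + cfg$gap + 5 * 0.5 + cfg$gap
  n_samples <- as.integer(round(fs * (cfg$lead_in + n_char * char_span +
                                        0.6)))
  seeds <- derive_seeds(cfg$seed, n_char + 2L)
  # per-event latency shifts (samples) and amplitude scales
  n_ev <- 8L * n_char
  jit <- with_seed(seeds[n_char + 2L], {
    shift_ms <- if (cfg$latency_jitter_sd > 0) {
      pmin(pmax(stats::rnorm(n_ev, 0, cfg$latency_jitter_sd),
                -2.5 * cfg$latency_jitter_sd), 2.5 * cfg$latency_jitter_sd)
    } else rep(0, n_ev)
    amp <- if (cfg$amplitude_jitter_sd > 0) {
      pmax(stats::rnorm(n_ev, 1, cfg$amplitude_jitter_sd), 0.2)
    } else rep(1, n_ev)
    list(shift = as.integer(round(shift_ms * fs / 1000)), amp = amp)
  })
  ev_counter <- 0L

  labels <- default_montage(include_mastoids = TRUE)$labels
  signal <- simulate_noise(cfg, length(labels), n_samples,
                           seed = seeds[n_char + 1L])
  data_rows <- match(montage62$labels, labels)

  events <- vector("list", n_char)
  truth <- vector("list", n_char)
  for (i in seq_len(n_char)) {
    sched <- build_schedule(chars[i], codebook, seed = seeds[i])
    t0 <- cfg$lead_in + (i - 1L) * char_span
    bits <- code_bits(sched$code)
    all_bits <- vapply(codebook$codes, code_bits, integer(3))  # 3 x 8
    ev1 <- data.frame(
      sample = as.integer(round((t0 + (0:2) * 0.5) * fs)) + 1L,
      time = t0 + (0:2) * 0.5,
      stage = 1L, char_index = i, position = 1:3,
      attended = bits == 1L,
      flashed = apply(all_bits, 1L, paste, collapse = ""),
      shown = NA_character_
    )
    t2 <- t0 + 1.5 + cfg$gap
    ev2 <- data.frame(
      sample = as.integer(round((t2 + (0:4) * 0.5) * fs)) + 1L,
      time = t2 + (0:4) * 0.5,
      stage = 2L, char_index = i, position = 1:5,
      attended = sched$stage2$is_target,
      flashed = "",
      shown = sched$stage2$char
    )
    ev <- rbind(ev1, ev2)
    for (j in seq_len(nrow(ev))) {
      ev_counter <- ev_counter + 1L
      tpl <- if (ev$stage[j] == 1L) {
        if (ev$attended[j]) tgt1 else non1
      } else {
        if (ev$attended[j]) tgt2 else non2
      }
      if (any(tpl != 0)) {
        if (jit$shift[ev_counter] != 0L) {
          tpl <- .shift_waveform(tpl, jit$shift[ev_counter])
        }
        tpl <- tpl * jit$amp[ev_counter]
        idx <- ev$sample[j]:(ev$sample[j] + epoch_len - 1L)
        signal[data_rows, idx] <- signal[data_rows, idx] + tpl
      }
    }
    events[[i]] <- ev
    truth[[i]] <- data.frame(char_index = i, char = chars[i],
                             group = sched$group, within = sched$within,
                             code = sched$code)
  }
  events <- do.call(rbind, events)
  stopifnot(all(diff(events$sample) > 0))
  structure(
    list(signal = signal, fs = fs, labels = labels, events = events,
         truth = do.call(rbind, truth), montage = montage62, config = cfg,
         text = paste(chars, collapse = ""), templates = templates),
    class = "eeg_session"
  )
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf(
    "eeg_session: %d channels x %d samples at %g Hz, %d characters, %d markers\n",
    nrow(x$signal), ncol(x$signal), x$fs, nrow(x$truth), nrow(x$events)))
  invisible(x)
}
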
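#' Construct a continuous recording object
#'
#' @param signal channels x samples numeric matrix in microvolts.
#' @param fs Sampling rate in Hz.
#' @param labels Channel names (unique, one per row).
#' @param events Data frame with at least a 1-based `sample` column; other
#'   columns (stage, labels, provenance) are carried through.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, labels, events) {
  signal <- as.matrix(signal)
  labels <- as.character(labels)
  stopifnot(nrow(signal) == length(labels), !anyDuplicated(labels), fs > 0)
  if (nrow(events) > 0) {
    stopifnot(all(events$sample >= 1L), all(events$sample <= ncol(signal)))
  }
  structure(list(signal = signal, fs = fs, labels = labels, events = events),
            class = "eeg_recording")
}

#' Coerce a simulated session to a recording
#' @param session An `eeg_session`.
#' @return An `eeg_recording` with the same signal, labels and events.
#' @export
as_recording <- function(session) {
  stopifnot(inherits(session, "eeg_session"))
  eeg_recording(session$signal, session$fs, session$labels, session$events)
}

#' Re-reference to the mean of two reference channels
#'
#' Subtracts the average of the two reference channels (bilateral mastoids
#' by default) from every other channel and drops the reference channels,
#' leaving the 62 data channels.
#'
#' @param rec An [eeg_recording()].
#' @param refs Two reference channel names.
#' @return Re-referenced `eeg_recording` without the reference channels.
#' @export
rereference <- function(rec, refs = c("M1", "M2")) {
  stopifnot(inherits(rec, "eeg_recording"), length(refs) == 2L)
  miss <- setdiff(refs, rec$labels)
  if (length(miss)) {
    stop(sprintf("reference channel(s) not found: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  ref_idx <- match(refs, rec$labels)
  ref_mean <- colMeans(rec$signal[ref_idx, , drop = FALSE])
  keep <- setdiff(seq_along(rec$labels), ref_idx)
  sig <- rec$signal[keep, , drop = FALSE]
  # subtract row-wise in place; a sweep() would allocate a second full copy,
  # which matters on hour-long 64-channel recordings
  for (ch in seq_len(nrow(sig))) {
    sig[ch, ] <- sig[ch, ] - ref_mean
  }
  eeg_recording(sig, rec$fs, rec$labels[keep], rec$events)
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), so the passband gain is ~1 with no phase shift --
#' ERP latencies are preserved.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz (defaults 1 and 30).
#' @param order Butterworth order.
#' @return Filtered `eeg_recording`.
#' @export
bandpass <- function(rec, low = 1, high = 30, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"), low > 0, high > low)
  if (rec$fs <= 2 * high) {
    stop(sprintf("sampling rate %g Hz too low for a %g Hz band edge",
                 rec$fs, high), call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  sig <- rec$signal
  for (ch in seq_len(nrow(sig))) {
    sig[ch, ] <- signal::filtfilt(bf, sig[ch, ])
  }
  eeg_recording(sig, rec$fs, rec$labels, rec$events)
}

#' Decimate a recording to a lower sampling rate
#'
#' Keeps every (fs/target_fs)-th sample; the caller is responsible for
#' anti-alias filtering beforehand (the 30 Hz low edge of [bandpass()]
#' covers the default 200 Hz target). Event indices are remapped by
#' round(index * target_fs / fs).
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Target rate in Hz; `fs` must be an integer multiple.
#' @return Decimated `eeg_recording`.
#' @export
downsample <- function(rec, target_fs = 200) {
  stopifnot(inherits(rec, "eeg_recording"))
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    stop(sprintf("fs %g is not an integer multiple of target %g Hz",
                 rec$fs, target_fs), call. = FALSE)
  }
  factor <- as.integer(round(factor))
  sig <- rec$signal[, seq(1L, ncol(rec$signal), by = factor), drop = FALSE]
  events <- rec$events
  if (nrow(events) > 0) {
    # 0-based remap then back to 1-based, clamped to the decimated length
    events$sample <- pmin(
      as.integer(round((events$sample - 1L) / factor)) + 1L, ncol(sig))
  }
  eeg_recording(sig, target_fs, rec$labels, events)
}

#' Extract baseline-corrected single-trial epochs
#'
#' For every event takes the window -0.1 to 0.5 s around onset, subtracts
#' the per-channel mean of the -0.1 to 0 s baseline, and keeps the 0 to
#' 0.5 s segment: at 200 Hz a 62 x 100 matrix per epoch. Events too close
#' to the recording edges are skipped with a warning and counted in the
#' returned summary.
#'
#' @param rec An [eeg_recording()] at the epoch rate (200 Hz by default
#'   usage).
#' @param events Event data frame (defaults to `rec$events`); a logical
#'   `attended` column becomes the target/nontarget label.
#' @param pre,post Window extents in seconds.
#' @return Object of class `epoch_set`: list with `data` (channels x
#'   samples x n array), `labels` (factor target/nontarget or NA), `info`
#'   (the event rows kept), `channels`, `fs`, `times` (ms, 0 to 495),
#'   `n_skipped`.
#' @export
extract_epochs <- function(rec, events = rec$events, pre = 0.1, post = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_pre <- as.integer(round(pre * rec$fs))
  n_post <- as.integer(round(post * rec$fs))
  n <- ncol(rec$signal)
  ok <- events$sample - n_pre >= 1L & events$sample + n_post - 1L <= n
  if (any(!ok)) {
    warning(sprintf("%d event(s) too close to the recording edge; skipped",
                    sum(!ok)))
  }
  kept <- events[ok, , drop = FALSE]
  data <- array(0, dim = c(nrow(rec$signal), n_post, nrow(kept)))
  for (j in seq_len(nrow(kept))) {
    s <- kept$sample[j]
    base <- rowMeans(rec$signal[, (s - n_pre):(s - 1L), drop = FALSE])
    data[, , j] <- rec$signal[, s:(s + n_post - 1L), drop = FALSE] - base
  }
  labels <- if ("attended" %in% names(kept)) {
    factor(ifelse(kept$attended, "target", "nontarget"),
           levels = c("nontarget", "target"))
  } else factor(rep(NA_character_, nrow(kept)),
                levels = c("nontarget", "target"))
  structure(
    list(data = data, labels = labels, info = kept, channels = rec$labels,
         fs = rec$fs, times = (seq_len(n_post) - 1L) / rec$fs * 1000,
         n_skipped = sum(!ok)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d epochs of %d channels x %d samples at %g Hz\n",
              dim(x$data)[3], dim(x$data)[1], dim(x$data)[2], x$fs))
  if (!all(is.na(x$labels))) print(table(x$labels))
  invisible(x)
}

#' Subset an epoch set
#' @param x An `epoch_set`.
#' @param i Integer or logical index over epochs.
#' @return The subsetted `epoch_set`.
#' @export
subset_epochs <- function(x, i) {
  stopifnot(inherits(x, "epoch_set"))
  structure(
    list(data = x$data[, , i, drop = FALSE], labels = x$labels[i],
         info = x$info[i, , drop = FALSE], channels = x$channels,
         fs = x$fs, times = x$times, n_skipped = x$n_skipped),
    class = "epoch_set"
  )
}

#' Concatenate epoch sets with identical geometry
#' @param ... `epoch_set` objects.
#' @return A single combined `epoch_set`.
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L)
  data <- array(unlist(lapply(sets, `[[`, "data")),
                dim = c(dim(sets[[1L]]$data)[1:2],
                        sum(vapply(sets, function(s) dim(s$data)[3], 0))))
  structure(
    list(data = data,
         labels = factor(unlist(lapply(sets, function(s)
           as.character(s$labels))), levels = c("nontarget", "target")),
         info = do.call(rbind, lapply(sets, `[[`, "info")),
         channels = sets[[1L]]$channels, fs = sets[[1L]]$fs,
         times = sets[[1L]]$times,
         n_skipped = sum(vapply(sets, `[[`, 0, "n_skipped"))),
    class = "epoch_set"
  )
}

#' Full preprocessing chain: raw 1000 Hz recording to 62 x 100 epochs
#'
#' Composition, in order: mastoid re-referencing, 1-30 Hz zero-phase
#' band-pass (which also anti-aliases the subsequent decimation), 200 Hz
#' resampling, epoch extraction with -0.1 to 0 s baseline correction.
#'
#' @param rec An [eeg_recording()] (64 channels incl. mastoids, 1000 Hz).
#' @param refs Reference channel pair.
#' @param low,high Band-pass edges in Hz.
#' @param target_fs Epoch sampling rate in Hz.
#' @return An `epoch_set` of 62 x 100 matrices.
#' @export
preprocess_pipeline <- function(rec, refs = c("M1", "M2"), low = 1,
                                high = 30, target_fs = 200) {
  rec <- rereference(rec, refs)
  gc(FALSE)  # hour-long 64-channel recordings: free the pre-stage copy now
  cpp_malloc_trim()
  rec <- bandpass(rec, low, high)
  gc(FALSE)
  cpp_malloc_trim()
  rec <- downsample(rec, target_fs)
  extract_epochs(rec)
}

#' Grand-average waveform of a set of epochs
#'
#' @param epochs An `epoch_set`.
#' @param label Optional label filter ("target"/"nontarget").
#' @param stage Optional stage filter (1 or 2, needs `info$stage`).
#' @return channels x samples matrix: the arithmetic mean across epochs.
#' @export
grand_average <- function(epochs, label = NULL, stage = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- rep(TRUE, dim(epochs$data)[3])
  if (!is.null(label)) keep <- keep & epochs$labels == label
  if (!is.null(stage)) keep <- keep & epochs$info$stage == stage
  if (!any(keep)) stop("no epochs match the filter", call. = FALSE)
  m <- apply(epochs$data[, , keep, drop = FALSE], c(1L, 2L), mean)
  dimnames(m) <- list(epochs$channels, NULL)
  m
}
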
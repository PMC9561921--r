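# Portable container: a flat little-endian float64 binary array next to a
# JSON sidecar holding the schema version, dimensions, units, sampling
# rate, channel labels, event table and an md5 checksum of the binary
# payload. Sample indices are written 0-based ("index_base": 0) and
# converted back on read.

.container_version <- "1.0"

.write_payload <- function(x, bin_path) {
  con <- file(bin_path, "wb")
  on.exit(close(con))
  writeBin(as.vector(x), con, size = 8L, endian = "little")
}

.read_payload <- function(bin_path, n) {
  con <- file(bin_path, "rb")
  on.exit(close(con))
  readBin(con, "double", n = n, size = 8L, endian = "little")
}

.events_out <- function(events) {
  ev <- events
  if (nrow(ev) > 0) ev$sample <- ev$sample - 1L
  ev
}

.events_in <- function(events) {
  ev <- as.data.frame(events)
  if (nrow(ev) > 0) ev$sample <- as.integer(ev$sample) + 1L
  ev
}

.check_sidecar <- function(meta, kind, bin_path) {
  if (!identical(meta$container_version, .container_version)) {
    stop(sprintf("container version mismatch: file %s, reader %s",
                 meta$container_version, .container_version), call. = FALSE)
  }
  if (!identical(meta$kind, kind)) {
    stop(sprintf("expected a %s container, found %s", kind, meta$kind),
         call. = FALSE)
  }
  md5 <- unname(tools::md5sum(bin_path))
  if (!identical(md5, meta$checksum_md5)) {
    stop("binary payload checksum mismatch; file corrupt or stale sidecar",
         call. = FALSE)
  }
}

#' Write a continuous recording to the portable container
#'
#' @param rec An [eeg_recording()] (or an `eeg_session`, coerced).
#' @param path Base path; `<path>.bin` and `<path>.json` are written.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (inherits(rec, "eeg_session")) rec <- as_recording(rec)
  stopifnot(inherits(rec, "eeg_recording"))
  bin <- paste0(path, ".bin")
  .write_payload(rec$signal, bin)
  meta <- list(
    container_version = .container_version, kind = "recording",
    units = "uV", order = "channel-major", index_base = 0L,
    n_channels = nrow(rec$signal), n_samples = ncol(rec$signal),
    fs = rec$fs, labels = rec$labels, events = .events_out(rec$events),
    checksum_md5 = unname(tools::md5sum(bin))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a continuous recording from the portable container
#'
#' @param path Base path used in [write_recording()].
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path) {
  bin <- paste0(path, ".bin")
  if (!file.exists(bin) || !file.exists(paste0(path, ".json"))) {
    stop(sprintf("no container at '%s' (.bin/.json missing)", path),
         call. = FALSE)
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  .check_sidecar(meta, "recording", bin)
  sig <- matrix(.read_payload(bin, meta$n_channels * meta$n_samples),
                nrow = meta$n_channels)
  eeg_recording(sig, as.numeric(meta$fs), meta$labels,
                .events_in(meta$events))
}

#' Write an epoch set to the portable container
#'
#' @param epochs An `epoch_set`.
#' @param path Base path; `<path>.bin` and `<path>.json` are written.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  bin <- paste0(path, ".bin")
  .write_payload(epochs$data, bin)
  meta <- list(
    container_version = .container_version, kind = "epochs",
    units = "uV", index_base = 0L, dim = dim(epochs$data),
    fs = epochs$fs, channels = epochs$channels, times_ms = epochs$times,
    labels = as.character(epochs$labels), info = .events_out(epochs$info),
    n_skipped = epochs$n_skipped, checksum_md5 = unname(tools::md5sum(bin))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an epoch set from the portable container
#'
#' @param path Base path used in [write_epochs()].
#' @return An `epoch_set`.
#' @export
read_epochs <- function(path) {
  bin <- paste0(path, ".bin")
  if (!file.exists(bin) || !file.exists(paste0(path, ".json"))) {
    stop(sprintf("no container at '%s' (.bin/.json missing)", path),
         call. = FALSE)
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  .check_sidecar(meta, "epochs", bin)
  d <- as.integer(meta$dim)
  structure(
    list(data = array(.read_payload(bin, prod(d)), d),
         labels = factor(meta$labels, levels = c("nontarget", "target")),
         info = .events_in(meta$info), channels = meta$channels,
         fs = as.numeric(meta$fs), times = meta$times_ms,
         n_skipped = as.integer(meta$n_skipped)),
    class = "epoch_set"
  )
}

#' Serialize a model to a portable checkpoint
#'
#' Weights go into a flat float64 binary; the JSON sidecar embeds the model
#' configuration, the parameter layout and the running batch-norm
#' statistics.
#'
#' @param model An `sta_cnn`.
#' @param path Base path; `<path>.bin` and `<path>.json` are written.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "sta_cnn"))
  bin <- paste0(path, ".bin")
  .write_payload(unlist(model$params, use.names = FALSE), bin)
  layout <- lapply(model$params, function(p) {
    if (is.null(dim(p))) length(p) else dim(p)
  })
  meta <- list(
    container_version = .container_version, kind = "model",
    config = unclass(model$config), layout = layout,
    running = model$running, checksum_md5 = unname(tools::md5sum(bin))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a model checkpoint
#'
#' @param path Base path used in [write_model()].
#' @return An `sta_cnn`.
#' @export
read_model <- function(path) {
  bin <- paste0(path, ".bin")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  .check_sidecar(meta, "model", bin)
  cf <- meta$config
  config <- model_config(
    n_channels = cf$n_channels, n_time = cf$n_time,
    n_filters = cf$n_filters, kernel_times = cf$kernel_times,
    pad1 = cf$pad1, pool = cf$pool, dropout_p = cf$dropout_p,
    attn_hidden_t = cf$attn_hidden_t, attn_hidden_s = cf$attn_hidden_s,
    n_classes = cf$n_classes, variant = cf$variant, seed = cf$seed
  )
  sizes <- vapply(meta$layout, prod, 0)
  vals <- .read_payload(bin, sum(sizes))
  params <- list()
  offset <- 0L
  for (nm in names(meta$layout)) {
    dm <- as.integer(meta$layout[[nm]])
    n <- prod(dm)
    v <- vals[offset + seq_len(n)]
    params[[nm]] <- if (length(dm) > 1L) array(v, dm) else v
    offset <- offset + n
  }
  running <- lapply(meta$running, function(r) {
    list(mean = as.numeric(r$mean), var = as.numeric(r$var))
  })
  structure(list(config = config, params = params, running = running),
            class = "sta_cnn")
}

#' Load a run configuration from JSON or YAML
#'
#' Nested configuration with top-level sections `codebook`, `simulation`,
#' `preprocessing`, `model`, `training`, `evaluation`, `seed`, `out_dir`;
#' unknown top-level keys are rejected.
#'
#' @param path A `.json`, `.yaml` or `.yml` file.
#' @return Named list merged over the defaults of [default_run_config()].
#' @export
load_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    stop(sprintf("unsupported config format '.%s'", ext), call. = FALSE)
  }
  defaults <- default_run_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  utils::modifyList(defaults, cfg)
}

#' Default run configuration
#' @return Named list of all recognised configuration sections.
#' @export
default_run_config <- function() {
  list(
    codebook = list(codes = .default_codes),
    simulation = list(fs = 1000, noise_amplitude = 10,
                      spectral_exponent = 1, snr_scale = 1),
    preprocessing = list(low = 1, high = 30, target_fs = 200),
    model = list(variant = "STA-CNN"),
    training = list(max_passes = 300, lr = 1e-3, batch_size = 64),
    evaluation = list(),
    seed = 1L,
    out_dir = "."
  )
}

#' Generate the small deterministic demo fixture
#'
#' A 20-character, low-noise session with its ground truth: small enough for
#' continuous integration, large enough to exercise the full encode ->
#' simulate -> preprocess -> decode chain.
#'
#' @param seed Master seed.
#' @param text Characters to spell (default the first 20 of the charset).
#' @param noise_amplitude Background RMS in microvolts.
#' @return List with `session` (an `eeg_session`), `codebook`, `epochs`
#'   (preprocessed `epoch_set`).
#' @export
make_fixtures <- function(seed = 42L, text = NULL, noise_amplitude = 1) {
  cb <- build_codebook()
  if (is.null(text)) text <- paste(cb$charset[1:20], collapse = "")
  cfg <- sim_config(noise_amplitude = noise_amplitude, seed = seed)
  session <- simulate_session(text, cb, cfg)
  epochs <- preprocess_pipeline(as_recording(session))
  list(session = session, codebook = cb, epochs = epochs)
}
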
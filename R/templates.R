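#' Construct a parametric ERP component
#'
#' A component is a Gaussian bump in time scaled by a scalp topography:
#' amplitude * exp(-(t - latency)^2 / (2 sigma^2)) on each channel, weighted
#' by that channel's topography entry.
#'
#' @param name Component label ("P1", "N2", "P2", "P300", ...).
#' @param latency_ms Peak latency in ms after stimulus onset.
#' @param sigma_ms Gaussian width (sigma) in ms.
#' @param amplitude Signed peak amplitude in microvolts.
#' @param topography Per-channel weight vector in `[0, 1]` with at least one
#'   nonzero entry.
#' @return Object of class `erp_component`.
#' @export
erp_component <- function(name, latency_ms, sigma_ms, amplitude, topography) {
  stopifnot(latency_ms >= 0, sigma_ms > 0)
  topography <- as.numeric(topography)
  if (!any(topography != 0)) {
    stop("topography must have at least one nonzero entry", call. = FALSE)
  }
  if (any(topography < 0) || any(topography > 1)) {
    stop("topography weights must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, latency_ms = latency_ms, sigma_ms = sigma_ms,
                 amplitude = amplitude, topography = topography),
            class = "erp_component")
}

#' Default ERP templates for the two speller stages
#'
#' Stage-1 targets carry the motion-onset VEP components P1 (+, 90 ms),
#' N2 (-, 130 ms) and P2 (+, 195 ms); stage-2 targets carry the shortened
#' audio-assisted latencies P1 (+, 50 ms), N2 (-, 90 ms), P2 (+, 180 ms)
#' plus a P300 (+, 350 ms). Nontarget templates are empty (no evoked
#' response). Topographies fall off from a right-parietal centroid, giving
#' the right-hemisphere temporo-occipital/parietal dominance of these
#' components.
#'
#' @param stage 1 or 2.
#' @param montage 62-channel [default_montage()].
#' @param amplitude Base component amplitude in microvolts (P300 uses the
#'   same magnitude).
#' @param centroid Topography centroid electrode.
#' @return List with `target` and `nontarget`, each of class `erp_template`
#'   (fields `stage`, `condition`, `components`).
#' @export
default_templates <- function(stage, montage = default_montage(),
                              amplitude = 5, centroid = "P4") {
  if (!stage %in% c(1L, 2L)) stop("`stage` must be 1 or 2", call. = FALSE)
  topo <- gaussian_topography(montage, centroid = centroid)
  comps <- if (stage == 1L) {
    list(
      erp_component("P1", 90, 20, amplitude, topo),
      erp_component("N2", 130, 20, -amplitude, topo),
      erp_component("P2", 195, 20, amplitude, topo)
    )
  } else {
    list(
      erp_component("P1", 50, 20, amplitude, topo),
      erp_component("N2", 90, 20, -amplitude, topo),
      erp_component("P2", 180, 20, amplitude, topo),
      erp_component("P300", 350, 50, amplitude, topo)
    )
  }
  target <- structure(list(stage = stage, condition = "target",
                           components = comps), class = "erp_template")
  nontarget <- structure(list(stage = stage, condition = "nontarget",
                              components = list()), class = "erp_template")
  list(target = target, nontarget = nontarget)
}

#' Render an ERP template to a channels x samples waveform
#'
#' Pointwise sum of the template's Gaussian components; deterministic.
#'
#' @param template An `erp_template`.
#' @param fs Sampling rate in Hz.
#' @param duration Window length in seconds; every component must satisfy
#'   latency + 3 sigma <= duration.
#' @param n_channels Number of channels (must match the topographies).
#' @return `n_channels x round(fs * duration)` matrix in microvolts.
#' @export
render_template <- function(template, fs, duration, n_channels = 62L) {
  stopifnot(inherits(template, "erp_template"), fs > 0, duration > 0)
  n <- as.integer(round(fs * duration))
  out <- matrix(0, nrow = n_channels, ncol = n)
  t_ms <- (seq_len(n) - 1L) / fs * 1000
  for (comp in template$components) {
    if (length(comp$topography) != n_channels) {
      stop("component topography length does not match n_channels",
           call. = FALSE)
    }
    if (comp$latency_ms + 3 * comp$sigma_ms > duration * 1000) {
      stop(sprintf("component %s (latency %g ms) exceeds the %g ms window",
                   comp$name, comp$latency_ms, duration * 1000),
           call. = FALSE)
    }
    bump <- comp$amplitude *
      exp(-(t_ms - comp$latency_ms)^2 / (2 * comp$sigma_ms^2))
    out <- out + outer(comp$topography, bump)
  }
  out
}

#' Channels a template's topography marks as active
#'
#' Channels whose maximum topography weight across components is at least
#' `threshold` times the template maximum.
#'
#' @param template An `erp_template` with at least one component.
#' @param threshold Fraction of the maximum weight.
#' @return Integer channel indices.
#' @export
template_active_channels <- function(template, threshold = 0.5) {
  stopifnot(inherits(template, "erp_template"),
            length(template$components) > 0)
  w <- do.call(pmax, lapply(template$components, `[[`, "topography"))
  which(w >= threshold * max(w))
}
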
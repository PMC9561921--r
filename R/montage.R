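# 64-electrode recording cap (10-10 layout as used by 64-channel Neuroscan
# systems): 62 scalp channels plus the bilateral mastoids M1/M2 that serve
# as the offline reference. Positions are schematic 2-D head coordinates
# (x: left -1 .. right +1, y: posterior -1 .. anterior +1), sufficient for
# topography rendering and distance-based template topographies.
.cap_rows <- list(
  list(y = 0.95, ch = c("FP1", "FPZ", "FP2")),
  list(y = 0.80, ch = c("AF3", "AF4")),
  list(y = 0.62, ch = c("F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8")),
  list(y = 0.42, ch = c("FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4",
                        "FC6", "FT8")),
  list(y = 0.20, ch = c("T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8")),
  list(y = -0.02, ch = c("TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4",
                         "CP6", "TP8")),
  list(y = -0.25, ch = c("P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6",
                         "P8")),
  list(y = -0.48, ch = c("PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8")),
  list(y = -0.70, ch = c("CB1", "O1", "OZ", "O2", "CB2")),
  list(y = -0.15, ch = c("M1", "M2"))  # mastoids, far lateral
)

.cap_positions <- local({
  pos <- do.call(rbind, lapply(.cap_rows, function(r) {
    n <- length(r$ch)
    x <- if (n == 1L) 0 else seq(-1, 1, length.out = n)
    # mastoids sit beyond the scalp ring
    if (identical(r$ch, c("M1", "M2"))) x <- c(-1.25, 1.25)
    data.frame(label = r$ch, x = x, y = r$y, stringsAsFactors = FALSE)
  }))
  rownames(pos) <- pos$label
  pos
})

#' Recording montage of the speller sessions
#'
#' 62 scalp channels (10-10 names) with schematic 2-D positions; the
#' bilateral mastoids M1/M2 are carried separately because raw recordings
#' contain them and re-referencing removes them.
#'
#' @param include_mastoids If `TRUE`, return all 64 recorded channels
#'   (M1/M2 last); otherwise the 62 data channels.
#' @return Object of class `montage`: list with `labels` and `positions`
#'   (data frame with `label`, `x`, `y`).
#' @export
default_montage <- function(include_mastoids = FALSE) {
  pos <- .cap_positions
  if (!include_mastoids) pos <- pos[!pos$label %in% c("M1", "M2"), ]
  structure(list(labels = pos$label, positions = pos), class = "montage")
}

#' Gaussian scalp topography around a centroid electrode
#'
#' Weight for channel c is exp(-d(c, centroid)^2 / (2 rho^2)) in the
#' montage's schematic coordinates, normalised to max 1.
#'
#' @param montage A [default_montage()] object (62 channels).
#' @param centroid Electrode label at the topography peak.
#' @param rho Spatial falloff scale in montage units.
#' @return Numeric weight vector in `[0, 1]`, named by channel.
#' @export
gaussian_topography <- function(montage, centroid = "P4", rho = 0.45) {
  stopifnot(inherits(montage, "montage"))
  pos <- montage$positions
  if (!centroid %in% pos$label) {
    stop(sprintf("centroid channel '%s' not in montage", centroid),
         call. = FALSE)
  }
  c0 <- pos[pos$label == centroid, c("x", "y")]
  d2 <- (pos$x - c0$x)^2 + (pos$y - c0$y)^2
  w <- exp(-d2 / (2 * rho^2))
  names(w) <- pos$label
  w / max(w)
}
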
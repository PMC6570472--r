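#' Beamformed RF frame
#'
#' One beamformed radiofrequency scan plane: a matrix of echo samples (rows
#' = axial samples starting at the transducer face, columns = lateral
#' lines) with its acquisition geometry.  Depth maps to sample index through
#' the pulse-echo relation `z = c * t / 2`.
#'
#' @param samples numeric matrix, axial x lateral, arbitrary units.
#' @param fs axial sampling rate in Hz.
#' @param line_pitch lateral line spacing in metres.
#' @param sound_speed speed of sound in m/s.
#' @param centre_frequency probe centre frequency in Hz.
#' @param plane_index integer index of the plane within a patient's sweep.
#' @param ground_truth optional list recording the phantom parameters that
#'   generated a synthetic frame.
#' @return an object of class `rf_frame`.
#' @export
rf_frame <- function(samples, fs, line_pitch, sound_speed = 1540,
                     centre_frequency = 6e6, plane_index = 1L,
                     ground_truth = NULL) {
  samples <- as.matrix(samples)
  assert_that(all(is.finite(samples)), "RF samples must be finite")
  assert_that(fs > 2 * centre_frequency,
              "sampling rate must exceed twice the centre frequency")
  assert_that(line_pitch > 0, "line_pitch must be positive (metres)")
  structure(
    list(samples = samples, fs = fs, line_pitch = line_pitch,
         sound_speed = sound_speed, centre_frequency = centre_frequency,
         plane_index = as.integer(plane_index), ground_truth = ground_truth),
    class = "rf_frame")
}

# Axial / lateral pixel-centre coordinates in mm.
axial_mm <- function(frame) {
  (seq_len(nrow(frame$samples)) - 1) * frame$sound_speed / (2 * frame$fs) * 1e3
}
lateral_mm <- function(frame) {
  (seq_len(ncol(frame$samples)) - 1) * frame$line_pitch * 1e3
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d samples x %d lines (%.1f x %.1f mm), fs %.0f MHz, f0 %.1f MHz\n",
              nrow(x$samples), ncol(x$samples),
              max(axial_mm(x)), max(lateral_mm(x)),
              x$fs / 1e6, x$centre_frequency / 1e6))
  invisible(x)
}

#' B-mode rendering of an RF frame
#'
#' Per-line analytic-signal envelope, log-compressed to the given dynamic
#' range and normalised to `[0, 1]`.  Used for visual QA and ROI overlays
#' only; every quantitative step in the package works on the raw RF.
#'
#' @param frame an [rf_frame()].
#' @param dynamic_range_db display dynamic range in dB.
#' @return numeric matrix in `[0, 1]` with the frame's dimensions.
#' @export
envelope_bmode <- function(frame, dynamic_range_db = 60) {
  stopifnot(inherits(frame, "rf_frame"))
  env <- analytic_envelope(frame$samples)
  m <- max(env)
  if (m == 0) return(env)                       # all-zero frame stays zero
  db <- 20 * log10(pmax(env / m, 10^(-dynamic_range_db / 20)))
  (db + dynamic_range_db) / dynamic_range_db
}

#' @export
plot.rf_frame <- function(x, dynamic_range_db = 60, roi = NULL, ...) {
  b <- envelope_bmode(x, dynamic_range_db)
  image(lateral_mm(x), axial_mm(x), t(b)[, rev(seq_len(nrow(b)))],
        col = gray(seq(0, 1, length.out = 128)),
        xlab = "lateral (mm)", ylab = "depth (mm)", ...)
  invisible(x)
}

#' Write / read an RF frame as a plain-text pair
#'
#' The frame is stored as `<prefix>.tsv` (tab-separated samples, axial rows
#' by lateral columns) plus a JSON sidecar `<prefix>.json` holding the
#' geometry attributes (`fs`, `line_pitch_m`, `c`, `f0`, `plane_index`) and,
#' for synthetic frames, the generating phantom's ground truth.
#'
#' @param frame an [rf_frame()].
#' @param prefix file path without extension.
#' @return `write_rf_frame` returns `prefix` invisibly; `read_rf_frame`
#'   returns the reconstructed [rf_frame()].
#' @export
write_rf_frame <- function(frame, prefix) {
  stopifnot(inherits(frame, "rf_frame"))
  write.table(frame$samples, paste0(prefix, ".tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(fs = frame$fs, line_pitch_m = frame$line_pitch,
               c = frame$sound_speed, f0 = frame$centre_frequency,
               plane_index = frame$plane_index)
  gt <- frame$ground_truth
  if (!is.null(gt)) {
    gt$populations <- lapply(gt$populations, function(p) if (is.null(p)) NULL else unclass(p))
    meta$ground_truth <- gt
  }
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_rf_frame
#' @export
read_rf_frame <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  samples <- as.matrix(read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(samples) <- NULL
  rf_frame(samples, fs = meta$fs, line_pitch = meta$line_pitch_m,
           sound_speed = meta$c, centre_frequency = meta$f0,
           plane_index = meta$plane_index %||% 1L,
           ground_truth = meta$ground_truth)
}
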
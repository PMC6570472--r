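#' Attenuation coefficient estimate (ACE) by spectral difference
#'
#' Round-trip attenuation tilts and depresses the normalised spectrum
#' progressively with depth: at frequency `f` (MHz), power in dB falls as
#' `-2 * alpha * f * z` with depth `z` (cm).  For each band frequency the
#' normalised power (dB) is regressed against window depth, giving a decay
#' slope `s(f)` in dB/cm; regressing `s(f)` against `f` then gives
#' `-2 * ace`, with `ace` in dB/cm/MHz.
#'
#' @param spectra list of [normalized_spectrum()] objects for windows at
#'   different depths within one ROI (same band grid); at least 3 windows
#'   spanning at least `min_span_cm` of depth.
#' @param min_span_cm minimum depth span in cm.
#' @return list with `ace` (dB/cm/MHz) and `n_depth_windows`.
#' @export
estimate_ace <- function(spectra, min_span_cm = 1) {
  assert_that(length(spectra) >= 3, "need >= 3 windows for attenuation estimation")
  depths <- vapply(spectra, function(s) s$window_depth_cm, 0)
  assert_that(all(is.finite(depths)), "spectra must carry window depths")
  assert_that(diff(range(depths)) >= min_span_cm,
              sprintf("depth span %.2f cm is below the required %.2f cm",
                      diff(range(depths)), min_span_cm))
  band <- spectra[[1]]$band
  f <- spectra[[1]]$f_mhz[band]
  P <- vapply(spectra, function(s) s$power_db[s$band], numeric(sum(band)))
  # per-frequency decay with depth (dB/cm), then its slope across frequency
  sx <- depths - mean(depths)
  sf <- as.numeric(P %*% sx) / sum(sx^2)
  fit <- lm(sf ~ f)
  list(ace = -unname(coef(fit)[2]) / 2, n_depth_windows = length(spectra))
}
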
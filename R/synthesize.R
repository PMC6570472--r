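#' Synthesise an RF frame from a phantom
#'
#' Each lateral line is an impulse train at the scatterer depths (depth to
#' sample through `z = c t / 2`), weighted by scatterer amplitude, convolved
#' with the transmit pulse.  Scattering is shaped by a Gaussian form factor:
#' the backscattered *power* from a scatterer of effective diameter `d` is
#' attenuated by `exp(-0.827 k^2 (d/2)^2)` with `k = 2 pi f / c`, so the
#' amplitude filter applied here is the square root of that factor.
#' Frequency-dependent round-trip attenuation multiplies the amplitude by
#' `10^(-2 alpha f z / 20)` (`alpha` in dB/cm/MHz, `f` in MHz, `z` in cm).
#' Additive white electronic noise is set by `snr_db` relative to the RF
#' RMS.
#'
#' Synthesis runs in the frequency domain per line, with scatterers grouped
#' into thin depth bins (default 1 mm) inside which the attenuation filter
#' is treated as constant; each scatterer's amplitude is corrected to its
#' exact attenuation at the centre frequency, so only the spectral *tilt*
#' is quantised by the binning.  There is no diffraction or elevational
#' beam model: scatterers map to their nearest line.  This is deliberate —
#' the downstream estimators operate on windowed per-line spectra, which
#' this level of realism exercises fully.
#'
#' @param phantom a [tissue_phantom()].
#' @param pulse a [make_pulse()] object (or a [pulse_spec()], converted).
#' @param seed integer seed controlling placement and noise.
#' @param line_pitch_mm lateral line spacing in mm.
#' @param snr_db electronic signal-to-noise ratio in dB; `Inf` disables
#'   noise.
#' @param scatterers optional pre-placed scatterer table (as returned by
#'   [place_scatterers()]); placement is skipped when supplied.
#' @param depth_bin_mm depth quantisation of the attenuation filter.
#' @return an [rf_frame()] carrying the phantom ground truth.
#' @export
synthesize_rf <- function(phantom, pulse = make_pulse(), seed = 1L,
                          line_pitch_mm = 0.2, snr_db = 30,
                          scatterers = NULL, depth_bin_mm = 1) {
  if (inherits(pulse, "pulse_spec")) pulse <- make_pulse(pulse)
  stopifnot(inherits(phantom, "tissue_phantom"), inherits(pulse, "qus_pulse"))
  ps <- pulse$spec
  fs <- ps$sampling_rate; c0 <- ps$sound_speed
  ext <- phantom$extent
  nz <- ceiling(2 * ext[1] * 1e-3 / c0 * fs)
  n_lines <- max(1L, floor(ext[2] / line_pitch_mm + 1e-9) + 1L)
  if (is.null(scatterers)) scatterers <- place_scatterers(phantom, seed)

  nfft <- nextn(nz + length(pulse$p))
  fgrid <- (0:(nfft - 1)) / nfft * fs
  fgrid[fgrid > fs / 2] <- fgrid[fgrid > fs / 2] - fs
  # advance by the pulse group delay so echo envelopes centre at z = c t / 2
  Pf <- fft(c(pulse$p, rep(0, nfft - length(pulse$p)))) *
    exp(2i * pi * fgrid * ((length(pulse$p) - 1) / 2) / fs)
  absf <- abs(fgrid)
  k2 <- (2 * pi * absf / c0)^2

  Y <- matrix(0 + 0i, nfft, n_lines)
  if (nrow(scatterers) > 0) {
    samp <- round(2 * scatterers$z_mm * 1e-3 / c0 * fs) + 1L
    line <- round(scatterers$x_mm / line_pitch_mm) + 1L
    ok <- samp >= 1 & samp <= nz & line >= 1 & line <= n_lines
    if (any(!ok)) warning(sum(!ok), " scatterer(s) outside the imaging grid were skipped")
    sc <- scatterers[ok, , drop = FALSE]
    samp <- samp[ok]; line <- line[ok]
    alpha <- unname(phantom$attenuation[sc$region])
    # exact per-scatterer attenuation at f0; binned filter carries the tilt
    att0 <- 10^(-2 * alpha * (ps$centre_frequency / 1e6) * (sc$z_mm / 10) / 20)
    key <- paste(sc$region, floor(sc$z_mm / depth_bin_mm))
    for (kk in unique(key)) {
      sel <- which(key == kk)
      pop <- phantom$populations[[sc$region[sel[1]]]]
      a <- phantom$attenuation[[sc$region[sel[1]]]]
      zb_cm <- (floor(sc$z_mm[sel[1]] / depth_bin_mm) + 0.5) * depth_bin_mm / 10
      att_bin <- 10^(-2 * a * (absf / 1e6) * zb_cm / 20)
      att_bin0 <- 10^(-2 * a * (ps$centre_frequency / 1e6) * zb_cm / 20)
      ffa <- exp(-0.827 * k2 * (pop$effective_diameter * 1e-6 / 2)^2 / 2)
      amp <- sc$amplitude[sel] * att0[sel] / att_bin0
      M <- matrix(0, nfft, n_lines)
      acc <- rowsum(amp, samp[sel] + (line[sel] - 1L) * nfft)
      M[as.integer(rownames(acc))] <- acc
      Y <- Y + mvfft(M) * (Pf * ffa * att_bin)
    }
  }
  rf <- Re(mvfft(Y, inverse = TRUE)) / nfft
  rf <- rf[seq_len(nz), , drop = FALSE]
  if (is.finite(snr_db) && any(rf != 0)) {
    set.seed(derive_seed(seed, "noise"))
    sig <- sqrt(mean(rf^2)) * 10^(-snr_db / 20)
    rf <- rf + matrix(rnorm(length(rf), 0, sig), nrow(rf))
  }
  gt <- attr(scatterers, "ground_truth") %||% list(
    populations = phantom$populations, attenuation = phantom$attenuation,
    extent = phantom$extent, seed = seed)
  gt$snr_db <- snr_db
  rf_frame(rf, fs = fs, line_pitch = line_pitch_mm * 1e-3,
           sound_speed = c0, centre_frequency = ps$centre_frequency,
           ground_truth = gt)
}
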
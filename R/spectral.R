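#' Reference-normalised window power spectrum
#'
#' Per-line, mean-removed, tapered periodograms are averaged over the
#' window's lines, divided by the reference power spectral density, and
#' expressed in dB.  The fitting band is the reference -6 dB band
#' intersected with `[1 MHz, 0.8 * Nyquist]`; the spectrum is retained over
#' the wider -20 dB band so that the scatterer-spacing estimator can see
#' more ripple periods.
#'
#' The default Hann taper gives the usual bias/variance trade-off for the
#' regression parameters.  The spacing estimator instead requires the
#' *untapered* (`"rect"`) periodogram: a Hann taper on a 2 mm window smears
#' spectral structure over about twice the rectangular resolution and
#' suppresses the millimetre-scale ripple entirely.
#'
#' @param frame an [rf_frame()].
#' @param window one row of a [tile_windows()] grid (or any list with
#'   `a0`, `a1`, `l0`, `l1`, `depth_cm`).
#' @param reference_psd function of frequency (Hz) returning the reference
#'   power spectral density, e.g. `make_pulse(...)$reference_psd`.
#' @param taper `"hann"` (regression estimators) or `"rect"` (spacing).
#' @param nfft FFT length (zero-padded).
#' @return an object of class `normalized_spectrum`: `f_mhz`, `power_db`,
#'   `linear_power` over the retained support, logical `band` marking the
#'   -6 dB fitting band, plus `centre_frequency_mhz`, `window_depth_cm`,
#'   `window_len_s`, `sound_speed`.
#' @export
normalized_spectrum <- function(frame, window, reference_psd,
                                taper = c("hann", "rect"), nfft = 2048) {
  stopifnot(inherits(frame, "rf_frame"))
  taper <- match.arg(taper)
  seg <- frame$samples[window$a0:window$a1, window$l0:window$l1, drop = FALSE]
  if (ncol(seg) < 2)
    warning("window holds a single line; spectrum is a single periodogram")
  n <- nrow(seg)
  w <- if (taper == "hann") hann_taper(n) else rep(1, n)
  seg <- sweep(seg, 2, colMeans(seg)) * w
  nfft <- max(nfft, nextn(n))
  S <- rowMeans(Mod(mvfft(rbind(seg, matrix(0, nfft - n, ncol(seg)))))^2)
  f <- (0:(nfft - 1)) / nfft * frame$fs
  half <- seq_len(nfft %/% 2)
  f <- f[half]; S <- S[half]

  fs <- frame$fs; f0 <- frame$centre_frequency
  pb <- spectral_support(reference_psd, f0, fs)
  keep <- f >= pb$support[1] & f <= pb$support[2]
  ref <- reference_psd(f[keep])
  assert_that(all(ref > 0), "reference PSD must be positive on the analysis band")
  lin <- S[keep] / ref
  structure(
    list(f_mhz = f[keep] / 1e6,
         power_db = 10 * log10(pmax(lin, .Machine$double.xmin)),
         linear_power = lin,
         band = f[keep] >= pb$band[1] & f[keep] <= pb$band[2],
         centre_frequency_mhz = f0 / 1e6,
         window_depth_cm = window$depth_cm %||% NA_real_,
         window_len_s = n / fs,
         sound_speed = frame$sound_speed,
         taper = taper),
    class = "normalized_spectrum")
}

# -6 dB fitting band and -20 dB retained support of a reference PSD,
# clipped to [1 MHz, 0.8 * Nyquist].
spectral_support <- function(reference_psd, f0, fs) {
  fseq <- seq(1e6, 0.8 * fs / 2, length.out = 2048)
  r <- reference_psd(fseq)
  pk <- max(r)
  band <- range(fseq[r >= pk * 10^(-6 / 10)])
  supp <- range(fseq[r >= pk * 10^(-20 / 10)])
  list(band = band, support = supp)
}

#' Linear-regression spectral parameters: MBF, SS, SI
#'
#' Ordinary least squares of the normalised power (dB) against frequency
#' (MHz) over the fitting band.  The spectral slope SS is the fitted slope
#' (dB/MHz), the 0-MHz intercept SI is the fitted intercept (dB), and the
#' midband fit MBF is the fitted value at the probe centre frequency, so
#' `MBF = SS * f_c + SI` holds as an exact identity.
#'
#' @param spec a [normalized_spectrum()].
#' @return list with `mbf` (dB), `ss` (dB/MHz), `si` (dB), `r2`.
#' @export
fit_spectral_params <- function(spec) {
  stopifnot(inherits(spec, "normalized_spectrum"))
  f <- spec$f_mhz[spec$band]
  y <- spec$power_db[spec$band]
  assert_that(length(f) >= 5, "need >= 5 frequency bins on the fitting band")
  assert_that(diff(range(f)) > 0, "degenerate fitting band")
  fit <- lm(y ~ f)
  ss <- unname(coef(fit)[2]); si <- unname(coef(fit)[1])
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(resid(fit)^2) / sst else 1
  list(mbf = ss * spec$centre_frequency_mhz + si,
       ss = ss, si = si, r2 = r2)
}
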
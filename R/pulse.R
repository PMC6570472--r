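#' Transmit pulse specification
#'
#' Describes the imaging pulse of a linear-array acquisition: a
#' Gaussian-envelope sinusoid at the probe centre frequency.  Defaults match
#' a 6 MHz linear array sampled at 40 MHz, with a -6 dB fractional power
#' bandwidth of 0.6 and a sound speed of 1540 m/s.
#'
#' @param centre_frequency pulse centre frequency in Hz.
#' @param fractional_bandwidth -6 dB power bandwidth divided by the centre
#'   frequency; must lie in (0, 2).
#' @param sampling_rate RF sampling rate in Hz; must exceed twice the centre
#'   frequency.
#' @param sound_speed assumed speed of sound in m/s.
#' @return an object of class `pulse_spec`.
#' @examples
#' ps <- pulse_spec()
#' pu <- make_pulse(ps)
#' @export
pulse_spec <- function(centre_frequency = 6e6,
                       fractional_bandwidth = 0.6,
                       sampling_rate = 40e6,
                       sound_speed = 1540) {
  assert_that(centre_frequency > 0 && sampling_rate > 0 && sound_speed > 0,
              "centre_frequency, sampling_rate and sound_speed must be positive")
  assert_that(centre_frequency < sampling_rate / 2,
              "centre_frequency must be below the Nyquist frequency (sampling_rate/2)")
  assert_that(fractional_bandwidth > 0 && fractional_bandwidth < 2,
              "fractional_bandwidth must lie in (0, 2)")
  structure(
    list(centre_frequency = centre_frequency,
         fractional_bandwidth = fractional_bandwidth,
         sampling_rate = sampling_rate,
         sound_speed = sound_speed),
    class = "pulse_spec")
}

#' Generate the sampled transmit pulse and its analytic power spectrum
#'
#' The pulse is a unit-peak Gaussian-envelope sinusoid whose -6 dB power
#' bandwidth equals `fractional_bandwidth * centre_frequency`.  The envelope
#' standard deviation follows from the Gaussian Fourier pair: for a -6 dB
#' power full width `B`, `sigma_t = sqrt(0.6 ln 10) / (pi B)`.
#'
#' The returned object carries the closed-form power spectrum of the sampled
#' pulse (the continuous-time Fourier transform scaled by the sampling
#' rate).  This analytic spectrum is used as the normalisation reference of
#' [normalized_spectrum()]: dividing a tissue spectrum by it removes the
#' system (pulse) response, which is the role a reference phantom plays on a
#' clinical scanner.
#'
#' @param spec a [pulse_spec()].
#' @return an object of class `qus_pulse` with elements `t` (time axis, s),
#'   `p` (samples, unit peak), `spec`, `sigma_t`, and `reference_psd`, a
#'   function of frequency in Hz returning the analytic power spectrum.
#' @export
make_pulse <- function(spec = pulse_spec()) {
  stopifnot(inherits(spec, "pulse_spec"))
  B <- spec$fractional_bandwidth * spec$centre_frequency
  sigma_t <- sqrt(0.6 * log(10)) / (pi * B)
  dt <- 1 / spec$sampling_rate
  half <- ceiling(3.5 * sigma_t / dt)
  assert_that(half >= 1, "pulse bandwidth implies sub-sample duration; check parameters")
  tt <- (-half:half) * dt
  p <- exp(-tt^2 / (2 * sigma_t^2)) * cos(2 * pi * spec$centre_frequency * tt)
  f0 <- spec$centre_frequency
  fs <- spec$sampling_rate
  ref <- function(f) {
    G <- function(x) sigma_t * sqrt(2 * pi) * exp(-2 * pi^2 * sigma_t^2 * x^2)
    (fs * 0.5 * (G(f - f0) + G(f + f0)))^2
  }
  structure(
    list(t = tt, p = p, spec = spec, sigma_t = sigma_t, reference_psd = ref),
    class = "qus_pulse")
}

#' Usable frequency band of a pulse
#'
#' Returns the band where the analytic pulse power spectrum is within
#' `floor_db` of its peak, intersected with `[1 MHz, 0.8 * Nyquist]`.  The
#' -6 dB band is the conventional fitting band for the spectral-regression
#' parameters; a wider -20 dB band is retained for the scatterer-spacing
#' estimator, which benefits from observing more ripple periods.
#'
#' @param pulse a `qus_pulse`.
#' @param floor_db band edge level relative to the spectral peak, in dB
#'   (negative).
#' @return numeric length-2 vector, band edges in Hz.
#' @export
pulse_band <- function(pulse, floor_db = -6) {
  stopifnot(inherits(pulse, "qus_pulse"))
  spec <- pulse$spec
  f0 <- spec$centre_frequency
  # Gaussian analytic half width at floor_db (power)
  sigma_f <- 1 / (2 * pi * pulse$sigma_t)
  hw <- sigma_f * sqrt(-floor_db / 10 * log(10))
  lo <- max(f0 - hw, 1e6)
  hi <- min(f0 + hw, 0.8 * spec$sampling_rate / 2)
  assert_that(lo < hi, "degenerate analysis band")
  c(lo, hi)
}
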
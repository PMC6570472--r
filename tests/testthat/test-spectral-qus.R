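# Helper: a synthetic normalized_spectrum with prescribed dB power.
synthetic_spectrum <- function(power_db, f_mhz = seq(4.2, 7.8, length.out = 120),
                               fc = 6, c0 = 1540, window_len_s = 1) {
  structure(list(f_mhz = f_mhz, power_db = power_db,
                 linear_power = 10^(power_db / 10),
                 band = rep(TRUE, length(f_mhz)),
                 centre_frequency_mhz = fc, window_depth_cm = NA_real_,
                 window_len_s = window_len_s, sound_speed = c0, taper = "rect"),
            class = "normalized_spectrum")
}

test_that("window tiling reproduces the 2 mm / 94% overlap arithmetic", {
  fs <- 40e6; c0 <- 1540
  fr <- rf_frame(matrix(0, 1559, 60), fs = fs, line_pitch = 2e-4, sound_speed = c0)
  sq <- rbind(c(5, 2), c(5, 10), c(25, 10), c(25, 2))
  roi <- build_rois(sq, fr)
  g <- tile_windows(roi, fr)
  expect_equal(attr(g, "len_a"), 104)   # round(2e-3 * 2 * fs / c)
  expect_equal(attr(g, "step_a"), 6)    # max(1, round(0.06 * 104))
  expect_equal(attr(g, "len_l"), 10)
  expect_equal(attr(g, "step_l"), 1)
  expect_gt(nrow(g), 0)
  # overlap 0 -> step equals the window length
  g0 <- tile_windows(roi, fr, overlap = 0)
  expect_equal(attr(g0, "step_a"), 104)
  expect_equal(attr(g0, "step_l"), 10)
  # ROI too small for one window -> empty grid with warning
  tiny <- build_rois(rbind(c(10, 5), c(10, 5.4), c(10.8, 5.4), c(10.8, 5)), fr)
  expect_warning(ge <- tile_windows(tiny, fr), "smaller than one")
  expect_equal(nrow(ge), 0)
})

test_that("a window holding exactly the reference pulse normalises to ~0 dB", {
  pu <- default_pulse()
  n <- 104
  line <- numeric(n)
  at <- (n - length(pu$p)) %/% 2
  line[at + seq_along(pu$p)] <- pu$p
  fr <- rf_frame(matrix(line, n, 10), fs = 40e6, line_pitch = 2e-4)
  w <- list(a0 = 1, a1 = n, l0 = 1, l1 = 10, depth_cm = 1)
  sp <- normalized_spectrum(fr, w, pu$reference_psd, taper = "rect")
  on_band <- sp$power_db[sp$band]
  expect_lt(max(abs(on_band)), 0.5)
  # doubling the window amplitudes raises the whole spectrum by 6.02 dB
  fr2 <- rf_frame(2 * fr$samples, fs = 40e6, line_pitch = 2e-4)
  sp2 <- normalized_spectrum(fr2, w, pu$reference_psd, taper = "rect")
  expect_equal(sp2$power_db - sp$power_db,
               rep(20 * log10(2), length(sp$power_db)), tolerance = 1e-9)
})

test_that("spectral line fit is exact and satisfies the MBF identity", {
  f <- seq(4.2, 7.8, length.out = 100)
  sp <- synthetic_spectrum(2 * f + 3, f_mhz = f)
  fit <- fit_spectral_params(sp)
  expect_equal(fit$ss, 2, tolerance = 1e-10)
  expect_equal(fit$si, 3, tolerance = 1e-10)
  expect_equal(fit$mbf, 15, tolerance = 1e-10)

  flat <- fit_spectral_params(synthetic_spectrum(rep(-10, 100), f_mhz = f))
  expect_equal(flat$ss, 0, tolerance = 1e-10)
  expect_equal(flat$si, -10, tolerance = 1e-10)
  expect_equal(flat$mbf, -10, tolerance = 1e-10)
})

test_that("slope estimates are unbiased under additive dB noise", {
  f <- seq(4.2, 7.8, length.out = 60)
  set.seed(42)
  ss <- replicate(200, fit_spectral_params(
    synthetic_spectrum(2 * f + 3 + rnorm(60), f_mhz = f))$ss)
  se <- stats::sd(ss) / sqrt(length(ss))
  expect_lt(abs(mean(ss) - 2), 3 * se)
})

test_that("diffuse fine-scatterer spectra are flat on average (SS ~ 0)", {
  frames <- fixture("frames_flat",
                    synth_frames(full_core_phantom(1), 3, seed = 77))
  est <- do.call(rbind, lapply(frames, frame_estimates, what = "fit"))
  expect_gte(nrow(est), 50)
  se <- stats::sd(est$ss) / sqrt(nrow(est))
  expect_lt(abs(mean(est$ss)), max(3 * se, 0.1))
})

test_that("Gaussian form-factor fit inverts its own model", {
  f <- seq(4.2, 7.8, length.out = 120)
  k2 <- (2 * pi * f * 1e6 / 1540)^2
  model <- function(asd_um, C) 10 * log10(C * exp(-0.827 * k2 * (asd_um * 1e-6 / 2)^2))
  est <- fit_form_factor(synthetic_spectrum(model(100, 10), f_mhz = f))
  expect_lt(abs(est$asd - 100), 2)
  expect_equal(est$aac, 10, tolerance = 0.05)
  expect_false(est$flagged)

  # concentration scaling x10 adds 10 dB to AAC and leaves ASD unchanged
  est10 <- fit_form_factor(synthetic_spectrum(model(100, 100), f_mhz = f))
  expect_equal(est10$aac - est$aac, 10, tolerance = 0.05)
  expect_lt(abs(est10$asd - est$asd), 0.5)

  # Rayleigh limit: no roll-off (rising spectrum) pins ASD at the lower bound
  ray <- fit_form_factor(synthetic_spectrum(40 * log10(f), f_mhz = f))
  expect_true(ray$flagged)
  expect_equal(ray$asd, 10)
})

test_that("spacing maps spectral ripple period through sas = c / (2 df)", {
  f <- seq(2.7, 9.3, length.out = 400)
  ripple <- 1 + 0.6 * cos(2 * pi * f / 0.77)
  sp <- synthetic_spectrum(10 * log10(ripple + 1e-6), f_mhz = f, window_len_s = 1)
  est <- estimate_sas(sp)
  expect_false(est$absent)
  expect_equal(est$sas, 1540 / (2 * 0.77e6) * 1e6, tolerance = 0.02)
  expect_gt(est$peak_prominence, 0.25)

  # featureless spectrum -> absent flag
  flat <- synthetic_spectrum(rep(0, 400), f_mhz = f)
  expect_true(estimate_sas(flat)$absent)
})

test_that("attenuation estimation is null-calibrated", {
  # identical spectra at different depths -> zero decay -> ACE = 0
  f <- seq(4.2, 7.8, length.out = 80)
  sps <- lapply(c(1, 1.6, 2.2), function(d) {
    s <- synthetic_spectrum(0.5 * f - 4, f_mhz = f)
    s$window_depth_cm <- d
    s
  })
  est <- estimate_ace(sps)
  expect_equal(est$ace, 0, tolerance = 1e-10)
  expect_equal(est$n_depth_windows, 3)
  expect_error(estimate_ace(sps[1:2]), ">= 3 windows")
  sh <- sps; sh[[2]]$window_depth_cm <- 1.01; sh[[3]]$window_depth_cm <- 1.02
  expect_error(estimate_ace(sh), "depth span")

  # alpha = 0 phantom -> ACE within 0.1 of 0
  fr <- frames_for_diameter(100)[[1]]
  pu <- default_pulse()
  g <- frame_windows(fr, step_frac = 0.5)
  sps0 <- lapply(seq_len(nrow(g)), function(i)
    normalized_spectrum(fr, g[i, ], pu$reference_psd))
  expect_lt(abs(estimate_ace(sps0)$ace), 0.1)
})

test_that("the MBF identity holds to machine precision on real windows", {
  est <- estimates_for_diameter(100)[1:40, ]
  expect_lt(max(abs(est$mbf - (est$ss * 6 + est$si))), 1e-12)
})
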
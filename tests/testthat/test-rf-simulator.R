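test_that("pulse has the requested centre frequency and -6 dB bandwidth", {
  pu <- default_pulse()
  expect_equal(max(abs(pu$p)), 1, tolerance = 1e-6)

  nfft <- 8192
  P <- Mod(fft(c(pu$p, rep(0, nfft - length(pu$p)))))^2
  f <- (0:(nfft - 1)) / nfft * pu$spec$sampling_rate
  half <- seq_len(nfft / 2)
  peak <- f[half][which.max(P[half])]
  expect_lt(abs(peak - 6e6), pu$spec$sampling_rate / nfft + 1e-6)

  # measured -6 dB power band vs fractional_bandwidth * f0 = 3.6 MHz
  inband <- f[half][P[half] >= max(P) * 10^(-0.6)]
  width <- diff(range(inband))
  expect_lt(abs(width - 3.6e6) / 3.6e6, 0.02)
  expect_equal(range(inband) / 1e6, c(4.2, 7.8), tolerance = 0.02)

  # analytic reference PSD matches the DFT of the generated pulse
  expect_equal(pu$reference_psd(6e6), max(P), tolerance = 0.01)
})

test_that("pulse spec rejects invalid parameters", {
  expect_error(pulse_spec(sampling_rate = 8e6, centre_frequency = 6e6), "Nyquist")
  expect_error(pulse_spec(fractional_bandwidth = 0), "fractional_bandwidth")
  expect_error(pulse_spec(fractional_bandwidth = 2.5), "fractional_bandwidth")
})

test_that("scatterer placement follows the spatial Poisson model", {
  # zero density -> empty
  ph0 <- full_core_phantom(100, density = 0)
  expect_equal(nrow(place_scatterers(ph0, seed = 1)), 0)

  # density 10/mm^2 over a 100 mm^2 core: count within 3 sigma of 1000
  pop <- scatterer_population(10, 100)
  ph <- tissue_phantom(extent = c(12, 12),
                       core_polygon = rbind(c(1, 1), c(1, 11), c(11, 11), c(11, 1)),
                       populations = list(core = pop), attenuation = 0)
  counts <- vapply(1:5, function(s) sum(place_scatterers(ph, s)$region == "core"), 0)
  expect_true(all(abs(counts - 1000) < 3 * sqrt(1000)))

  # jitter-free lattice: sorted axial gaps all equal the spacing
  phl <- full_core_phantom(100, density = 0, regular_spacing = 1000)
  phl$populations$core$spacing_jitter <- 0
  sc <- place_scatterers(phl, seed = 3)
  zs <- sort(unique(round(sc$z_mm, 9)))
  expect_true(all(abs(diff(zs) - 1) < 1e-9))
})

test_that("RF synthesis places echoes at the round-trip time of flight", {
  pu <- default_pulse()
  ph <- full_core_phantom(100, density = 0)
  # empty scatterer list, no noise -> all-zero frame
  empty <- place_scatterers(ph, 1)
  fr0 <- synthesize_rf(ph, pu, seed = 1, snr_db = Inf, scatterers = empty)
  expect_true(all(fr0$samples == 0))

  # single scatterer at 20 mm depth: envelope peak at 2*0.020*fs/c ~ 1039
  one <- empty
  one[1, ] <- list(20, 6, 1, 100, "core")
  fr1 <- synthesize_rf(ph, pu, seed = 1, snr_db = Inf, scatterers = one)
  line <- round(6 / 0.2) + 1
  env <- analytic_envelope(fr1$samples[, line])
  expect_lt(abs(which.max(env) - 2 * 0.020 * fr1$fs / fr1$sound_speed), 2.5)

  # linearity: doubling all amplitudes scales the frame exactly x2
  two <- one; two$amplitude <- 2 * two$amplitude
  fr2 <- synthesize_rf(ph, pu, seed = 1, snr_db = Inf, scatterers = two)
  expect_equal(fr2$samples, 2 * fr1$samples, tolerance = 1e-12)

  # time invariance: shifting the scatterer by dz shifts the echo by 2 dz fs/c
  sh <- one; sh$z_mm <- sh$z_mm + 3
  fr3 <- synthesize_rf(ph, pu, seed = 1, snr_db = Inf, scatterers = sh)
  d <- round(2 * 3e-3 * fr1$fs / fr1$sound_speed)
  env3 <- analytic_envelope(fr3$samples[, line])
  expect_lt(abs(which.max(env3) - which.max(env) - d), 2.5)

  # out-of-grid scatterer is skipped with a warning
  out <- one; out$z_mm <- 45
  expect_warning(synthesize_rf(ph, pu, seed = 1, snr_db = Inf, scatterers = out),
                 "skipped")
})

test_that("frames carry their generating ground truth", {
  fr <- frames_for_diameter(100)[[1]]
  gt <- fr$ground_truth
  expect_equal(gt$populations$core$effective_diameter, 100)
  expect_equal(unname(gt$attenuation["core"]), 0)
})

test_that("simulated cohorts have the requested size, labels and null behaviour", {
  tab <- simulate_cohort(cohort_spec(n_per_class = c(83, 17), seed = 5))
  expect_equal(nrow(tab), 100)
  expect_equal(sum(tab$class == 1), 83)
  expect_equal(ncol(tab), 49 + 3 + 1)
  expect_named(tab, c(qus_feature_names(TRUE), "class"), ignore.order = FALSE)

  # all effect sizes 0 -> univariate p-values uniform across features
  null_tab <- simulate_cohort(cohort_spec(n_per_class = c(60, 60), n_features = 200,
                                          effect_sizes = 0, correlation = 0, seed = 9))
  p <- univariate_rank(null_tab[, 1:200], null_tab$class)$p_value
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)

  # a single strong feature ranks first in nearly every replicate
  hits <- vapply(1:100, function(s) {
    tb <- simulate_cohort(cohort_spec(n_per_class = c(50, 50), n_features = 10,
                                      effect_sizes = c(3, rep(0, 9)),
                                      correlation = 0, seed = s))
    pv <- vapply(1:10, function(j) t.test(tb[tb$class == 1, j], tb[tb$class == 0, j])$p.value, 0)
    which.min(pv) == 1L
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  # invalid correlation structure is rejected
  bad <- matrix(0.99, 3, 3); bad[1, 2] <- bad[2, 1] <- -0.99; diag(bad) <- 1
  expect_error(cohort_spec(n_features = 3, correlation = bad), "positive definite")
})
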
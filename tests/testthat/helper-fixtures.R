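# Shared fixtures: phantoms, frames and window-level estimates are built
# once per test run and cached, because RF synthesis dominates runtime.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

default_pulse <- function() fixture("pulse", make_pulse(pulse_spec()))

# Phantom whose core fills (almost) the whole grid: used for estimator
# recovery, where margins are irrelevant.
full_core_phantom <- function(diameter_um, density = 60, alpha = 0,
                              extent = c(30, 12), regular_spacing = NULL,
                              lattice_amplitude = 3) {
  pop <- scatterer_population(density, diameter_um,
                              regular_spacing = regular_spacing,
                              lattice_amplitude = lattice_amplitude)
  eps <- 0.01
  poly <- rbind(c(eps, eps), c(eps, extent[2] - eps),
                c(extent[1] - eps, extent[2] - eps), c(extent[1] - eps, eps))
  tissue_phantom(extent = extent, core_polygon = poly,
                 populations = list(core = pop),
                 attenuation = alpha)
}

synth_frames <- function(phantom, n, seed, ...) {
  lapply(seq_len(n), function(i)
    synthesize_rf(phantom, default_pulse(), seed = derive_seed(seed, i), ...))
}

# Non-overlapping analysis windows over the full frame (no ROI machinery).
frame_windows <- function(frame, step_frac = 1) {
  fs <- frame$fs; c0 <- frame$sound_speed
  len_a <- round(2e-3 * 2 * fs / c0)
  len_l <- max(1L, round(2e-3 / frame$line_pitch))
  sa <- max(1L, round(len_a * step_frac)); sl <- max(1L, round(len_l * step_frac))
  g <- expand.grid(a0 = seq(1, nrow(frame$samples) - len_a + 1, by = sa),
                   l0 = seq(1, ncol(frame$samples) - len_l + 1, by = sl))
  g$a1 <- g$a0 + len_a - 1L; g$l1 <- g$l0 + len_l - 1L
  g$depth_cm <- (g$a0 + (len_a - 1) / 2) / fs * c0 / 2 * 100
  g
}

# Per-window spectral fits over one frame; returns a data.frame.
frame_estimates <- function(frame, what = c("fit", "ff"), step_frac = 1) {
  pu <- default_pulse()
  g <- frame_windows(frame, step_frac)
  out <- lapply(seq_len(nrow(g)), function(i) {
    sp <- normalized_spectrum(frame, g[i, ], pu$reference_psd, taper = "hann")
    row <- list(depth_cm = g$depth_cm[i])
    if ("fit" %in% what) row <- c(row, fit_spectral_params(sp))
    if ("ff" %in% what) {
      ff <- fit_form_factor(sp)
      row <- c(row, list(asd = ff$asd, aac = ff$aac, ff_flag = ff$flagged))
    }
    if ("sas" %in% what) {
      sr <- normalized_spectrum(frame, g[i, ], pu$reference_psd, taper = "rect",
                                nfft = 4096)
      ss <- estimate_sas(sr)
      row <- c(row, list(sas = ss$sas, sas_prom = ss$peak_prominence,
                         sas_absent = ss$absent))
    }
    as.data.frame(row)
  })
  do.call(rbind, out)
}

frames_for_diameter <- function(d, n = 20) {
  fixture(paste0("frames_d", d),
          synth_frames(full_core_phantom(d), n, seed = 1000 + d))
}

estimates_for_diameter <- function(d, n = 20) {
  fixture(paste0("est_d", d), {
    do.call(rbind, lapply(frames_for_diameter(d, n),
                          frame_estimates, what = c("fit", "ff")))
  })
}

# Small cohort generators used by selection/classification tests.
separated_cohort <- function(n = 50, delta = 3, p_signal = 3, p_noise = 2, seed = 1) {
  set.seed(seed)
  shift <- delta / sqrt(p_signal)
  X <- rbind(matrix(rnorm(n * p_signal), n),
             matrix(rnorm(n * p_signal, shift), n))
  X <- cbind(X, matrix(rnorm(2 * n * p_noise), 2 * n))
  colnames(X) <- c(paste0("SIG", seq_len(p_signal)), paste0("NOI", seq_len(p_noise)))
  list(table = as.data.frame(X), labels = rep(c(0L, 1L), each = n))
}

xor_cohort <- function(n = 120, p_noise = 4, seed = 11) {
  set.seed(seed)
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  y <- as.integer(xor(x1, x2))
  X <- cbind(XORA = x1 + rnorm(n, 0, 0.2), XORB = x2 + rnorm(n, 0, 0.2),
             matrix(rnorm(n * p_noise), n,
                    dimnames = list(NULL, paste0("NOI", seq_len(p_noise)))))
  list(table = as.data.frame(X), labels = y)
}

# Brute-force GLCM oracle: direct enumeration of all symmetric pairs at the
# four unit offsets, independently of the package implementation.
glcm_oracle <- function(v, levels) {
  v <- as.matrix(v)
  rng <- range(v, na.rm = TRUE)
  q <- if (rng[2] > rng[1])
    matrix(pmin(levels, 1L + floor((v - rng[1]) / (rng[2] - rng[1]) * levels)),
           nrow(v)) else
    (v * 0 + 1)
  feats <- matrix(NA_real_, 4, 4)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  for (oi in seq_along(offs)) {
    off <- offs[[oi]]
    p <- matrix(0, levels, levels)
    for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
      if (is.na(q[r, cc]) || is.na(q[r2, c2])) next
      p[q[r, cc], q[r2, c2]] <- p[q[r, cc], q[r2, c2]] + 1
      p[q[r2, c2], q[r, cc]] <- p[q[r2, c2], q[r, cc]] + 1
    }
    if (sum(p) == 0) { feats[, oi] <- c(0, 0, 1, 1); next }
    p <- p / sum(p)
    con <- 0; ene <- 0; hom <- 0; mu_i <- 0; mu_j <- 0
    for (i in 1:levels) for (j in 1:levels) {
      con <- con + p[i, j] * (i - j)^2
      ene <- ene + p[i, j]^2
      hom <- hom + p[i, j] / (1 + abs(i - j))
      mu_i <- mu_i + i * p[i, j]; mu_j <- mu_j + j * p[i, j]
    }
    s_i <- 0; s_j <- 0; cov <- 0
    for (i in 1:levels) for (j in 1:levels) {
      s_i <- s_i + (i - mu_i)^2 * p[i, j]
      s_j <- s_j + (j - mu_j)^2 * p[i, j]
      cov <- cov + (i - mu_i) * (j - mu_j) * p[i, j]
    }
    cr <- if (s_i > 0 && s_j > 0) cov / sqrt(s_i * s_j) else 0
    feats[, oi] <- c(con, cr, ene, hom)
  }
  rowMeans(feats)
}
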
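---
title: "Quantitative ultrasound response prediction: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ultrasound response prediction: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the signal model
behind each estimator, the parameters that matter and their defaults, what
the synthetic-data generator does and does not emulate, and the places
where the design was genuinely open and a choice had to be made.

## 1. The problem

Conventional B-mode imaging discards the frequency content of the
backscattered radiofrequency (RF) signal. Quantitative ultrasound (QUS)
retains it: the shape of the per-window power spectrum encodes the size,
concentration, spacing and attenuation of sub-resolution scatterers, which
in tumours reflect cellular and glandular microstructure. The package
implements the pre-treatment prediction pipeline used in locally advanced
breast cancer: QUS features from the tumour core and a 5 mm margin band,
fed through imbalance-corrected feature selection into a shallow neural
network that predicts clinical response and 5-year recurrence-free
survival.

Because no patient-level RF dataset is publicly deposited for this design,
the package ships a first-class simulator (`tissue_phantom()`,
`synthesize_rf()`, `simulate_cohort()`) whose ground truth drives every
estimator-recovery and classifier-sanity test.

## 2. RF signal model and simulator

A frame is synthesised per lateral line as an impulse train at scatterer
depths (`z = c·t/2`) convolved with a Gaussian-envelope pulse.  Three
physical effects shape the spectrum:

* **Form factor.** The backscattered *power* of a scatterer of effective
  diameter `d` carries the Gaussian form factor
  `F(f) = exp(−0.827·k²·(d/2)²)`, `k = 2πf/c`; the simulator applies
  `sqrt(F)` to echo amplitudes so a round trip through the estimator sees
  `F` exactly once.  Because the simulated scatterers are otherwise
  frequency-flat point reflectors and normalisation is against the pulse
  spectrum (not a Rayleigh reference phantom), the fitted model contains no
  `f⁴` Rayleigh factor; `fit_form_factor(rayleigh_exponent = 4)` restores
  it for spectra normalised against a Rayleigh-scattering reference.
  A corollary used by the tests: as `d → 0` with zero attenuation the
  normalised spectrum is flat and the fitted spectral slope approaches 0.
* **Attenuation.** Round-trip amplitude factor `10^(−2·α·f·z/20)` with `α`
  in dB/cm/MHz.  It is applied in thin depth bins (1 mm default) with an
  exact per-scatterer correction at the centre frequency, so only the
  spectral *tilt* is quantised by binning — adequate for recovering `α`
  within the tolerances tested.
* **Electronic noise.** White Gaussian noise at a configurable SNR
  (default 30 dB relative to the RF RMS).

There is no diffraction, focusing or elevational beam model: scatterers map
to their nearest line and each line is an independent 1-D convolution.
This is deliberate — every downstream estimator operates on windowed
per-line spectra, which this level of realism exercises fully — but it
means the simulator does not reproduce depth-dependent beamwidth effects,
speckle statistics beyond the Rayleigh regime, or aberration.  Passing the
recovery tests therefore demonstrates correctness of the estimators under
the stated signal model, not their field performance on clinical scanners.

Defaults mirror a clinical linear-array acquisition: 6 MHz centre
frequency, 40 MHz sampling, 0.6 fractional (−6 dB) bandwidth, 1540 m/s,
0.2 mm line pitch, 30–40 mm imaging depth (desk-scale rather than the
4–6 cm clinical range, for runtime).

## 3. Windowing and spectral estimation

Windows are 2 × 2 mm with 94 % overlap (`tile_windows()`): 104 axial
samples and 10 lines at the defaults, stepping 6 samples / 1 line.  Windows
at least 90 % inside the ROI mask are kept (configurable).  Per window,
line periodograms (mean-removed, Hann-tapered, zero-padded) are averaged
and divided by the analytic pulse power spectrum — the role a measured
reference phantom plays on a scanner; `normalized_spectrum()` takes the
reference as an explicit argument so a measured one can be substituted.

The fitting band is the reference −6 dB band intersected with
`[1 MHz, 0.8·Nyquist]` (4.2–7.8 MHz at defaults); the spectrum is retained
over the −20 dB band (≈2.7–9.3 MHz) for the spacing estimator.

* **MBF/SS/SI** (`fit_spectral_params()`): OLS of dB power on frequency in
  MHz.  `MBF = SS·f_c + SI` is an identity of the fit and is asserted to
  machine precision.
* **ASD/AAC** (`fit_form_factor()`): linearised regression of `ln S` on
  `k²` (slope `−0.827·(ASD/2)²`, intercept `ln C`), followed by a
  golden-section polish of ASD to 1 µm with `C` profiled out.  Estimates
  are clipped to a 10–500 µm search range — the scatterer sizes clinical
  frequencies are sensitive to; a non-negative slope means the window
  carries no size information and pins the estimate at the lower bound
  with a flag.  Per-window estimates are right-skewed (a nonlinear
  transform of a noisy slope, truncated at the bound), so recovery tests
  quote the **median** across windows; the map *means* that become patient
  features keep the plain mean, per the feature-schema definition.
* **SAS** (`estimate_sas()`): a lattice at spacing `d` produces spectral
  ripple of period `Δf = c/(2d)`.  The estimator autocorrelates the
  detrended linear-power spectrum and converts the most prominent positive
  peak's lag.  Four numerical choices matter at the 2 mm window scale,
  where a 1 mm spacing is near the resolution limit:
  1. *rectangular* (not Hann) taper for this path — the Hann main lobe
     (≈1.5 MHz at 104 samples) smears the 0.77 MHz ripple away entirely;
  2. quadratic-polynomial detrend of the linear power (a plain mean
     removal leaves band-envelope structure that autocorrelates);
  3. candidate peaks re-weighted by the inverse squared taper
     autocorrelation at the implied time lag, undoing the window-truncation
     attenuation that otherwise favours short spacings;
  4. parabolic interpolation of the chosen peak across adjacent lags.
  The detection threshold on the normalised autocorrelation peak
  (`prominence_threshold`, default 0.32) was calibrated once by simulation
  against the package's lattice and diffuse phantom configurations and
  then frozen; windows below it report `NA` ("no detectable periodicity"),
  and parametric maps exclude absent cells from all statistics.
* **ACE** (`estimate_ace()`): spectral-difference method — per band
  frequency, regress dB power on window depth (cm); regress that slope on
  frequency (MHz); `ACE = −slope/2` (round trip).  Requires ≥3 windows
  spanning ≥1 cm.  Whether maps should be attenuation-compensated before
  the spectral fits is not settled; the package computes ACE as a
  whole-core scalar and applies no compensation to the other estimators,
  keeping the two questions separable.

## 4. Maps, texture and the 49-feature schema

Estimates are placed at window-grid positions (`build_map()`); map
resolution equals the window step.  GLCM texture (`glcm_features()`) uses
16 equal-width levels over each map's own min–max (making the features
invariant to affine rescaling of the parameter values), symmetric
co-occurrence at distance 1 over the four unit offsets, pairs touching an
absent cell skipped, and the four offsets averaged.  Conventions for
degenerate inputs: a constant map has CON = 0, ENE = HOM = 1 and COR
*defined as* 0 (bounded, rather than NaN); maps with fewer than 4 present
cells yield no texture and the plane is excluded from aggregation for that
map.

Texture is computed on core maps only; the margin contributes means and
the denominators of the contrast features — this follows the feature
schema's row structure, as does ACE being a core-only scalar.  The
core-to-margin features are `CMR = mean(core)/mean(margin)` and a
contrast-to-noise-style
`CMCR = |mean(core) − mean(margin)| / (sd(core) + sd(margin))`, the
denominator floored at machine epsilon and the result capped at 10⁶ so
constant maps stay finite.  The exact historical CMCR formula is not
reprinted in the accessible literature for this pipeline; the
contrast-to-noise form is isolated in one function (`cmr_cmcr()`) so an
alternative is a one-line change.  Counting means, textures, CMR and CMCR
gives exactly 49 QUS names (`qus_feature_names()`), 52 with ER/PR/HER2.

Patients are imaged on 4–7 planes; `aggregate_patient()` averages features
over planes, using present planes only for features missing on some.  The
5 mm margin is *derived* from the core contour by Euclidean-distance
dilation computed in millimetres (axial and lateral pixel pitches differ
by an order of magnitude, so a pixel-based dilation would be visibly
anisotropic); whether the original margins were contoured or derived is
not documented, and derivation is the reproducible choice.

## 5. Cohort generator

`simulate_cohort()` draws class-conditional multivariate normal QUS
features with exchangeable correlation plus Bernoulli receptor statuses.
Defaults are matched to the clinical study design: 83 responders / 17
non-responders, 49 features, effect size 0.3 SD per feature and
correlation 0.3 — small enough that no single feature separates the
classes univariately at n = 100, which is the regime that motivates
multi-feature non-linear classification in the first place.  What the
generator does **not** emulate: non-Gaussian feature distributions, the
real (unknown) correlation structure among QUS parameters, label noise in
response scoring, and any nonlinear feature–label structure except where
tests plant it explicitly (the XOR pair).  Classifier results on these
cohorts validate the machinery, not clinical effect sizes.

`study_labels()` returns the printed label structure of the reference
100-patient cohort (83 R / 17 NR2; 45 CR / 47 PR / 8 NR3; 86/14 survival)
for balanced-set arithmetic; the MR 4 vs 5 split inside CR is arbitrary
since only their union is printed.

## 6. Balancing, selection and evaluation

`make_balanced_sets()` forms sets of all minority patients plus an
equal-size draw from the majority, without replacement within a set, drawn
repeatedly until every majority patient has appeared.  Only the set *size*
is deterministic (twice the minority); the number of sets is a property of
the random coverage process, so tests assert sizes and coverage, and
compare mean set counts against a direct Monte-Carlo of the same procedure.

`sffs_select()` implements sequential floating forward selection with
p-value initialisation: start from the top-ranked feature of
`univariate_rank()` (t-test vs Mann–Whitney decided per feature by a
Shapiro–Wilk screen at α = 0.05 in both classes; ties in p broken by
standardised mean difference, then name), add the candidate maximising the
criterion, then conditionally drop features.  Two details keep the search
sound: removal must beat the *best subset of that size seen so far* (not
merely the current value), and the just-added feature is protected — the
naive "remove whenever it helps" rule oscillates forever.  The criterion
is validation AUC of the configured classifier (default: the network with
3 hidden units) averaged over 3 inner stratified splits whose randomness
derives entirely from the seed, making the criterion a deterministic
function of the subset (`selection_criterion()` exposes it).  Subset size
is capped at 5 against overfitting balanced sets as small as 16.

`train_eval_ann()` standardises by training-split statistics only, tunes
the hidden size over 1–10 by validation AUC on stratified 70/15/15 splits,
and averages test metrics over 10 independent re-splits ("bootstrapped"
train/validate/test sets read as re-splits; stratification satisfies the
every-class-in-every-part check constructively, with resampling retained
as a fallback).  The network is `nnet`: logistic hidden and output units,
cross-entropy loss, BFGS with weight decay 0.01 and 200 iterations as the
regularised stand-in for iteration-wise early stopping, which `nnet` does
not expose.  `train_eval_knn()` follows the identical protocol with k
tuned over {1,3,5,7,9} and vote fractions as AUC scores.  Metrics follow
the printed definitions (sensitivity TP/P, specificity TN/N, accuracy
correct/total, trapezoidal AUC via the rank identity); aggregation across
balanced sets uses the sample (n−1) SD.

All randomness flows from one master seed through labelled hash-derived
streams (`derive_seed()`), so a pipeline run is reproducible byte-for-byte
— asserted by the determinism test.

## 7. Problem sizes and limitations

The test-suite phantom studies use 20 frames per condition of a
30 × 12 mm full-core phantom (≈84 windows per frame); the acceptance
script uses 6 frames per condition.  These sizes were chosen so estimator
recovery assertions sit well inside their tolerances while the whole suite
runs in minutes on one CPU.

Known limitations: no absolute backscatter-coefficient calibration (AAC is
relative to an arbitrary reference); Gaussian form factor only (no fluid
sphere or shell); Fourier-family SAS only (no wavelet variant); the 2-D
line-convolution simulator cannot validate beam-dependent effects; and
classifier accuracies on synthetic cohorts say nothing about accuracies on
the undeposited clinical cohort — the pipeline reproduces the *procedure*
and its printed arithmetic, with recovery guarantees only against its own
generator's ground truth.
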
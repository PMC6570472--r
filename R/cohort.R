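#' Synthetic cohort specification
#'
#' Describes a two-class labelled feature cohort with known ground truth:
#' class-conditional multivariate normal QUS features with per-feature
#' standardised mean differences and an exchangeable inter-feature
#' correlation, plus Bernoulli molecular receptor statuses with
#' class-conditional prevalences.
#'
#' The defaults mirror the clinical study design this pipeline targets: 83
#' responders versus 17 non-responders, 49 QUS features, and effect sizes
#' of 0.3 SD on every feature — small enough that no single feature
#' separates the classes (univariate p-values at n = 100 hover around or
#' above 0.05), which is precisely the regime that motivates multi-feature
#' non-linear classification.
#'
#' @param n_per_class integer length-2, class sizes (class 1 = responder
#'   first, class 0 second); each >= 2.
#' @param n_features number of QUS features.
#' @param effect_sizes standardised mean differences per feature (recycled).
#' @param correlation exchangeable inter-feature correlation in `[0, 1)`,
#'   or a full correlation matrix (must be positive definite).
#' @param molecular_rates 2-row matrix (class1, class0) of positive rates
#'   for ER, PR, HER2.
#' @param seed integer seed recorded into the table.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(83, 17),
                        n_features = 49,
                        effect_sizes = 0.3,
                        correlation = 0.3,
                        molecular_rates = rbind(c(0.6, 0.5, 0.35),
                                                c(0.6, 0.5, 0.15)),
                        seed = 1L) {
  assert_that(length(n_per_class) == 2 && all(n_per_class >= 2),
              "need >= 2 samples per class")
  effect_sizes <- rep_len(effect_sizes, n_features)
  if (is.matrix(correlation)) {
    assert_that(nrow(correlation) == n_features && ncol(correlation) == n_features,
                "correlation matrix dimension must match n_features")
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    assert_that(min(ev) > 1e-10, "correlation matrix must be positive definite")
  } else {
    assert_that(correlation >= 0 && correlation < 1,
                "exchangeable correlation must lie in [0, 1)")
  }
  structure(
    list(n_per_class = n_per_class, n_features = n_features,
         effect_sizes = effect_sizes, correlation = correlation,
         molecular_rates = molecular_rates, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Simulate a labelled feature cohort
#'
#' Draws class-conditional multivariate normal feature vectors with the
#' spec's effect sizes and correlation structure.  Feature columns follow
#' the standard QUS naming convention ([qus_feature_names()]) when
#' `n_features` is 49, otherwise `F1 ... Fk`.  Class 1 has its mean shifted
#' by the effect sizes (unit within-class SD, so the shifts are Cohen's d).
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with feature columns, `ER`, `PR`, `HER2`, and a
#'   binary `class` column (1 first); attribute `cohort_spec` records the
#'   generator settings.
#' @examples
#' tab <- simulate_cohort(cohort_spec(n_per_class = c(83, 17)))
#' nrow(tab)   # 100
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(derive_seed(spec$seed, "cohort"))
  p <- spec$n_features
  Sigma <- if (is.matrix(spec$correlation)) spec$correlation else
    (1 - spec$correlation) * diag(p) + spec$correlation
  n1 <- spec$n_per_class[1]; n0 <- spec$n_per_class[2]
  X1 <- MASS::mvrnorm(n1, mu = spec$effect_sizes, Sigma = Sigma)
  X0 <- MASS::mvrnorm(n0, mu = rep(0, p), Sigma = Sigma)
  X <- rbind(X1, X0)
  colnames(X) <- if (p == 49) qus_feature_names() else paste0("F", seq_len(p))
  mol <- rbind(
    vapply(spec$molecular_rates[1, ], function(r) rbinom(n1, 1, r), integer(n1)),
    vapply(spec$molecular_rates[2, ], function(r) rbinom(n0, 1, r), integer(n0)))
  colnames(mol) <- c("ER", "PR", "HER2")
  out <- data.frame(X, mol, class = rep(c(1L, 0L), c(n1, n0)), check.names = FALSE)
  attr(out, "cohort_spec") <- spec
  out
}

#' Label structure of the reference clinical cohort
#'
#' The modified-response (MR) score groups patients as responder
#' (R, MR 3-5) versus non-responder (NR2, MR 1-2) in the binary scheme, and
#' complete responder (CR, MR 4-5), partial responder (PR, MR 2-3) and
#' non-responder (NR3, MR 1) in the three-class scheme.  This helper
#' returns the printed class counts of the 100-patient study cohort —
#' 83 R / 17 NR2, 45 CR / 47 PR / 8 NR3, 86 five-year recurrence-free
#' survivors / 14 recurrences — as label vectors, for balanced-set
#' arithmetic and synthetic studies that mirror the clinical class
#' imbalance.
#'
#' @return list with `mr_score` (length 100, scores 1-5; the split of MR 4
#'   versus 5 inside CR is arbitrary) and `survival_5yr` (length 100,
#'   binary).
#' @export
study_labels <- function() {
  mr <- rep(c(1L, 2L, 3L, 4L, 5L), c(8L, 9L, 38L, 22L, 23L))
  list(mr_score = mr, survival_5yr = rep(c(1L, 0L), c(86L, 14L)))
}
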
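#' Univariate feature ranking between outcome groups
#'
#' For every feature, the two classes are compared with an unpaired
#' two-sided test and the features are ranked by ascending p-value.  The
#' test is chosen per feature by a normality screen: if both classes pass
#' Shapiro-Wilk at `alpha_normality`, the equal-variance two-sample t-test
#' is used, otherwise the Mann-Whitney rank-sum test (exact when sample
#' sizes permit and there are no ties, with the normal tie-corrected
#' approximation otherwise).  Raw p-values are reported — ranking drives
#' feature-selection initialisation, not inference — with Bonferroni
#' adjustment available as a reporting column.
#'
#' Ties in p-value are broken by the larger absolute standardised mean
#' difference, then by name, so the ranking is deterministic.  A feature
#' constant in both classes gets p = 1 and ranks last.
#'
#' @param table data.frame or matrix of numeric features.
#' @param labels binary 0/1 class labels (rows with `NA` dropped).
#' @param alpha_normality Shapiro-Wilk screen level.
#' @param bonferroni append a Bonferroni-adjusted p-value column.
#' @return data.frame of class `ranked_features`, sorted by rank, with
#'   columns `feature`, `p_value`, `test_used`, `smd`, `rank`.
#' @export
univariate_rank <- function(table, labels, alpha_normality = 0.05,
                            bonferroni = FALSE) {
  X <- as.data.frame(table)
  ok <- !is.na(labels)
  X <- X[ok, , drop = FALSE]; y <- as.integer(labels[ok])
  assert_that(sum(y == 1) >= 2 && sum(y == 0) >= 2, "need >= 2 samples per class")
  res <- lapply(names(X), function(nm) {
    a <- X[[nm]][y == 1]; b <- X[[nm]][y == 0]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(feature = nm, p_value = 1, test_used = "none", smd = 0))
    sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
    smd <- if (sp > 0) abs(mean(a) - mean(b)) / sp else 0
    if (sd1(a) == 0 && sd1(b) == 0)
      return(data.frame(feature = nm, p_value = 1, test_used = "none", smd = 0))
    normal <- function(v) {
      if (length(v) < 3 || length(v) > 5000 || sd1(v) == 0) return(FALSE)
      shapiro.test(v)$p.value >= alpha_normality
    }
    if (normal(a) && normal(b)) {
      p <- t.test(a, b, var.equal = TRUE)$p.value
      test <- "t"
    } else {
      p <- suppressWarnings(wilcox.test(a, b)$p.value)
      test <- "mann_whitney"
    }
    data.frame(feature = nm, p_value = p, test_used = test, smd = smd)
  })
  out <- do.call(rbind, res)
  ord <- order(out$p_value, -out$smd, out$feature)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (bonferroni) out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ranked_features", "data.frame")
  out
}
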
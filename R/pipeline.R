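#' Full response-classification pipeline on a feature cohort
#'
#' The package's headline evaluation: the cohort is down-sampled into
#' class-balanced sets covering the majority class; within each balanced
#' set, features are ranked by univariate p-value, a subset of at most
#' `max_features` is chosen by sequential floating forward selection, and
#' the configured classifier is trained and tested on `n_boot` stratified
#' 70/15/15 re-splits; set-level metrics are aggregated into mean and SD
#' across sets.
#'
#' All randomness derives from `seed`, so two runs with the same seed
#' produce byte-identical reports.
#'
#' @param table data.frame of candidate features (numeric columns only).
#' @param labels binary 0/1 labels aligned to `table` rows (`NA` rows are
#'   excluded by the balancing step).
#' @param model `"ann"` or `"knn"`.
#' @param seed master seed.
#' @param scheme scheme name recorded in the report.
#' @param max_features subset-size cap of the selection step.
#' @param n_boot re-splits per balanced set.
#' @param max_sets optional cap on the number of balanced sets evaluated
#'   (all generated sets are used by default).
#' @param select run feature selection per set (if `FALSE`, all columns
#'   are used).
#' @param ... further arguments to [train_eval_ann()] / [train_eval_knn()].
#' @return an [compile_report()] `eval_report`; per-set detail includes the
#'   chosen features (comma-separated).
#' @export
evaluate_scheme <- function(table, labels, model = c("ann", "knn"), seed = 1L,
                            scheme = "R_vs_NR2", max_features = 5L,
                            n_boot = 10L, max_sets = Inf, select = TRUE, ...) {
  model <- match.arg(model)
  X <- as.data.frame(table)
  sets <- make_balanced_sets(labels, seed = seed)
  use <- seq_len(min(length(sets), max_sets))
  rows <- vector("list", length(use))
  for (si in use) {
    bs <- sets[[si]]
    Xs <- X[bs$indices, , drop = FALSE]
    ys <- as.integer(labels[bs$indices])
    feats <- colnames(Xs)
    crit <- NA_real_
    if (select && ncol(Xs) > max_features) {
      ranked <- univariate_rank(Xs, ys)
      sel <- sffs_select(Xs, ys, ranked = ranked, max_k = max_features,
                         seed = derive_seed(seed, "select", si),
                         classifier = model)
      feats <- sel$chosen_features
      crit <- sel$criterion
    }
    ev <- if (model == "ann")
      train_eval_ann(Xs, ys, feats, seed = derive_seed(seed, "eval", si),
                     n_boot = n_boot, ...)
    else
      train_eval_knn(Xs, ys, feats, seed = derive_seed(seed, "eval", si),
                     n_boot = n_boot, ...)
    rows[[si]] <- data.frame(set_id = bs$set_id, t(ev$metrics),
                             selection_criterion = crit,
                             features = paste(feats, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  per_set <- do.call(rbind, rows)
  compile_report(per_set, scheme = scheme, model = model,
                 config = list(seed = seed, max_features = max_features,
                               n_boot = n_boot, n_sets_generated = length(sets),
                               set_size = attr(sets, "set_size"),
                               select = select, model = model))
}
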
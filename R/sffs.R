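#' Deterministic subset criterion used by the floating search
#'
#' Validation AUC of the configured classifier on `n_inner` stratified
#' 70/15/15 splits whose randomness (and the classifier's weight
#' initialisation) derives entirely from `seed`, so the value is a
#' deterministic function of the feature subset.  Exposed so that
#' alternative search strategies can be scored against [sffs_select()] on
#' identical footing.
#'
#' @param table data.frame or matrix of features.
#' @param labels binary 0/1 labels.
#' @param features character vector naming the subset (empty gives 0.5).
#' @param seed integer seed fixing splits and initialisation.
#' @param classifier `"ann"` or `"knn"`.
#' @param n_inner number of inner splits averaged.
#' @param ann_size hidden size of the criterion network.
#' @param knn_k neighbour count of the knn criterion.
#' @return mean validation AUC.
#' @export
selection_criterion <- function(table, labels, features, seed = 1L,
                                classifier = c("ann", "knn"), n_inner = 3L,
                                ann_size = 3L, knn_k = 5L) {
  classifier <- match.arg(classifier)
  if (!length(features)) return(0.5)
  Xs <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  y <- as.integer(labels)
  aucs <- vapply(seq_len(n_inner), function(i) {
    set.seed(derive_seed(seed, "sffs-split", i))
    part <- stratified_split(y)
    st <- standardize_by_train(Xs, part)
    set.seed(derive_seed(seed, "sffs-fit", i))
    sc <- if (classifier == "ann") {
      fit <- fit_ann(st$Z[part == 1, , drop = FALSE], y[part == 1], ann_size)
      predict_ann(fit, st$Z[part == 2, , drop = FALSE])
    } else {
      predict_knn(st$Z[part == 1, , drop = FALSE], y[part == 1],
                  st$Z[part == 2, , drop = FALSE],
                  min(knn_k, sum(part == 1)))
    }
    auc_trapezoid(sc, y[part == 2])
  }, 0)
  mean(aucs)
}

#' Sequential floating forward selection with p-value initialisation
#'
#' Starts from the top-ranked feature of the univariate screen, then
#' alternates forward steps (add the candidate that maximises the
#' criterion) with conditional backward steps (drop an included feature
#' when the reduced subset beats the best subset of that size seen so far
#' — the "floating" rule, with the just-added feature protected so the
#' search cannot cycle).  The subset size is capped at `max_k` to avoid
#' overfitting small balanced cohorts.  The criterion is the validation
#' AUC of the configured classifier under the module's stratified 70/15/15
#' protocol, averaged over `n_inner` fixed inner splits; the inner splits
#' and classifier initialisation derive from `seed`, so the criterion is a
#' deterministic function of the subset and the search is reproducible.
#'
#' @param table data.frame of candidate features.
#' @param labels binary 0/1 labels.
#' @param ranked optional [univariate_rank()] result (computed if `NULL`).
#' @param max_k maximum subset size.
#' @param seed integer seed fixing the inner criterion.
#' @param classifier `"ann"` (default) or `"knn"` criterion model.
#' @param n_inner inner splits averaged per criterion evaluation.
#' @param ann_size hidden size of the criterion network.
#' @param knn_k neighbour count of the knn criterion.
#' @return object of class `selection_result`: `chosen_features` (best
#'   subset found, <= `max_k`), `criterion` (its AUC), and a step `trace`.
#' @export
sffs_select <- function(table, labels, ranked = NULL, max_k = 5L, seed = 1L,
                        classifier = c("ann", "knn"), n_inner = 3L,
                        ann_size = 3L, knn_k = 5L) {
  classifier <- match.arg(classifier)
  X <- as.data.frame(table)
  y <- as.integer(labels)
  assert_that(ncol(X) >= 2, "need at least two candidate features")
  if (is.null(ranked)) ranked <- univariate_rank(X, y)

  Xm <- as.matrix(X)
  crit_eval <- function(sub)
    selection_criterion(Xm, y, sub, seed = seed, classifier = classifier,
                        n_inner = n_inner, ann_size = ann_size, knn_k = knn_k)
  memo <- new.env(parent = emptyenv())
  C <- function(sub) {
    key <- paste(sort(sub), collapse = "\r")
    v <- memo[[key]]
    if (is.null(v)) { v <- crit_eval(sub); memo[[key]] <- v }
    v
  }

  S <- ranked$feature[1]
  best <- list(list(S = S, v = C(S)))        # best subset per size
  trace <- data.frame(action = "init", feature = S, size = 1L,
                      criterion = best[[1]]$v, stringsAsFactors = FALSE)
  all_feats <- colnames(X)
  repeat {
    cand <- setdiff(all_feats, S)
    if (!length(cand) || length(S) >= max_k) break
    vals <- vapply(cand, function(cc) C(c(S, cc)), 0)
    added <- cand[which.max(vals)]
    S <- c(S, added)
    k <- length(S)
    if (length(best) < k || C(S) > best[[k]]$v) best[[k]] <- list(S = S, v = C(S))
    trace <- rbind(trace, data.frame(action = "add", feature = added,
                                     size = k, criterion = C(S)))
    repeat {                                  # conditional (floating) removal
      k <- length(S)
      if (k <= 2) break
      rv <- vapply(S, function(ff) C(setdiff(S, ff)), 0)
      worst <- S[which.max(rv)]
      if (identical(worst, added)) break
      if (max(rv) > best[[k - 1]]$v + 1e-12) {
        S <- setdiff(S, worst)
        best[[k - 1]] <- list(S = S, v = C(S))
        trace <- rbind(trace, data.frame(action = "remove", feature = worst,
                                         size = k - 1L, criterion = C(S)))
      } else break
    }
  }
  vb <- which.max(vapply(best, function(b) b$v, 0))
  structure(
    list(chosen_features = best[[vb]]$S,
         criterion = best[[vb]]$v,
         trace = trace,
         classifier = classifier, seed = seed, max_k = max_k),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s criterion %.3f: %s\n",
              x$classifier, x$criterion, paste(x$chosen_features, collapse = ", ")))
  invisible(x)
}
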
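# Classifier protocol shared by selection and evaluation:
# stratified 70/15/15 split, training-split standardisation, shallow models.

#' Stratified train/validation/test split
#'
#' Splits samples into 70/15/15 parts stratified by class, guaranteeing at
#' least one sample of each class in every part (a direct construction of
#' the verification-and-resample rule: stratification satisfies the check
#' constructively; if rounding ever leaves a part without a class the split
#' is redrawn).
#'
#' @param labels binary class labels.
#' @param proportions length-3 fractions summing to 1.
#' @return integer vector: 1 = train, 2 = validation, 3 = test.
#' @export
stratified_split <- function(labels, proportions = c(0.70, 0.15, 0.15)) {
  n <- length(labels)
  for (attempt in 1:20) {
    part <- integer(n)
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      k <- length(idx)
      n1 <- max(1L, round(proportions[1] * k))
      n2 <- max(1L, round(proportions[2] * k))
      n1 <- min(n1, k - 2L)
      n3 <- k - n1 - n2
      if (n3 < 1L) { n2 <- n2 - 1L; n3 <- 1L }
      part[idx] <- rep(1:3, c(n1, n2, n3))
    }
    ok <- all(vapply(1:3, function(p)
      length(unique(labels[part == p])) == length(unique(labels)), TRUE))
    if (ok) return(part)
  }
  stop("could not produce a stratified split with all classes present", call. = FALSE)
}

# Standardise by training-part statistics only (anti-leakage).
standardize_by_train <- function(X, part) {
  mu <- colMeans(X[part == 1, , drop = FALSE])
  s <- apply(X[part == 1, , drop = FALSE], 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  list(Z = sweep(sweep(X, 2, mu), 2, s, "/"), mu = mu, sd = s)
}

fit_ann <- function(Ztr, ytr, size, decay = 0.01, maxit = 200) {
  nnet::nnet(Ztr, ytr, size = size, decay = decay, maxit = maxit,
             trace = FALSE, entropy = TRUE)
}
predict_ann <- function(fit, Z) as.numeric(predict(fit, Z))

# KNN "model" is the training data; score = class-1 neighbour vote fraction.
predict_knn <- function(Ztr, ytr, Z, k) {
  pr <- class::knn(Ztr, Z, factor(ytr, levels = c(0, 1)), k = k, prob = TRUE)
  win <- attr(pr, "prob")
  ifelse(pr == "1", win, 1 - win)
}

set_metrics <- function(scores, truth, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  c(sensitivity = 100 * mean(pred[truth == 1] == 1),
    specificity = 100 * mean(pred[truth == 0] == 0),
    accuracy = 100 * mean(pred == truth),
    auc = auc_trapezoid(scores, truth))
}

#' Train and evaluate the shallow neural-network classifier
#'
#' On a (balanced) cohort: features are standardised by the training-split
#' mean and SD; a single-hidden-layer network (sigmoidal hidden units,
#' logistic output, cross-entropy loss, BFGS optimisation with weight-decay
#' regularisation) is tuned over hidden sizes 1-10 by validation AUC on a
#' stratified 70/15/15 split; test-set sensitivity, specificity, accuracy
#' and AUC are recorded.  The whole procedure is repeated over `n_boot`
#' independent stratified re-splits and the metrics averaged, absorbing the
#' split-to-split variability of small cohorts.
#'
#' @param table data.frame of features.
#' @param labels binary 0/1 labels.
#' @param features character vector of feature columns to use.
#' @param seed integer seed (drives splits and weight initialisation).
#' @param n_boot number of random train/validate/test re-splits.
#' @param sizes hidden-layer sizes tuned over.
#' @param decay,maxit nnet weight decay and iteration cap.
#' @return list with `per_boot` (one row of metrics per re-split),
#'   `metrics` (their mean), and `chosen_sizes`.
#' @export
train_eval_ann <- function(table, labels, features, seed = 1L, n_boot = 10L,
                           sizes = 1:10, decay = 0.01, maxit = 200L) {
  X <- as.matrix(table[, features, drop = FALSE])
  check_finite_features(X, features)
  y <- as.integer(labels)
  per <- matrix(NA_real_, n_boot, 4,
                dimnames = list(NULL, c("sensitivity", "specificity", "accuracy", "auc")))
  chosen <- integer(n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, "ann", b))
    part <- stratified_split(y)
    st <- standardize_by_train(X, part)
    best <- NULL; best_auc <- -Inf; best_size <- NA_integer_
    for (s in sizes) {
      fit <- fit_ann(st$Z[part == 1, , drop = FALSE], y[part == 1], s,
                     decay = decay, maxit = maxit)
      a <- auc_trapezoid(predict_ann(fit, st$Z[part == 2, , drop = FALSE]), y[part == 2])
      if (is.finite(a) && a > best_auc) { best_auc <- a; best <- fit; best_size <- s }
    }
    sc <- predict_ann(best, st$Z[part == 3, , drop = FALSE])
    per[b, ] <- set_metrics(sc, y[part == 3])
    chosen[b] <- best_size
  }
  list(per_boot = as.data.frame(per), metrics = colMeans(per), chosen_sizes = chosen)
}

#' Train and evaluate the k-nearest-neighbour comparator
#'
#' Identical protocol to [train_eval_ann()] — standardisation by training
#' statistics, stratified 70/15/15 splits, `n_boot` repeats — with the
#' neighbour count tuned over `k_grid` by validation AUC.  Distances are
#' Euclidean on standardised features; the AUC score is the neighbour vote
#' fraction.
#'
#' @inheritParams train_eval_ann
#' @param k_grid odd neighbour counts tuned over.
#' @return list with `per_boot`, `metrics`, `chosen_k`.
#' @export
train_eval_knn <- function(table, labels, features, seed = 1L, n_boot = 10L,
                           k_grid = c(1, 3, 5, 7, 9)) {
  X <- as.matrix(table[, features, drop = FALSE])
  check_finite_features(X, features)
  y <- as.integer(labels)
  per <- matrix(NA_real_, n_boot, 4,
                dimnames = list(NULL, c("sensitivity", "specificity", "accuracy", "auc")))
  chosen <- integer(n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, "knn", b))
    part <- stratified_split(y)
    st <- standardize_by_train(X, part)
    Ztr <- st$Z[part == 1, , drop = FALSE]; ytr <- y[part == 1]
    k_grid_b <- k_grid[k_grid <= length(ytr)]
    aucs <- vapply(k_grid_b, function(k)
      auc_trapezoid(predict_knn(Ztr, ytr, st$Z[part == 2, , drop = FALSE], k), y[part == 2]), 0)
    kbest <- k_grid_b[which.max(aucs)]
    sc <- predict_knn(Ztr, ytr, st$Z[part == 3, , drop = FALSE], kbest)
    per[b, ] <- set_metrics(sc, y[part == 3])
    chosen[b] <- kbest
  }
  list(per_boot = as.data.frame(per), metrics = colMeans(per), chosen_k = chosen)
}

check_finite_features <- function(X, features) {
  bad <- features[!vapply(seq_len(ncol(X)), function(j) all(is.finite(X[, j])), TRUE)]
  assert_that(length(bad) == 0,
              paste("non-finite values in feature(s):", paste(bad, collapse = ", ")))
}
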
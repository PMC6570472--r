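test_that("grouping schemes map MR scores per the clinical definitions", {
  mr <- c(1, 2, 3, 4, 5)
  expect_equal(response_labels(mr, "R_vs_NR2"), c(0L, 0L, 1L, 1L, 1L))
  expect_equal(response_labels(mr, "CR_vs_PRNR3"), c(0L, 0L, 0L, 1L, 1L))
  expect_equal(response_labels(mr, "CRPR_vs_NR3"), c(0L, 1L, 1L, 1L, 1L))
  expect_equal(response_labels(mr, "PR_vs_NR3"), c(0L, 1L, 1L, NA, NA))
  expect_equal(response_labels(scheme = "survival", survival = c(1, 0)), c(1L, 0L))

  lab <- study_labels()
  expect_equal(table(response_labels(lab$mr_score, "R_vs_NR2")),
               table(factor(rep(c(0, 1), c(17, 83)))), ignore_attr = TRUE)
})

test_that("balanced sets have exact size and cover the majority class", {
  y <- rep(c(1L, 0L), c(83L, 17L))
  sets <- make_balanced_sets(y, seed = 4)
  expect_equal(attr(sets, "set_size"), 34L)
  expect_equal(attr(sets, "majority_coverage"), 1)
  for (s in sets) {
    expect_length(s$indices, 34)
    expect_equal(sum(y[s$indices] == 0), 17)
    expect_equal(sum(y[s$indices] == 1), 17)
    expect_equal(anyDuplicated(s$indices), 0)
  }
  expect_true(all(which(y == 0) %in% sets[[1]]$indices))  # minority always in
  cov <- sort(unique(unlist(lapply(sets, function(s) s$indices[y[s$indices] == 1]))))
  expect_equal(cov, which(y == 1))

  # equal classes: a single set containing everyone
  ye <- rep(c(0L, 1L), each = 10)
  se <- make_balanced_sets(ye, seed = 1)
  expect_length(se, 1)
  expect_equal(sort(se[[1]]$indices), 1:20)
})

test_that("set counts match a direct simulation of the coverage procedure", {
  # oracle: draw minority-size samples from the majority until all seen
  oracle_counts <- function(n_maj, m, reps, seed) {
    set.seed(seed)
    vapply(seq_len(reps), function(i) {
      seen <- logical(n_maj); k <- 0L
      while (!all(seen)) { seen[sample(n_maj, m)] <- TRUE; k <- k + 1L }
      k
    }, 0L)
  }
  want <- mean(oracle_counts(4, 2, 4000, seed = 99))
  got <- mean(vapply(1:2000, function(s)
    length(make_balanced_sets(rep(c(1, 0), c(4, 2)), seed = s)), 0L))
  expect_lt(abs(got - want) / want, 0.05)
})

test_that("stratified splits always contain every class in every part", {
  set.seed(5)
  for (i in 1:50) {
    y <- rep(c(0L, 1L), c(8, 8))
    part <- stratified_split(y)
    for (p in 1:3) expect_setequal(unique(y[part == p]), c(0L, 1L))
    expect_equal(sum(part == 1), 12)
  }
})

test_that("standardisation uses training statistics only", {
  set.seed(6)
  X <- matrix(rnorm(60, 5, 2), 20, 3)
  part <- rep(c(1L, 2L, 3L), c(14, 3, 3))
  st <- standardize_by_train(X, part)
  expect_equal(st$mu, colMeans(X[part == 1, ]))
  expect_equal(unname(st$sd), unname(apply(X[part == 1, ], 2, sd)))
  # test rows never influence the transform
  X2 <- X; X2[part == 3, ] <- X2[part == 3, ] + 100
  st2 <- standardize_by_train(X2, part)
  expect_equal(st2$mu, st$mu)
  expect_equal(st2$sd, st$sd)
})

test_that("the ANN separates well-separated Gaussian classes", {
  co <- separated_cohort(n = 50, delta = 4, seed = 21)
  ev <- train_eval_ann(co$table, co$labels, paste0("SIG", 1:3), seed = 31)
  expect_gte(ev$metrics[["auc"]], 0.97)
  expect_true(all(ev$chosen_sizes %in% 1:10))
  expect_error(train_eval_ann(transform(co$table, SIG1 = NA), co$labels,
                              paste0("SIG", 1:3), seed = 1), "SIG1")
})

test_that("KNN votes match the hand example and track the ANN on easy tasks", {
  # 3-point example: query nearer two class-1 points with k = 3 -> vote 2/3
  Ztr <- matrix(c(0, 0.2, 5, 0, 0, 0), ncol = 2)
  sc <- predict_knn(Ztr, c(1L, 1L, 0L), matrix(c(0.1, 0), 1), k = 3)
  expect_equal(sc, 2 / 3)

  co <- separated_cohort(n = 30, delta = 4, seed = 22)
  ev_knn <- train_eval_knn(co$table, co$labels, paste0("SIG", 1:3), seed = 5,
                           n_boot = 10)
  ev_ann <- train_eval_ann(co$table, co$labels, paste0("SIG", 1:3), seed = 5,
                           n_boot = 10)
  expect_gte(ev_knn$metrics[["auc"]], 0.9)
  expect_gte(ev_ann$metrics[["auc"]], ev_knn$metrics[["auc"]] - 0.03)
})

test_that("selection finds a perfect separator and beats pure greedy forward", {
  set.seed(44)
  n <- 60
  tab <- data.frame(GOOD = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
                    N1 = rnorm(n), N2 = rnorm(n), N3 = rnorm(n),
                    N4 = rnorm(n), N5 = rnorm(n), N6 = rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  sel <- sffs_select(tab, y, seed = 3)
  expect_true("GOOD" %in% sel$chosen_features)
  expect_gte(sel$criterion, 0.95)

  # floating search never does worse than plain greedy forward selection
  # (oracle: greedy chain re-scored with the identical frozen criterion)
  co <- separated_cohort(n = 30, delta = 2, p_signal = 4, p_noise = 4, seed = 17)
  sel2 <- sffs_select(co$table, co$labels, max_k = 5, seed = 13)
  crit_of <- function(sub) selection_criterion(co$table, co$labels, sub, seed = 13)
  greedy_best <- local({
    S <- univariate_rank(co$table, co$labels)$feature[1]
    vals <- crit_of(S)
    while (length(S) < 5) {
      rem <- setdiff(colnames(co$table), S)
      sc <- vapply(rem, function(f) crit_of(c(S, f)), 0)
      S <- c(S, rem[which.max(sc)])
      vals <- c(vals, max(sc))
    }
    max(vals)
  })
  expect_gte(sel2$criterion, greedy_best - 1e-9)
})

test_that("floating selection recovers an interacting (XOR) feature pair", {
  co <- xor_cohort(seed = 11)
  ranked <- univariate_rank(co$table, co$labels)
  # neither XOR feature is marginally informative on its own
  expect_true(all(ranked$p_value[ranked$feature %in% c("XORA", "XORB")] > 0.01))
  sel <- sffs_select(co$table, co$labels, ranked = ranked, seed = 7)
  expect_true(all(c("XORA", "XORB") %in% sel$chosen_features))
  expect_gte(sel$criterion, 0.9)
})

test_that("report aggregation applies the printed metric definitions", {
  m <- confusion_metrics(tp = 8, fn = 1, tn = 7, fp = 2)
  expect_equal(unname(m), c(100 * 8 / 9, 100 * 7 / 9, 100 * 15 / 18),
               tolerance = 1e-10)

  one <- data.frame(sensitivity = 80, specificity = 70, accuracy = 75, auc = 0.8)
  rep1 <- compile_report(one)
  expect_true(all(rep1$aggregate$sd == 0))

  two <- data.frame(sensitivity = c(80, 90), specificity = c(70, 80),
                    accuracy = c(80, 90), auc = c(0.8, 0.9))
  rep2 <- compile_report(two)
  acc <- rep2$aggregate[rep2$aggregate$metric == "accuracy", ]
  expect_equal(acc$mean, 85)
  expect_equal(acc$sd, sd(c(80, 90)))   # n-1 convention, 7.071
})

test_that("AUC equals the hand-enumerated trapezoidal ROC area", {
  # n = 6 toy with one monotone feature: scores 1..6, labels 0,0,1,0,1,1
  sc <- 1:6; y <- c(0, 0, 1, 0, 1, 1)
  # hand TP/FP path: thresholds descending -> ROC points
  # (0,0) (1/3,0) (2/3,0) (2/3,1/3) (1,1/3) (1,2/3) (1,1): area = 8/9
  expect_equal(auc_trapezoid(sc, y), 8 / 9, tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(1)
    s2 <- rnorm(40); y2 <- rbinom(40, 1, 0.5)
    expect_equal(auc_trapezoid(s2, y2),
                 as.numeric(suppressMessages(pROC::auc(y2, s2, direction = "<"))),
                 tolerance = 1e-10)
  }
})
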
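#' Classification metrics from a confusion count
#'
#' Sensitivity is true positives over all positives in the test set,
#' specificity true negatives over all negatives, accuracy correct over
#' total, all in percent; AUC is the trapezoidal area under the ROC.
#'
#' @param tp,fn,tn,fp confusion counts.
#' @return named vector of sensitivity, specificity, accuracy (percent).
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  c(sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / (tp + fn + tn + fp))
}

#' Aggregate per-set metrics into an evaluation report
#'
#' Averages the per-balanced-set metrics (each itself a mean over bootstrap
#' re-splits) into mean and standard deviation per metric, using the
#' sample (n-1) SD convention across sets.
#'
#' @param per_set data.frame with one row per balanced set and columns
#'   `sensitivity`, `specificity`, `accuracy`, `auc` (plus anything else,
#'   carried through in `detail`).
#' @param scheme grouping scheme name.
#' @param model classifier name.
#' @param config list snapshot of the configuration used.
#' @return object of class `eval_report` with `aggregate` (mean and sd per
#'   metric), `per_set` detail, `n_sets`, `scheme`, `model`, `config`.
#' @export
compile_report <- function(per_set, scheme = "R_vs_NR2", model = "ann",
                           config = list()) {
  per_set <- as.data.frame(per_set)
  assert_that(nrow(per_set) >= 1, "need at least one evaluated balanced set")
  metrics <- c("sensitivity", "specificity", "accuracy", "auc")
  agg <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_set[[m]]), 0),
    sd = vapply(metrics, function(m) sd1(per_set[[m]]), 0),
    row.names = NULL)
  structure(
    list(scheme = scheme, model = model, n_sets = nrow(per_set),
         aggregate = agg, per_set = per_set, config = config),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s / %s over %d balanced set(s)\n",
              x$scheme, x$model, x$n_sets))
  a <- x$aggregate
  for (i in seq_len(nrow(a))) {
    if (a$metric[i] == "auc")
      cat(sprintf("  %-12s %.2f +/- %.2f\n", a$metric[i], a$mean[i], a$sd[i]))
    else
      cat(sprintf("  %-12s %.1f +/- %.1f %%\n", a$metric[i], a$mean[i], a$sd[i]))
  }
  invisible(x)
}

#' Serialise an evaluation report
#'
#' Writes the report as JSON (and optionally the per-set detail as CSV).
#' The serialisation contains no timestamps, so identical runs produce
#' byte-identical files.
#'
#' @param report an [compile_report()] result.
#' @param path JSON output path; `NULL` returns the JSON string.
#' @param csv optional CSV path for the per-set table.
#' @return the JSON string, invisibly when written to file.
#' @export
write_report <- function(report, path = NULL, csv = NULL) {
  stopifnot(inherits(report, "eval_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null")
  if (!is.null(csv)) utils::write.csv(report$per_set, csv, row.names = FALSE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
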
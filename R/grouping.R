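GROUPING_SCHEMES <- c("R_vs_NR2", "CR_vs_PRNR3", "CRPR_vs_NR3", "PR_vs_NR3", "survival")

#' Map clinical labels to a binary classification scheme
#'
#' The binary schemes derived from the modified-response score are:
#' `R_vs_NR2` (responder MR 3-5 = 1, non-responder MR 1-2 = 0),
#' `CR_vs_PRNR3` (complete responder MR 4-5 = 1 versus MR 1-3 = 0),
#' `CRPR_vs_NR3` (any response MR 2-5 = 1 versus MR 1 = 0), and
#' `PR_vs_NR3` (partial responder MR 2-3 = 1 versus MR 1 = 0, all other
#' patients dropped as `NA`).  `survival` passes the five-year
#' recurrence-free indicator through (survivor = 1).
#'
#' @param mr_score integer vector of MR scores 1-5 (ignored for
#'   `"survival"`).
#' @param scheme scheme name.
#' @param survival binary five-year recurrence-free survival indicator
#'   (required for `"survival"`).
#' @return integer vector of 0/1 labels (with `NA` for patients excluded
#'   by the scheme).
#' @export
response_labels <- function(mr_score = NULL, scheme = GROUPING_SCHEMES,
                            survival = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "survival") {
    assert_that(!is.null(survival), "survival labels required for the survival scheme")
    return(as.integer(survival))
  }
  assert_that(all(mr_score %in% 1:5), "mr_score values must lie in 1..5")
  switch(scheme,
    R_vs_NR2    = as.integer(mr_score >= 3),
    CR_vs_PRNR3 = as.integer(mr_score >= 4),
    CRPR_vs_NR3 = as.integer(mr_score >= 2),
    PR_vs_NR3   = ifelse(mr_score == 1, 0L,
                         ifelse(mr_score %in% c(2L, 3L), 1L, NA_integer_)))
}
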
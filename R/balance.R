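#' Down-sample the majority class into balanced sets
#'
#' Class imbalance is corrected by repeated random down-sampling: each
#' balanced set contains the full minority class plus an equally sized
#' uniform random draw from the majority class (without replacement within
#' a set; patients may reappear across sets).  Sets are generated until
#' every majority-class patient has appeared at least once, so the number
#' of sets is itself random — only the set size (twice the minority count)
#' is deterministic.
#'
#' @param labels binary 0/1 vector (`NA`s excluded).
#' @param seed integer seed for the draws.
#' @param max_sets safety cap on the number of sets.
#' @return list of `balanced_set` objects (`indices` into `labels`,
#'   `set_id`, `seed`), with attributes `set_size`, `n_sets`,
#'   `majority_coverage` (fraction of majority patients sampled, always 1).
#' @examples
#' sets <- make_balanced_sets(rep(c(1, 0), c(83, 17)), seed = 7)
#' attr(sets, "set_size")   # 34
#' @export
make_balanced_sets <- function(labels, seed = 1L, max_sets = 1000L) {
  idx <- which(!is.na(labels))
  y <- labels[idx]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  assert_that(n1 > 0 && n0 > 0, "both classes must be non-empty")
  if (n0 > n1) { maj <- idx[y == 0]; mino <- idx[y == 1] }
  else         { maj <- idx[y == 1]; mino <- idx[y == 0] }
  m <- length(mino)
  if (length(maj) < m) {
    warning("minority class larger than majority; classes swapped")
    tmp <- maj; maj <- mino; mino <- tmp; m <- length(mino)
  }
  set.seed(derive_seed(seed, "balance"))
  sets <- list()
  seen <- logical(length(maj))
  repeat {
    draw <- sample(seq_along(maj), m)
    seen[draw] <- TRUE
    sets[[length(sets) + 1]] <- structure(
      list(indices = sort(c(mino, maj[draw])),
           set_id = length(sets) + 1L, seed = seed),
      class = "balanced_set")
    if (all(seen) || length(sets) >= max_sets) break
  }
  structure(sets,
            set_size = 2L * m,
            n_sets = length(sets),
            majority_coverage = mean(seen))
}
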
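# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' All randomness in the package flows from one integer master seed.  Child
#' streams (scatterer placement, electronic noise, balanced-set draws,
#' bootstrap splits, ...) are derived by hashing the master seed together
#' with a stream label, so each operation is reproducible in isolation and
#' independent streams do not collide.  The result is always a positive
#' integer below 2^31.
#'
#' @param seed integer master seed.
#' @param ... integers or short strings identifying the stream.
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    h <- (h * 48271 + as.double(p) + 1) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Trapezoidal area under the ROC curve
#'
#' Computed from the rank statistic, which equals the trapezoidal area under
#' the empirical ROC curve with ties counted half (the Mann-Whitney
#' identity).
#'
#' @param scores numeric classifier scores, larger = more positive.
#' @param labels binary 0/1 vector, 1 = positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Hann taper of length n (periodic-symmetric form used for periodograms).
hann_taper <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

# Per-column analytic-signal envelope via the FFT method.
analytic_envelope <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- mvfft(x)
  abs(mvfft(X * h, inverse = TRUE) / n)
}

# Sample standard deviation (n - 1); returns 0 for length-1 input.
sd1 <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(0)
  stats::sd(x)
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
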
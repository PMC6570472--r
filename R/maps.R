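#' Assemble a parametric map from per-window estimates
#'
#' Places one estimate per window at its (row, col) position on the sliding
#' window grid; the map resolution is the window step.  Cells without a
#' window (outside the ROI) are `NA` and are excluded from every downstream
#' statistic.
#'
#' @param window_estimates numeric vector, one estimate per grid row.
#' @param grid a [tile_windows()] result.
#' @param parameter parameter name (e.g. `"MBF"`).
#' @param roi_label `"core"` or `"margin"`.
#' @return an object of class `parametric_map` wrapping a numeric matrix.
#' @export
build_map <- function(window_estimates, grid, parameter = "MBF",
                      roi_label = attr(grid, "roi_label")) {
  stopifnot(length(window_estimates) == nrow(grid))
  nr <- max(grid$row, 0); nc <- max(grid$col, 0)
  m <- matrix(NA_real_, nr, nc)
  if (nrow(grid)) m[cbind(grid$row, grid$col)] <- window_estimates
  structure(list(values = m, parameter = parameter, roi_label = roi_label),
            class = "parametric_map")
}

map_values <- function(map) {
  if (inherits(map, "parametric_map")) map$values else as.matrix(map)
}

#' GLCM texture features of a parametric map
#'
#' Quantises present (non-`NA`) cells to `levels` equal-width bins over the
#' map's own minimum-maximum, counts symmetric co-occurrences at distance 1
#' for the four offsets 0, 45, 90 and 135 degrees (pairs touching an absent
#' cell are skipped), normalises each matrix to probabilities, computes the
#' Haralick features
#' contrast `CON = sum p(i,j) (i-j)^2`,
#' correlation `COR = sum (i-mu_i)(j-mu_j) p(i,j) / (sigma_i sigma_j)`,
#' energy `ENE = sum p^2` and
#' homogeneity `HOM = sum p / (1 + |i-j|)`,
#' and averages the four offsets.  Quantising over the map's own range
#' makes the features invariant to affine rescaling of the map values.
#'
#' A constant map has a single occupied bin: `CON = 0`, `ENE = 1`,
#' `HOM = 1`, and `COR` is defined as 0 (zero-variance convention, keeping
#' the feature bounded instead of propagating `NaN`).
#'
#' @param map a `parametric_map` or plain numeric matrix (may contain `NA`).
#' @param levels number of grey levels.
#' @return list with `con`, `cor`, `ene`, `hom`; `NULL` if fewer than 4
#'   present cells.
#' @export
glcm_features <- function(map, levels = 16L) {
  v <- map_values(map)
  present <- is.finite(v)
  if (sum(present) < 4) return(NULL)
  rng <- range(v[present])
  q <- matrix(NA_integer_, nrow(v), ncol(v))
  if (rng[2] > rng[1]) {
    q[present] <- pmin(levels, 1L + as.integer(floor(
      (v[present] - rng[1]) / (rng[2] - rng[1]) * levels)))
  } else {
    q[present] <- 1L
  }
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))  # 0,45,90,135 deg
  feats <- vapply(offsets, function(off) glcm_one(q, off, levels), numeric(4))
  out <- rowMeans(feats)
  list(con = out[1], cor = out[2], ene = out[3], hom = out[4])
}

# Haralick features for one symmetric offset of a quantised (NA-skipping) map.
glcm_one <- function(q, off, levels) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1, 1 - off[1]):min(nr, nr - off[1])
  c1 <- max(1, 1 - off[2]):min(nc, nc - off[2])
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(c(0, 0, 1, 1))
  i <- c(a[ok], b[ok]); j <- c(b[ok], a[ok])   # symmetric counting
  p <- matrix(0, levels, levels)
  tab <- table(factor(i, levels = 1:levels), factor(j, levels = 1:levels))
  p[] <- tab / sum(tab)
  idx_i <- row(p); idx_j <- col(p)
  con <- sum(p * (idx_i - idx_j)^2)
  mu_i <- sum(idx_i * p); mu_j <- sum(idx_j * p)
  s_i <- sqrt(sum((idx_i - mu_i)^2 * p)); s_j <- sqrt(sum((idx_j - mu_j)^2 * p))
  cor <- if (s_i > 0 && s_j > 0) sum((idx_i - mu_i) * (idx_j - mu_j) * p) / (s_i * s_j) else 0
  ene <- sum(p^2)
  hom <- sum(p / (1 + abs(idx_i - idx_j)))
  c(con, cor, ene, hom)
}

#' Core-to-margin contrast features
#'
#' The core-to-margin ratio is the ratio of map means,
#' `CMR = mean(core) / mean(margin)`.  The core-to-margin contrast ratio is
#' a contrast-to-noise-style measure,
#' `CMCR = |mean(core) - mean(margin)| / (sd(core) + sd(margin))`,
#' with the denominator floored at machine epsilon and the result capped so
#' that degenerate constant maps stay finite.  Statistics run over present
#' cells only.
#'
#' @param core_map,margin_map `parametric_map`s (or matrices) of the same
#'   parameter over the two ROIs.
#' @param cap upper cap applied to CMCR (and |CMR|).
#' @return list with `cmr` (`NA` if the margin mean is 0) and `cmcr`.
#' @export
cmr_cmcr <- function(core_map, margin_map, cap = 1e6) {
  cv <- map_values(core_map); mv <- map_values(margin_map)
  cv <- cv[is.finite(cv)]; mv <- mv[is.finite(mv)]
  assert_that(length(cv) > 0 && length(mv) > 0, "both maps must have present cells")
  mc <- mean(cv); mm <- mean(mv)
  cmr <- if (mm == 0) NA_real_ else max(min(mc / mm, cap), -cap)
  denom <- max(sd1(cv) + sd1(mv), .Machine$double.eps)
  cmcr <- min(abs(mc - mm) / denom, cap)
  list(cmr = cmr, cmcr = cmcr)
}
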
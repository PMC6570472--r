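#' Tile sliding analysis windows over an ROI
#'
#' Lays a regular grid of 2 x 2 mm RF windows (by default) over the
#' bounding box of an ROI mask, with 94% overlap in both directions, and
#' keeps windows whose footprint is at least `min_inside` inside the mask.
#' At the default geometry (40 MHz sampling, 1540 m/s, 0.2 mm pitch) the
#' axial window length is `round(2 mm * 2 * fs / c) = 104` samples and the
#' step is `max(1, round(0.06 * length)) = 6` samples.
#'
#' @param roi a [build_rois()] result.
#' @param frame the [rf_frame()] the ROI belongs to.
#' @param roi_label which mask to tile: `"core"` or `"margin"`.
#' @param window_mm axial x lateral window size in mm.
#' @param overlap overlap fraction in each axis, in `[0, 1)`.
#' @param min_inside minimum fraction of the window footprint that must lie
#'   inside the mask.
#' @return an object of class `window_grid`: a data.frame of window spans
#'   (`a0`, `a1` axial samples; `l0`, `l1` lines; `row`, `col` grid indices;
#'   `depth_cm` centre depth) with geometry attributes.  Empty (with a
#'   warning) if the ROI cannot hold one window.
#' @export
tile_windows <- function(roi, frame, roi_label = c("core", "margin"),
                         window_mm = c(2, 2), overlap = 0.94,
                         min_inside = 0.9) {
  stopifnot(inherits(roi, "roi_set"), inherits(frame, "rf_frame"))
  roi_label <- match.arg(roi_label)
  mask <- if (roi_label == "core") roi$core_mask else roi$margin_mask
  fs <- frame$fs; c0 <- frame$sound_speed
  len_a <- round(window_mm[1] * 1e-3 * 2 * fs / c0)
  len_l <- max(1L, round(window_mm[2] * 1e-3 / frame$line_pitch))
  step_a <- max(1L, round((1 - overlap) * len_a))
  step_l <- max(1L, round((1 - overlap) * len_l))

  empty <- function() {
    g <- data.frame(a0 = integer(), a1 = integer(), l0 = integer(), l1 = integer(),
                    row = integer(), col = integer(), depth_cm = numeric())
    structure(g, class = c("window_grid", "data.frame"),
              len_a = len_a, len_l = len_l, step_a = step_a, step_l = step_l,
              roi_label = roi_label)
  }
  if (!any(mask)) { warning("ROI mask is empty; no windows"); return(empty()) }
  ridx <- range(which(rowSums(mask) > 0))
  cidx <- range(which(colSums(mask) > 0))
  if (diff(ridx) + 1 < len_a || diff(cidx) + 1 < len_l) {
    warning("ROI smaller than one analysis window; no windows")
    return(empty())
  }
  a_starts <- seq(ridx[1], ridx[2] - len_a + 1, by = step_a)
  l_starts <- seq(cidx[1], cidx[2] - len_l + 1, by = step_l)
  cum <- apply(mask, 2, cumsum)           # column-wise cumulative counts
  inside_count <- function(a0, l0) {
    cols <- l0:(l0 + len_l - 1)
    hi <- cum[a0 + len_a - 1, cols]
    lo <- if (a0 > 1) cum[a0 - 1, cols] else 0
    sum(hi - lo)
  }
  grid <- expand.grid(row = seq_along(a_starts), col = seq_along(l_starts))
  grid$a0 <- a_starts[grid$row]; grid$l0 <- l_starts[grid$col]
  frac <- mapply(inside_count, grid$a0, grid$l0) / (len_a * len_l)
  grid <- grid[frac >= min_inside, , drop = FALSE]
  g <- data.frame(a0 = grid$a0, a1 = grid$a0 + len_a - 1L,
                  l0 = grid$l0, l1 = grid$l0 + len_l - 1L,
                  row = grid$row, col = grid$col,
                  depth_cm = (grid$a0 + (len_a - 1) / 2) / fs * c0 / 2 * 100)
  g <- g[order(g$row, g$col), ]
  rownames(g) <- NULL
  structure(g, class = c("window_grid", "data.frame"),
            len_a = len_a, len_l = len_l, step_a = step_a, step_l = step_l,
            roi_label = roi_label)
}
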
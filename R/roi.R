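#' Dual-ROI construction: tumour core and 5 mm margin band
#'
#' Rasterises the manually contoured core polygon onto the frame's sample
#' grid (pixel centres; boundary counts as inside) and derives the margin as
#' the band of tissue within `margin_thickness_mm` of the core, excluding
#' the core itself and clipped at the frame edges.  Dilation is performed on
#' a Euclidean distance transform computed in *millimetres*, because axial
#' sample pitch and lateral line pitch differ by an order of magnitude; a
#' pixel-based dilation would produce a visibly anisotropic "5 mm" band.
#'
#' @param core_polygon two-column matrix of (axial_mm, lateral_mm) vertices,
#'   at least 3, non-self-intersecting, inside the frame extent.
#' @param frame an [rf_frame()] defining the grid.
#' @param margin_thickness_mm margin band thickness in mm.
#' @return an object of class `roi_set` with logical matrices `core_mask`
#'   and `margin_mask` (frame-sized, mutually exclusive) and
#'   `margin_thickness`.
#' @export
build_rois <- function(core_polygon, frame, margin_thickness_mm = 5) {
  stopifnot(inherits(frame, "rf_frame"))
  poly <- as.matrix(core_polygon)
  assert_that(ncol(poly) == 2 && nrow(poly) >= 3,
              "core_polygon needs >= 3 (axial_mm, lateral_mm) vertices")
  if (polygon_self_intersects(poly)) stop("core_polygon is self-intersecting", call. = FALSE)
  if (polygon_degenerate(poly)) stop("core_polygon vertices are collinear", call. = FALSE)
  az <- axial_mm(frame); lx <- lateral_mm(frame)
  assert_that(all(poly[, 1] >= 0 & poly[, 1] <= max(az)) &&
              all(poly[, 2] >= 0 & poly[, 2] <= max(lx)),
              "core_polygon must lie inside the frame extent")
  gz <- rep(az, times = length(lx))
  gx <- rep(lx, each = length(az))
  core <- matrix(pracma::inpolygon(gz, gx, poly[, 1], poly[, 2], boundary = TRUE),
                 nrow = length(az))
  d <- edt_mm(core, dz = az[2] - az[1], dx = lx[2] - lx[1])
  margin <- d > 0 & d <= margin_thickness_mm
  structure(list(core_mask = core, margin_mask = margin,
                 margin_thickness = margin_thickness_mm),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> core %d px, margin %d px (%.0f mm band)\n",
              sum(x$core_mask), sum(x$margin_mask), x$margin_thickness))
  invisible(x)
}

polygon_degenerate <- function(poly) {
  z <- poly[, 1]; x <- poly[, 2]
  n <- nrow(poly)
  area2 <- sum(z * x[c(2:n, 1)] - z[c(2:n, 1)] * x)
  abs(area2) < 1e-12
}

# Segment intersection test over all non-adjacent edge pairs.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1 else i + 1, ])
  ccw <- function(a, b, c) (c[2] - a[2]) * (b[1] - a[1]) > (b[2] - a[2]) * (c[1] - a[1])
  inter <- function(p1, p2, p3, p4)
    ccw(p1, p3, p4) != ccw(p2, p3, p4) && ccw(p1, p2, p3) != ccw(p1, p2, p4)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next         # adjacent through the closure
      s1 <- seg(i); s2 <- seg(j)
      if (inter(s1[1, ], s1[2, ], s2[1, ], s2[2, ])) return(TRUE)
    }
  }
  FALSE
}

# Anisotropic Euclidean distance transform (mm) to the TRUE pixels of mask,
# by the two-pass separable lower-envelope algorithm on squared distances.
edt_mm <- function(mask, dz, dx) {
  INF <- 1e18
  f <- matrix(INF, nrow(mask), ncol(mask))
  f[mask] <- 0
  # pass 1: columns (axial), spacing dz
  for (j in seq_len(ncol(f))) f[, j] <- edt_1d(f[, j], dz)
  # pass 2: rows (lateral), spacing dx
  for (i in seq_len(nrow(f))) f[i, ] <- edt_1d(f[i, ], dx)
  sqrt(f)
}

# 1-D squared-distance lower envelope (Felzenszwalb-Huttenlocher).
edt_1d <- function(f, h) {
  n <- length(f)
  if (all(!is.finite(f)) || n == 1) return(f)
  d <- numeric(n)
  v <- integer(n); zb <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; zb[1] <- -Inf; zb[2] <- Inf
  x <- (seq_len(n) - 1) * h
  for (q in 2:n) {
    s <- ((f[q] + x[q]^2) - (f[v[k]] + x[v[k]]^2)) / (2 * x[q] - 2 * x[v[k]])
    while (s <= zb[k]) {
      k <- k - 1L
      s <- ((f[q] + x[q]^2) - (f[v[k]] + x[v[k]]^2)) / (2 * x[q] - 2 * x[v[k]])
    }
    k <- k + 1L
    v[k] <- q
    zb[k] <- s; zb[k + 1] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (zb[k + 1] < x[q]) k <- k + 1L
    d[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  d
}
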
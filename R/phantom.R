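#' Scatterer population of one phantom region
#'
#' Describes the sub-resolution scatterers of one tissue region.  Diffuse
#' scatterers are drawn from a homogeneous spatial Poisson process with the
#' given number density; their relative impedance amplitudes are Gaussian
#' with the given mean and spread (a zero mean gives fully developed,
#' Rayleigh-like speckle).  If `regular_spacing` is set, an axial lattice of
#' coherently scattering planes at that spacing is superimposed — the
#' structural periodicity that the spacing-among-scatterers (SAS) estimator
#' detects.  Lattice scatterers take amplitude
#' `lattice_amplitude * |N(1, 0.2)|` so that the planes scatter coherently
#' across the lateral aperture.
#'
#' @param number_density diffuse scatterers per mm^2.
#' @param effective_diameter effective scatterer diameter in micrometres;
#'   sets the Gaussian form-factor roll-off of the region.
#' @param amplitude_mean,amplitude_sd mean and spread of the diffuse
#'   relative impedance amplitude.
#' @param regular_spacing axial lattice spacing in micrometres, or `NULL`
#'   for a purely diffuse region.
#' @param spacing_jitter Gaussian jitter of lattice positions as a fraction
#'   of the spacing, in `[0, 0.5)`.
#' @param lattice_amplitude amplitude scale of lattice scatterers relative
#'   to the diffuse unit spread.
#' @return an object of class `scatterer_population`.
#' @export
scatterer_population <- function(number_density,
                                 effective_diameter,
                                 amplitude_mean = 0,
                                 amplitude_sd = 1,
                                 regular_spacing = NULL,
                                 spacing_jitter = 0.05,
                                 lattice_amplitude = 3) {
  assert_that(number_density >= 0, "number_density must be >= 0")
  assert_that(effective_diameter > 0, "effective_diameter must be > 0")
  if (!is.null(regular_spacing)) {
    assert_that(regular_spacing > 0, "regular_spacing must be > 0")
    assert_that(spacing_jitter >= 0 && spacing_jitter < 0.5,
                "spacing_jitter must lie in [0, 0.5)")
  }
  structure(
    list(number_density = number_density,
         effective_diameter = effective_diameter,
         amplitude_mean = amplitude_mean,
         amplitude_sd = amplitude_sd,
         regular_spacing = regular_spacing,
         spacing_jitter = spacing_jitter,
         lattice_amplitude = lattice_amplitude),
    class = "scatterer_population")
}

#' Tissue phantom with a tumour core, margin band and background
#'
#' Geometry is axial (depth) by lateral, in millimetres, with the transducer
#' face at depth 0.  The tumour core is a polygon; the margin is the band of
#' tissue within `margin_thickness` mm of the core (its morphological
#' dilation minus the core); everything else is background.  Each region has
#' its own scatterer population and attenuation coefficient.
#'
#' @param extent numeric length-2, axial x lateral extent in mm.
#' @param core_polygon two-column matrix of (axial_mm, lateral_mm) vertices,
#'   counter-clockwise, lying inside `extent`.
#' @param populations named list with elements `core`, `margin`,
#'   `background`, each a [scatterer_population()].  Missing regions default
#'   to the background population; a `NULL` background means no background
#'   scatterers.
#' @param attenuation named numeric vector of attenuation coefficients in
#'   dB/cm/MHz for `core`, `margin`, `background` (recycled if length 1).
#' @param margin_thickness margin band thickness in mm (default 5, the rim
#'   of surrounding tissue analysed alongside the tumour core).
#' @return an object of class `tissue_phantom`.
#' @export
tissue_phantom <- function(extent = c(30, 12),
                           core_polygon,
                           populations,
                           attenuation = 0,
                           margin_thickness = 5) {
  assert_that(length(extent) == 2 && all(extent > 0), "extent must be two positive lengths (mm)")
  core_polygon <- as.matrix(core_polygon)
  assert_that(ncol(core_polygon) == 2 && nrow(core_polygon) >= 3,
              "core_polygon needs >= 3 (axial, lateral) vertices")
  assert_that(all(core_polygon[, 1] >= 0 & core_polygon[, 1] <= extent[1]) &&
              all(core_polygon[, 2] >= 0 & core_polygon[, 2] <= extent[2]),
              "core_polygon must lie inside extent")
  regions <- c("core", "margin", "background")
  if (inherits(populations, "scatterer_population")) {
    populations <- list(core = populations)
  }
  pops <- setNames(vector("list", 3), regions)
  for (r in regions) pops[[r]] <- populations[[r]] %||% populations[["background"]]
  if (length(attenuation) == 1) attenuation <- setNames(rep(attenuation, 3), regions)
  assert_that(all(regions %in% names(attenuation)), "attenuation must name core, margin, background")
  structure(
    list(extent = extent,
         core_polygon = core_polygon,
         populations = pops,
         attenuation = attenuation[regions],
         margin_thickness = margin_thickness),
    class = "tissue_phantom")
}

# Distance (mm) from points to a closed polygon boundary (minimum over edges).
dist_to_polygon <- function(z, x, poly) {
  nv <- nrow(poly)
  d2 <- rep(Inf, length(z))
  for (i in seq_len(nv)) {
    a <- poly[i, ]
    b <- poly[if (i == nv) 1 else i + 1, ]
    vz <- b[1] - a[1]; vx <- b[2] - a[2]
    L2 <- vz^2 + vx^2
    t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((z - a[1]) * vz + (x - a[2]) * vx) / L2))
    d2 <- pmin(d2, (z - a[1] - t * vz)^2 + (x - a[2] - t * vx)^2)
  }
  sqrt(d2)
}

# Region label of points in phantom coordinates.
classify_points <- function(phantom, z, x) {
  inside <- pracma::inpolygon(z, x, phantom$core_polygon[, 1], phantom$core_polygon[, 2],
                              boundary = TRUE)
  reg <- rep("background", length(z))
  reg[inside] <- "core"
  notin <- !inside
  if (any(notin)) {
    d <- dist_to_polygon(z[notin], x[notin], phantom$core_polygon)
    reg[notin][d <= phantom$margin_thickness] <- "margin"
  }
  reg
}

#' Place scatterers in a phantom
#'
#' Diffuse scatterers are drawn as a homogeneous spatial Poisson process
#' over the full extent at each region's number density and thinned to the
#' region (an exact construction).  Regions whose population requests a
#' regular axial spacing additionally receive a lattice of scattering
#' planes with per-scatterer Gaussian jitter.  The per-region ground truth
#' is attached as an attribute so that estimator-recovery tests never peek
#' at anything else.
#'
#' @param phantom a [tissue_phantom()].
#' @param seed integer seed; all placement randomness derives from it.
#' @return data.frame with columns `z_mm`, `x_mm`, `amplitude`,
#'   `diameter_um`, `region`, and attribute `ground_truth`.
#' @export
place_scatterers <- function(phantom, seed = 1L) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  set.seed(derive_seed(seed, "place"))
  ext <- phantom$extent
  area <- ext[1] * ext[2]
  out <- list()
  for (r in c("core", "margin", "background")) {
    pop <- phantom$populations[[r]]
    if (is.null(pop)) next
    if (pop$number_density > 0) {
      n <- rpois(1, pop$number_density * area)
      if (n > 0) {
        z <- runif(n, 0, ext[1]); x <- runif(n, 0, ext[2])
        keep <- classify_points(phantom, z, x) == r
        if (any(keep)) {
          out[[length(out) + 1]] <- data.frame(
            z_mm = z[keep], x_mm = x[keep],
            amplitude = rnorm(sum(keep), pop$amplitude_mean, pop$amplitude_sd),
            diameter_um = pop$effective_diameter, region = r,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!is.null(pop$regular_spacing)) {
      sp_mm <- pop$regular_spacing / 1000
      zs <- seq(sp_mm / 2, ext[1] - sp_mm / 2, by = sp_mm)
      xs <- seq(0, ext[2], by = 0.1)
      g <- expand.grid(z_mm = zs, x_mm = xs)
      keep <- classify_points(phantom, g$z_mm, g$x_mm) == r
      g <- g[keep, , drop = FALSE]
      if (nrow(g) > 0) {
        if (pop$spacing_jitter > 0)
          g$z_mm <- g$z_mm + rnorm(nrow(g), 0, pop$spacing_jitter * sp_mm)
        g$amplitude <- pop$lattice_amplitude * abs(rnorm(nrow(g), 1, 0.2))
        g$diameter_um <- pop$effective_diameter
        g$region <- r
        out[[length(out) + 1]] <- g
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(z_mm = numeric(), x_mm = numeric(), amplitude = numeric(),
               diameter_um = numeric(), region = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "ground_truth") <- list(
    populations = phantom$populations,
    attenuation = phantom$attenuation,
    extent = phantom$extent,
    seed = seed)
  res
}
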
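#' Describe a nucleus population for a synthetic slide
#'
#' A population is a set of nuclei sharing a DNA-content distribution and a
#' nuclear shape class. DNA per nucleus is drawn from a normal distribution
#' truncated at 0.1 pg.
#'
#' @param mean_pg Mean DNA content per nucleus, pg.
#' @param sd_pg Biological SD of DNA content, pg (0 for a constant population,
#'   e.g. an internal standard of known C-value).
#' @param count Number of nuclei to render.
#' @param shape_class One of `"ellipse"` (eccentricity <= 0.6), `"cigar"`
#'   (elongated smooth-muscle-like nuclei, eccentricity >= 0.9), `"bell"`
#'   (hollow annular template mimicking metakaryotic bell-shaped nuclei),
#'   `"syncytium"` (linear chains of 4-10 member nuclei) or
#'   `"multinucleated"` (clusters of 2-20 nuclei, e.g. osteoclast-like cells).
#' @return A `nucleus_population` list.
#' @export
nucleus_population <- function(mean_pg, sd_pg = 0, count = 1,
                               shape_class = c("ellipse", "cigar", "bell",
                                               "syncytium", "multinucleated")) {
  shape_class <- match.arg(shape_class)
  stopifnot(mean_pg > 0, sd_pg >= 0, count >= 0)
  structure(list(mean_pg = mean_pg, sd_pg = sd_pg, count = as.integer(count),
                 shape_class = shape_class),
            class = "nucleus_population")
}

#' Recipe for a synthetic Feulgen slide
#'
#' Defines everything needed to render a transmitted-light image of a spread,
#' Feulgen-stained preparation with known per-nucleus DNA content. The
#' rendering model is Beer-Lambert: each nucleus deposits a total absorbance
#' of `stain_factor * true_pg` (the 1:1 stain-to-DNA premise of Feulgen
#' densitometry) over its footprint, and the camera sees
#' `I = i0 * illumination * 10^(-A) + noise`.
#'
#' @param image_shape Integer vector `c(rows, cols)` in pixels.
#' @param scale Areal image scale, pixels per square micron. Default 95.04.
#' @param i0 White-reference (clear-glass) intensity in detector units.
#' @param stain_factor Absorbance (OD x pixels) deposited per pg of DNA.
#' @param populations List of [nucleus_population()] objects.
#' @param area_per_pg Mean nuclear area per pg of DNA, um^2/pg. Default
#'   10.36 (a 2.5 pg chicken erythrocyte nucleus spreads to ~25.9 um^2).
#' @param area_cv Multiplicative (lognormal) CV of nuclear area around
#'   `area_per_pg * pg`.
#' @param stain_cv Per-nucleus multiplicative (lognormal, mean 1) CV of
#'   staining efficiency; models slide-to-slide chromatin/stoichiometry
#'   variability of the Feulgen reaction. True DNA content is unaffected.
#' @param noise_sd Additive Gaussian intensity noise SD (detector units);
#'   intensities are clipped to `[0, i0]`.
#' @param illumination_gradient Either `NULL` (flat field) or a numeric
#'   vector `c(gx, gy)` giving a linear relative shading across the image
#'   (e.g. `c(0.05, 0)` darkens one edge by 5%).
#' @param bits Output bit depth, 8 or 16 (16 default).
#' @param seed RNG seed; renders are bit-reproducible for a fixed spec.
#' @return A validated `slide_spec` list.
#' @export
slide_spec <- function(image_shape = c(1024L, 1024L),
                       scale = 95.04,
                       i0 = 10000,
                       stain_factor = 300,
                       populations = list(),
                       area_per_pg = 10.36,
                       area_cv = 0.12,
                       stain_cv = 0.23,
                       noise_sd = 50,
                       illumination_gradient = NULL,
                       bits = 16L,
                       seed = 1L) {
  if (inherits(populations, "nucleus_population")) populations <- list(populations)
  spec <- structure(list(
    image_shape = as.integer(image_shape), scale = scale, i0 = i0,
    stain_factor = stain_factor, populations = populations,
    area_per_pg = area_per_pg, area_cv = area_cv, stain_cv = stain_cv,
    noise_sd = noise_sd, illumination_gradient = illumination_gradient,
    bits = as.integer(bits), seed = as.integer(seed)),
    class = "slide_spec")
  validate_slide_spec(spec)
  spec
}

validate_slide_spec <- function(spec) {
  stopifnot(length(spec$image_shape) == 2, all(spec$image_shape >= 16))
  if (spec$stain_factor <= 0) stop("stain_factor must be > 0")
  if (spec$i0 <= 0) stop("i0 must be > 0")
  if (spec$scale <= 0) stop("scale must be > 0")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$area_per_pg <= 0) stop("area_per_pg must be > 0")
  if (spec$area_cv < 0 || spec$stain_cv < 0) stop("CV parameters must be >= 0")
  if (!spec$bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  for (p in spec$populations) {
    if (!inherits(p, "nucleus_population"))
      stop("populations must be a list of nucleus_population objects")
    if (p$count < 0 || p$sd_pg < 0) stop("invalid population")
  }
  invisible(spec)
}

#' @export
print.slide_spec <- function(x, ...) {
  cat(sprintf("slide_spec: %d x %d px, i0 = %g, stain_factor = %g OD.px/pg, seed = %d\n",
              x$image_shape[1], x$image_shape[2], x$i0, x$stain_factor, x$seed))
  for (p in x$populations)
    cat(sprintf("  population: %d x %s, %.3g +/- %.3g pg\n",
                p$count, p$shape_class, p$mean_pg, p$sd_pg))
  invisible(x)
}
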
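# Synthetic slide rendering.
#
# Beer-Lambert forward model: every nucleus deposits a total absorbance of
# stain_factor * true_pg over its pixel footprint (Feulgen stain mass is
# proportional to DNA 1:1), distributed by a smooth center-weighted radial
# chromatin profile so per-nucleus densitometric SD is nonzero. The camera
# records I = i0 * illumination * 10^(-A) + Gaussian noise, clipped to
# [0, i0].

#' A transmitted-light image
#'
#' Thin container for a grayscale transmitted-light image: an intensity
#' matrix in detector units plus the white-reference and scale metadata
#' needed for densitometry.
#'
#' @param intensity Numeric matrix of intensities (rows x cols).
#' @param i0 Nominal white-reference intensity (detector units), or `NA` if
#'   unknown (estimate it with [estimate_white_reference()]).
#' @param scale Areal scale, pixels per square micron.
#' @param bits Bit depth the image is meant to be stored at (8 or 16).
#' @return A `tl_image` object.
#' @export
tl_image <- function(intensity, i0 = NA_real_, scale = 95.04, bits = 16L) {
  stopifnot(is.matrix(intensity), is.numeric(intensity))
  structure(list(intensity = intensity, i0 = i0, scale = scale,
                 bits = as.integer(bits)),
            class = "tl_image")
}

#' @export
print.tl_image <- function(x, ...) {
  cat(sprintf("tl_image: %d x %d px, i0 = %s, scale = %g px/um^2, %d-bit\n",
              nrow(x$intensity), ncol(x$intensity),
              format(x$i0), x$scale, x$bits))
  invisible(x)
}

# Run code with the RNG seeded, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# -- footprint templates ------------------------------------------------------

# Pixel offsets and chromatin weights for one elliptical footprint.
# aspect = minor/major axis ratio; theta = orientation (radians).
# Returns dr, dc integer offsets and unnormalised weights; u is the
# normalised elliptical radius in [0, 1].
ellipse_template <- function(area_px, aspect, theta, hollow = FALSE) {
  if (hollow) {
    # annulus: outer radius R, hole at 0.6 R, same total area
    r_out <- sqrt(area_px / (pi * (1 - 0.6^2)))
    a <- r_out; b <- r_out
  } else {
    a <- sqrt(area_px / (pi * aspect))
    b <- a * aspect
  }
  h <- ceiling(max(a, b)) + 1L
  dr <- rep(-h:h, times = 2L * h + 1L)
  dc <- rep(-h:h, each = 2L * h + 1L)
  xr <- dc * cos(theta) + dr * sin(theta)
  yr <- -dc * sin(theta) + dr * cos(theta)
  u2 <- (xr / a)^2 + (yr / b)^2
  if (hollow) keep <- u2 <= 1 & u2 >= 0.6^2 else keep <- u2 <= 1
  u <- sqrt(u2[keep])
  if (hollow) {
    # peak mid-annulus, fading to the rim and the hole edge
    w <- 1.5 - ((u - 0.8) / 0.2)^2 * 0.75
  } else {
    # center-weighted chromatin profile: 1.5 at center, 0.5 at the rim
    w <- 1.5 - u^2
  }
  list(dr = dr[keep], dc = dc[keep], w = pmax(w, 0.25))
}

shape_aspect <- function(shape_class) {
  switch(shape_class,
    ellipse = stats::runif(1, 0.80, 1.00),        # eccentricity <= 0.6
    cigar = stats::runif(1, 0.25, 0.43),          # eccentricity >= 0.9
    bell = 1,
    syncytium = stats::runif(1, 0.60, 0.80),
    multinucleated = stats::runif(1, 0.80, 1.00))
}

# Relative member-center offsets for multi-nucleus structures. member_a is
# the largest member semi-major axis: spacing by it keeps members disjoint
# whatever their orientation (the golden-angle spiral's nearest-neighbour
# distance is about its radial coefficient).
group_offsets <- function(shape_class, n_members, member_a) {
  if (shape_class == "syncytium") {
    # linear chain along a random direction, >= 3 px gaps
    theta <- stats::runif(1, 0, pi)
    step <- 2 * member_a + 3
    d <- (seq_len(n_members) - (n_members + 1) / 2) * step
    cbind(dr = d * sin(theta), dc = d * cos(theta))
  } else {
    # golden-angle spiral packs members inside one cytoplasmic disc
    k <- seq_len(n_members)
    rad <- (2 * member_a + 3) * sqrt(k - 1)
    ang <- k * 2.39996323
    cbind(dr = rad * sin(ang), dc = rad * cos(ang))
  }
}

# -- renderer -----------------------------------------------------------------

#' Render a synthetic Feulgen slide
#'
#' Draws every nucleus described by `spec$populations`, deposits its
#' absorbance on an optical-density field and images it through the
#' Beer-Lambert model. The integral of the deposited absorbance over each
#' nucleus equals `stain_factor * true_pg * stain_jitter` exactly (the
#' chromatin weight profile is normalised per nucleus), so with
#' `stain_cv = 0`, flat illumination and `noise_sd = 0` the rendered
#' integrated OD recovers `stain_factor * true_pg`.
#'
#' Nuclei are placed uniformly at random without overlap (2 px minimum gap).
#' A nucleus that cannot be placed within the retry budget is skipped with a
#' warning and omitted from the truth table; a nucleus footprint larger than
#' the image is an error.
#'
#' @param spec A [slide_spec()].
#' @param retries Placement attempts per nucleus before it is skipped.
#' @return A list with `image` (a [tl_image()]) and `truth`, a data frame
#'   with one row per rendered nucleus: `nucleus_id`, `true_pg`,
#'   `shape_class`, `centroid_row`, `centroid_col` (0-based pixel centers),
#'   `true_area_um2` (footprint pixels / scale), `true_iod` (absorbance
#'   actually deposited, i.e. `stain_factor * true_pg * stain jitter`) and
#'   `group_id` (`NA` for isolated nuclei, shared within a syncytium or
#'   multinucleated cluster).
#' @export
render_slide <- function(spec, retries = 200L) {
  validate_slide_spec(spec)
  with_seed(spec$seed, render_slide_impl(spec, retries))
}

render_slide_impl <- function(spec, retries) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  A <- matrix(0, nr, nc)
  occupied <- matrix(FALSE, nr, nc)
  truth <- list()
  id <- 0L; group <- 0L

  place_one <- function(tmpl) {
    # returns c(r0, c0) or NULL; keeps a 1 px halo free around the footprint
    h <- max(abs(tmpl$dr), abs(tmpl$dc)) + 2L
    if (2L * h + 1L > min(nr, nc))
      stop("nucleus footprint larger than the image")
    for (i in seq_len(retries)) {
      r0 <- sample.int(nr - 2L * h, 1L) + h
      c0 <- sample.int(nc - 2L * h, 1L) + h
      if (!any(occupied[cbind(r0 + tmpl$dr, c0 + tmpl$dc)])) return(c(r0, c0))
    }
    NULL
  }

  stamp <- function(tmpl, at, pg, shape_class, gid) {
    rr <- at[1] + tmpl$dr; cc <- at[2] + tmpl$dc
    jit <- if (spec$stain_cv > 0) {
      s <- sqrt(log(1 + spec$stain_cv^2))
      exp(stats::rnorm(1, -s^2 / 2, s))  # lognormal, mean exactly 1
    } else 1
    w <- tmpl$w / sum(tmpl$w)
    idx <- cbind(rr, cc)
    A[idx] <<- A[idx] + spec$stain_factor * pg * jit * w
    # mark footprint + 1 px halo as occupied
    halo <- cbind(rep(rr, 5L) + rep(c(0L, 1L, -1L, 0L, 0L), each = length(rr)),
                  rep(cc, 5L) + rep(c(0L, 0L, 0L, 1L, -1L), each = length(cc)))
    halo <- halo[halo[, 1] >= 1 & halo[, 1] <= nr &
                 halo[, 2] >= 1 & halo[, 2] <= nc, , drop = FALSE]
    occupied[halo] <<- TRUE
    id <<- id + 1L
    truth[[id]] <<- data.frame(
      nucleus_id = id, true_pg = pg, shape_class = shape_class,
      centroid_row = mean(rr) - 1, centroid_col = mean(cc) - 1,
      true_area_um2 = length(rr) / spec$scale,
      true_iod = spec$stain_factor * pg * jit,
      group_id = gid)
  }

  draw_pg <- function(pop) {
    if (pop$sd_pg == 0) return(pop$mean_pg)
    max(0.1, stats::rnorm(1, pop$mean_pg, pop$sd_pg))
  }
  area_px_for <- function(pg) {
    a <- pg * spec$area_per_pg
    if (spec$area_cv > 0) {
      s <- sqrt(log(1 + spec$area_cv^2))
      a <- a * exp(stats::rnorm(1, -s^2 / 2, s))
    }
    max(12, a * spec$scale)
  }

  for (pop in spec$populations) {
    n_left <- pop$count
    if (pop$shape_class %in% c("syncytium", "multinucleated")) {
      rng <- if (pop$shape_class == "syncytium") 4:10 else 2:20
      while (n_left > 0L) {
        m <- min(n_left, sample(rng, 1L))
        pgs <- vapply(seq_len(m), function(i) draw_pg(pop), numeric(1))
        areas <- vapply(pgs, area_px_for, numeric(1))
        tmpls <- lapply(seq_len(m), function(i)
          ellipse_template(areas[i], shape_aspect(pop$shape_class),
                           stats::runif(1, 0, pi)))
        min_aspect <- if (pop$shape_class == "syncytium") 0.60 else 0.80
        member_a <- sqrt(max(areas) / (pi * min_aspect))
        off <- group_offsets(pop$shape_class, m, member_a)
        # place the whole group: every member footprint must be free
        placed <- NULL
        hmax <- max(vapply(seq_len(m), function(i)
          max(abs(tmpls[[i]]$dr), abs(tmpls[[i]]$dc)), numeric(1))) +
          ceiling(max(abs(off))) + 2L
        if (2L * hmax + 1L > min(nr, nc))
          stop("nucleus group larger than the image")
        for (i in seq_len(retries)) {
          r0 <- sample.int(max(nr - 2L * hmax, 1L), 1L) + hmax
          c0 <- sample.int(max(nc - 2L * hmax, 1L), 1L) + hmax
          ok <- TRUE
          for (j in seq_len(m)) {
            rr <- round(r0 + off[j, 1]) + tmpls[[j]]$dr
            cc <- round(c0 + off[j, 2]) + tmpls[[j]]$dc
            if (any(occupied[cbind(rr, cc)])) { ok <- FALSE; break }
          }
          if (ok) { placed <- c(r0, c0); break }
        }
        if (is.null(placed)) {
          warning(sprintf("skipped a %s group of %d nuclei: no free placement",
                          pop$shape_class, m))
        } else {
          group <- group + 1L
          for (j in seq_len(m))
            stamp(tmpls[[j]],
                  c(round(placed[1] + off[j, 1]), round(placed[2] + off[j, 2])),
                  pgs[j], pop$shape_class, group)
        }
        n_left <- n_left - m
      }
    } else {
      for (i in seq_len(n_left)) {
        pg <- draw_pg(pop)
        tmpl <- ellipse_template(area_px_for(pg), shape_aspect(pop$shape_class),
                                 stats::runif(1, 0, pi),
                                 hollow = pop$shape_class == "bell")
        at <- place_one(tmpl)
        if (is.null(at)) {
          warning("skipped a nucleus: no free placement within retry budget")
        } else {
          stamp(tmpl, at, pg, pop$shape_class, NA_integer_)
        }
      }
    }
  }

  illum <- matrix(1, nr, nc)
  g <- spec$illumination_gradient
  if (!is.null(g) && any(g != 0)) {
    cn <- matrix(seq_len(nc) / nc, nr, nc, byrow = TRUE)
    rn <- matrix(seq_len(nr) / nr, nr, nc)
    illum <- pmax(1 - g[1] * cn - g[2] * rn, 0.01)
  }
  I <- spec$i0 * illum * 10^(-A)
  if (spec$noise_sd > 0)
    I <- I + stats::rnorm(length(I), 0, spec$noise_sd)
  I <- matrix(pmin(pmax(I, 0), spec$i0), nr, nc)

  truth <- if (id > 0L) do.call(rbind, truth) else
    data.frame(nucleus_id = integer(), true_pg = numeric(),
               shape_class = character(), centroid_row = numeric(),
               centroid_col = numeric(), true_area_um2 = numeric(),
               true_iod = numeric(), group_id = integer())
  list(image = tl_image(I, i0 = spec$i0, scale = spec$scale, bits = spec$bits),
       truth = truth)
}

#' Render a chicken red-blood-cell standard smear
#'
#' The internal calibration standard: nucleated chicken erythrocytes whose
#' nuclei carry a constant, known diploid DNA content of 2C = 2.5 pg and
#' spread to small, near-round footprints (~25.9 um^2 on average). Smears are
#' rendered with the same optics and staining model as sample slides so a
#' smear processed in the same batch calibrates the batch.
#'
#' @param count Number of standard nuclei (>= 1).
#' @param seed RNG seed.
#' @param spec Optional [slide_spec()] carrying the optics to share with the
#'   sample slides (stain_factor, i0, noise, scale...). Its populations are
#'   replaced by the cRBC population and, when `image_shape` is missing or
#'   too small, the image is sized to hold `count` nuclei at ~15% packing.
#' @param mean_area_um2 Mean spread nuclear area of the standard, um^2.
#' @return As [render_slide()]: `list(image, truth)` with all
#'   `truth$true_pg == 2.5`.
#' @export
render_standard_smear <- function(count, seed = 1L, spec = NULL,
                                  mean_area_um2 = 25.9) {
  if (count < 1) stop("a standard smear must contain at least one nucleus")
  if (is.null(spec)) spec <- slide_spec(seed = seed)
  spec$seed <- as.integer(seed)
  spec$area_per_pg <- mean_area_um2 / 2.5
  spec$populations <- list(nucleus_population(2.5, 0, count, "ellipse"))
  need_px <- count * mean_area_um2 * spec$scale / 0.15
  side <- max(256L, as.integer(ceiling(sqrt(need_px))))
  if (prod(spec$image_shape) < need_px) spec$image_shape <- c(side, side)
  render_slide(spec)
}
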
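# Transmittance -> optical density and white-reference estimation.

#' Estimate the white-reference intensity of a slide image
#'
#' Feulgen densitometry needs the clear-glass intensity I0 to evaluate
#' transmittance T = I / I0. On spread preparations the background dominates
#' the bright end of the histogram, so the estimate is the median of the
#' pixels in the top decile of the intensity range, which is robust to the
#' (dark) nuclear foreground as long as a reasonable fraction of the image is
#' background.
#'
#' @param image A [tl_image()] or a plain intensity matrix.
#' @return The estimated white-reference intensity (scalar).
#' @export
estimate_white_reference <- function(image) {
  I <- if (inherits(image, "tl_image")) image$intensity else image
  stopifnot(is.matrix(I), length(I) > 0)
  mx <- max(I)
  if (mx <= 0) stop("no background detected: image is entirely dark")
  if (all(I == mx)) {
    if (inherits(image, "tl_image") && is.finite(image$bits) &&
        mx >= 2^image$bits - 1)
      warning("image appears saturated; returning the maximum intensity")
    return(mx)
  }
  stats::median(I[I >= 0.9 * mx])
}

#' Construct an optical-density image
#'
#' Container for a per-pixel absorbance map; normally produced by
#' [transmittance_to_od()], but constructable directly when OD values come
#' from elsewhere.
#'
#' @param od Numeric matrix of optical densities (>= 0).
#' @param scale Areal scale, pixels per square micron.
#' @param white_reference Intensity that was used as T = 1.
#' @param t_floor Transmittance floor used (caps OD).
#' @return An `od_image` object.
#' @export
od_image <- function(od, scale = 95.04, white_reference = 1,
                     t_floor = 1e-3) {
  stopifnot(is.matrix(od), all(od >= 0))
  structure(list(od = od, scale = scale, white_reference = white_reference,
                 t_floor = t_floor),
            class = "od_image")
}

#' Convert transmittance to optical density
#'
#' Per pixel, transmittance `T = I / white_reference` is clamped to
#' `[t_floor, 1]` and optical density is `OD = log10(1 / T)`. The floor caps
#' OD at `log10(1 / t_floor)` (3.0 by default) so fully dark pixels do not
#' produce infinite absorbance.
#'
#' @param image A [tl_image()] or intensity matrix.
#' @param white_reference Intensity corresponding to T = 1; defaults to
#'   [estimate_white_reference()] of the image.
#' @param t_floor Lower clamp for transmittance, in (0, 1).
#' @return An `od_image`: list with `od` matrix (>= 0 everywhere, 0 wherever
#'   intensity >= the white reference), `scale` and `white_reference`.
#' @export
transmittance_to_od <- function(image, white_reference = NULL,
                                t_floor = 1e-3) {
  I <- if (inherits(image, "tl_image")) image$intensity else image
  scale <- if (inherits(image, "tl_image")) image$scale else NA_real_
  if (is.null(white_reference)) white_reference <- estimate_white_reference(image)
  stopifnot(white_reference > 0, t_floor > 0, t_floor < 1)
  Tm <- pmin(pmax(I / white_reference, t_floor), 1)
  structure(list(od = matrix(log10(1 / Tm), nrow(I), ncol(I)),
                 scale = scale, white_reference = white_reference,
                 t_floor = t_floor),
            class = "od_image")
}

#' @export
print.od_image <- function(x, ...) {
  cat(sprintf("od_image: %d x %d px, white_reference = %g, max OD = %.3f\n",
              nrow(x$od), ncol(x$od), x$white_reference, max(x$od)))
  invisible(x)
}

# Otsu threshold of an OD matrix (256-bin histogram between 0 and od_cap).
otsu_od_threshold <- function(od, od_cap = 3) {
  img <- EBImage::Image(pmin(od / od_cap, 1))
  as.numeric(EBImage::otsu(img, range = c(0, 1), levels = 256)) * od_cap
}

# Hysteresis foreground mask: Otsu gives the strong (seed) threshold; the
# mask floods out to a weak threshold just above the background OD noise, so
# faintly stained rims are kept with their nucleus. On a dark-nucleus /
# clear-background OD image a single Otsu cut tends to shave the rim of
# weakly stained nuclei, which loses absorbance exactly where staining
# varies most.
hysteresis_mask <- function(od, strong) {
  bg <- od[od <= strong]
  weak <- max(0.02, 6 * stats::mad(bg, center = stats::median(bg)))
  weak <- min(weak, strong)
  mw <- od > weak
  if (!any(mw)) return(list(mask = mw, weak = weak))
  lab <- EBImage::bwlabel(EBImage::Image(mw * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(od), ncol(od))
  seeded <- unique(lab[od > strong])
  list(mask = matrix(lab %in% seeded[seeded > 0L], nrow(od), ncol(od)),
       weak = weak)
}

#' Segment nuclei on an optical-density image
#'
#' Thresholds the OD image and labels connected foreground components. In
#' auto mode (the default) Otsu's method on the OD histogram provides seed
#' pixels and the foreground floods out to a weak threshold just above the
#' background noise (hysteresis), so faint nuclear rims stay attached to
#' their nucleus; a fixed `od_threshold` is applied as a plain single
#' cut. It then labels components and flags
#' components that should not enter densitometry: touching the image border,
#' outside the area bounds, or suspected merges of touching nuclei. With
#' `split_touching = TRUE` a distance-transform watershed splits touching
#' nuclei before labelling (off by default: spread preparations are
#' monolayers by design).
#'
#' @param od_image An `od_image` from [transmittance_to_od()].
#' @param od_threshold Fixed OD threshold, or `NULL` for Otsu.
#' @param min_area_um2,max_area_um2 Area bounds in um^2; components outside
#'   are flagged (`under_min_area` excludes debris, `over_max_area` clumps).
#' @param split_touching Apply watershed splitting (logical).
#' @return A `label_map`: list with `labels` (integer matrix, 0 = background,
#'   labels are contiguous positive integers) and `flags`, a data frame with
#'   one row per label (`label`, `area_px`, `border_touching`,
#'   `under_min_area`, `over_max_area`, `merged_suspect`, `flagged`). An
#'   empty foreground yields zero labels with a warning (acellular slide).
#' @export
segment_nuclei <- function(od_image, od_threshold = NULL,
                           min_area_um2 = 8, max_area_um2 = 400,
                           split_touching = FALSE) {
  stopifnot(inherits(od_image, "od_image"))
  od <- od_image$od
  if (is.null(od_threshold)) {
    thr <- otsu_od_threshold(od)
    hy <- hysteresis_mask(od, thr)
    mask <- hy$mask
  } else {
    thr <- od_threshold
    mask <- od > thr
  }
  if (!any(mask)) {
    warning("empty foreground: no nuclei detected (acellular slide?)")
    return(structure(list(
      labels = matrix(0L, nrow(od), ncol(od)), threshold = thr,
      flags = data.frame(label = integer(), area_px = integer(),
                         border_touching = logical(), under_min_area = logical(),
                         over_max_area = logical(), merged_suspect = logical(),
                         flagged = logical())),
      class = "label_map"))
  }

  comp <- EBImage::bwlabel(EBImage::Image(mask * 1))
  if (split_touching) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    labels <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  } else {
    labels <- comp
  }
  labels <- matrix(as.integer(EBImage::imageData(labels)), nrow(od), ncol(od))
  comp <- matrix(as.integer(EBImage::imageData(comp)), nrow(od), ncol(od))

  n_lab <- max(labels)
  area_px <- tabulate(labels[labels > 0L], nbins = n_lab)
  scale <- od_image$scale
  area_um2 <- area_px / scale

  border <- rep(FALSE, n_lab)
  edge <- c(labels[1, ], labels[nrow(labels), ], labels[, 1], labels[, ncol(labels)])
  border[unique(edge[edge > 0L])] <- TRUE

  # merged_suspect: the pre-split connected component would watershed into
  # >= 2 pieces of plausible nucleus size
  merged <- rep(FALSE, n_lab)
  if (!split_touching) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    ws <- matrix(as.integer(EBImage::imageData(
      EBImage::watershed(dm, tolerance = 1, ext = 1))), nrow(od), ncol(od))
    fg <- labels > 0L
    pieces <- table(labels[fg], ws[fg])
    big <- pieces >= min_area_um2 * scale
    n_pieces <- rowSums(big)
    merged[as.integer(rownames(pieces))] <- n_pieces >= 2
  }

  flags <- data.frame(
    label = seq_len(n_lab),
    area_px = area_px,
    border_touching = border,
    under_min_area = area_um2 < min_area_um2,
    over_max_area = area_um2 > max_area_um2,
    merged_suspect = merged)
  flags$flagged <- with(flags, border_touching | under_min_area |
                          over_max_area | merged_suspect)
  structure(list(labels = labels, threshold = thr, flags = flags),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label_map: %d labels (%d flagged), OD threshold %.3f\n",
              nrow(x$flags), sum(x$flags$flagged), x$threshold))
  invisible(x)
}
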
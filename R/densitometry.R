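# Per-nucleus densitometry: the three measured features of Feulgen image
# cytometry — the densitometric sum (IOD), the densitometric area, and the
# densitometric standard deviation.

#' Measure segmented nuclei on an optical-density image
#'
#' For each retained label the integrated optical density is the plain sum
#' of per-pixel OD over the nucleus mask, `IOD = sum_i log10(1 / T_i)` — no
#' background subtraction beyond the white-reference normalisation, because
#' nuclear stain is heterogeneous and a single-point OD would not be
#' representative. Area is the pixel count converted through the areal
#' scale; `od_sd` is the per-pixel OD standard deviation within the mask
#' (n - 1 denominator).
#'
#' @param od_image An `od_image` from [transmittance_to_od()].
#' @param labels A `label_map` from [segment_nuclei()].
#' @param include_flagged Keep QC-flagged labels (default `FALSE`).
#' @return A data frame, one row per measured nucleus: `nucleus_id`, `iod`,
#'   `area_px`, `area_um2`, `od_sd`, `centroid_row`, `centroid_col`
#'   (0-based) and the QC flag columns. Labels with < 2 pixels get
#'   `od_sd = 0` and `under_min_area = TRUE`.
#' @export
measure_nuclei <- function(od_image, labels, include_flagged = FALSE) {
  stopifnot(inherits(od_image, "od_image"), inherits(labels, "label_map"))
  if (!identical(dim(od_image$od), dim(labels$labels)))
    stop("od_image and label map have mismatched shapes")
  flags <- labels$flags
  keep <- if (include_flagged) flags$label else flags$label[!flags$flagged]
  out <- data.frame(nucleus_id = integer(), iod = numeric(),
                    area_px = integer(), area_um2 = numeric(),
                    od_sd = numeric(), centroid_row = numeric(),
                    centroid_col = numeric())
  if (length(keep)) {
    lab <- labels$labels
    fg <- lab > 0L & matrix(lab %in% keep, nrow(lab), ncol(lab))
    lv <- lab[fg]
    odv <- od_image$od[fg]
    rows <- row(lab)[fg]; cols <- col(lab)[fg]
    f <- factor(lv, levels = keep)
    n <- as.integer(tabulate(f, nbins = length(keep)))
    iod <- as.numeric(tapply(odv, f, sum, default = 0))
    sdv <- as.numeric(tapply(odv, f, stats::sd, default = 0))
    sdv[n < 2] <- 0
    out <- data.frame(
      nucleus_id = keep,
      iod = iod,
      area_px = n,
      area_um2 = n / od_image$scale,
      od_sd = ifelse(is.na(sdv), 0, sdv),
      centroid_row = as.numeric(tapply(rows, f, mean)) - 1,
      centroid_col = as.numeric(tapply(cols, f, mean)) - 1)
  }
  fl <- flags[match(out$nucleus_id, flags$label),
              c("border_touching", "under_min_area", "over_max_area",
                "merged_suspect", "flagged")]
  rownames(fl) <- NULL
  cbind(out, fl)
}
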
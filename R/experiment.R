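#' Paired slide/standard recovery experiment
#'
#' The canonical validation run of the whole measurement chain: render a
#' chicken-erythrocyte standard smear and a sample slide whose nuclei carry
#' `sample_fold` times the standard's per-nucleus integrated absorbance
#' (2.4x the 2.5 pg standard emulates a diploid human population at
#' 2C = 6 pg), push both through OD transform, segmentation, densitometry
#' and internal-standard calibration, and report the recovered per-nucleus
#' DNA masses.
#'
#' @param n_sample,n_standard Nuclei per sample slide / standard smear.
#' @param sample_fold Sample per-nucleus absorbance as a multiple of the
#'   standard's.
#' @param seed RNG seed (the smear uses `seed`, the slide `seed + 1`).
#' @param base_spec Optics/staining shared by both renders; defaults to
#'   [slide_spec()] defaults. The sample image is sized to hold the nuclei
#'   at ~15% packing.
#' @return List: `mean_pg` (mean recovered DNA mass), `pg` (per nucleus),
#'   `true_pg` (the rendered ground truth), `calibration`, `n_measured`.
#' @export
recovery_experiment <- function(n_sample = 200L, n_standard = 200L,
                                sample_fold = 2.4, seed = 1L,
                                base_spec = NULL) {
  if (is.null(base_spec)) base_spec <- slide_spec(seed = as.integer(seed))
  smear <- render_standard_smear(n_standard, seed = seed, spec = base_spec)
  pg <- sample_fold * 2.5
  sspec <- base_spec
  need_px <- n_sample * pg * sspec$area_per_pg * sspec$scale / 0.15
  side <- max(512L, as.integer(ceiling(sqrt(need_px))))
  sspec$image_shape <- c(side, side)
  sspec$seed <- as.integer(seed) + 1L
  sspec$populations <- list(nucleus_population(pg, 0, n_sample))
  slide <- render_slide(sspec)

  measure <- function(img) {
    od <- transmittance_to_od(img)
    measure_nuclei(od, segment_nuclei(od))
  }
  cal <- fit_standard(measure(smear$image))
  m <- measure(slide$image)
  pgs <- iod_to_pg(cal, m$iod)
  list(mean_pg = mean(pgs), pg = pgs, true_pg = slide$truth$true_pg,
       calibration = cal, n_measured = nrow(m))
}
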
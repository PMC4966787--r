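# IOD -> absolute DNA mass via the internal cRBC standard.

#' Fit the internal-standard calibration
#'
#' Chicken red-blood-cell nuclei carry a constant diploid DNA content
#' (2C = 2.5 pg), so the mean IOD of a co-processed standard smear anchors a
#' one-point standard curve through the origin:
#' `DNA pg = standard_2c_pg / mean IOD standard x IOD sample`.
#'
#' @param standard_measurements Data frame of standard-nucleus measurements
#'   (from [measure_nuclei()]); must have an `iod` column. Flagged nuclei
#'   should already be excluded.
#' @param standard_2c_pg Known diploid DNA mass of the standard, pg.
#' @param min_n Minimum number of standard nuclei (QC floor).
#' @return A `calibration_model`: `mean_iod_standard`, `standard_2c_pg`,
#'   `standard_1c_pg`, `pg_per_iod`, `n_standard`, `cv_standard` (% IOD CV,
#'   a staining-quality check) and `curve_points` (origin plus the one known
#'   point).
#' @export
fit_standard <- function(standard_measurements, standard_2c_pg = 2.5,
                         min_n = 10L) {
  iod <- if (is.data.frame(standard_measurements))
    standard_measurements$iod else as.numeric(standard_measurements)
  iod <- iod[is.finite(iod)]
  if (length(iod) < min_n)
    stop(sprintf("standard underpowered: %d nuclei < floor of %d",
                 length(iod), min_n))
  m <- mean(iod)
  if (m <= 0) stop("standard mean IOD is zero; cannot calibrate")
  structure(list(
    mean_iod_standard = m,
    standard_2c_pg = standard_2c_pg,
    standard_1c_pg = standard_2c_pg / 2,
    pg_per_iod = standard_2c_pg / m,
    n_standard = length(iod),
    cv_standard = 100 * stats::sd(iod) / m,
    curve_points = data.frame(known_pg = c(0, standard_2c_pg),
                              mean_iod = c(0, m))),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(paste0("calibration_model: mean standard IOD %.4g (n = %d, ",
                     "CV %.1f%%), %g pg / IOD unit\n"),
              x$mean_iod_standard, x$n_standard, x$cv_standard, x$pg_per_iod))
  invisible(x)
}

#' Convert IOD to absolute DNA mass
#'
#' Applies the one-point internal-standard formula
#' `pg = standard_2c_pg / mean_iod_standard * iod`; linear through the
#' origin, so an IOD equal to the standard's own mean maps to exactly the
#' standard's 2C value.
#'
#' @param model A `calibration_model` from [fit_standard()].
#' @param iod Numeric vector of integrated optical densities (>= 0).
#' @return DNA mass in pg (same length as `iod`).
#' @export
iod_to_pg <- function(model, iod) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(iod < 0)) stop("negative IOD")
  model$standard_2c_pg / model$mean_iod_standard * iod
}

#' Express DNA mass as fold of the haploid C-value
#'
#' @param pg DNA mass, pg.
#' @param c1_pg Haploid (1C) genome mass of the species, pg; human 3.0
#'   (2C = 6 pg), chicken 1.25.
#' @return Fold-C values: a diploid human nucleus (6 pg) maps to 2.
#' @export
pg_to_fold_c <- function(pg, c1_pg = 3.0) {
  stopifnot(c1_pg > 0)
  pg / c1_pg
}
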
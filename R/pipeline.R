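# Pipeline orchestration: simulate -> segment -> measure -> calibrate ->
# summarise, with CSV/TIFF interfaces and a reproducible run configuration.
# The analysis scripts under analysis/ are thin drivers over these
# functions.

#' Default run configuration
#'
#' All knobs of the pipeline in one serialisable list: image scale,
#' OD-transform floor, segmentation parameters, calibration floor, species
#' C-value, statistics options, the simulation recipe and the single RNG
#' seed every stochastic step derives from.
#'
#' @return A nested list; see the vignette for the meaning and units of each
#'   entry.
#' @export
default_config <- function() {
  list(
    scale = 95.04,              # pixels per um^2
    t_floor = 1e-3,             # OD cap 3.0
    seed = 1L,
    segmentation = list(od_threshold = NULL,  # NULL = Otsu
                        min_area_um2 = 8, max_area_um2 = 400,
                        split_touching = FALSE),
    calibration = list(standard_2c_pg = 2.5, min_n = 10L),
    c1_pg = 3.0,                # human 1C; chicken would be 1.25
    stats = list(alpha = 0.05, p_adjust = "none", bin_width = 0.25),
    simulate = list(
      image_shape = c(1024L, 1024L),
      i0 = 10000, stain_factor = 300, noise_sd = 50,
      area_per_pg = 10.36, area_cv = 0.12, stain_cv = 0.23,
      n_standard = 200L,
      samples = list(list(sample_id = "diploid",
                          populations = list(list(mean_pg = 6, sd_pg = 0,
                                                  count = 100L,
                                                  shape_class = "ellipse"))))))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        nm != "samples" && nm != "populations")
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration from YAML or JSON
#'
#' Values present in the file override the defaults; everything else keeps
#' its [default_config()] value.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return The merged configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  override <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be YAML or JSON"))
  merge_config(default_config(), override)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  unname(tools::md5sum(f))
}

write_manifest <- function(config, out_dir, outputs) {
  manifest <- list(
    package = "feulgen",
    package_version = as.character(utils::packageVersion("feulgen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = config_hash(config),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

slide_spec_from_config <- function(config, populations, seed) {
  sim <- config$simulate
  pops <- lapply(populations, function(p)
    nucleus_population(p$mean_pg, p$sd_pg %||% 0, p$count,
                       p$shape_class %||% "ellipse"))
  slide_spec(image_shape = sim$image_shape, scale = config$scale,
             i0 = sim$i0, stain_factor = sim$stain_factor,
             populations = pops, area_per_pg = sim$area_per_pg,
             area_cv = sim$area_cv, stain_cv = sim$stain_cv,
             noise_sd = sim$noise_sd, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a transmitted-light image to TIFF
#'
#' Intensities are stored as `I / i0` so the white reference sits at full
#' scale; the OD transform is invariant to this normalisation because the
#' white reference is re-estimated from the image on reading.
#'
#' @param image A [tl_image()].
#' @param path Output path (`.tif`/`.tiff`).
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "tl_image"))
  i0 <- if (is.finite(image$i0)) image$i0 else max(image$intensity)
  m <- pmin(pmax(image$intensity / i0, 0), 1)
  tiff::writeTIFF(m, path, bits.per.sample = image$bits)
  invisible(path)
}

#' Read a grayscale TIFF or PNG as a transmitted-light image
#'
#' @param path Image path; bit depth is taken from the file and intensities
#'   are returned on \[0, 1\] (densitometry is invariant to the intensity
#'   scale since the white reference is estimated from the image).
#' @param scale Areal scale to attach, pixels per um^2.
#' @return A [tl_image()] with `i0 = NA` (estimate it).
#' @export
read_image <- function(path, scale = 95.04) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(m)) == 3) m <- m[, , 1]
  tl_image(m, i0 = NA_real_, scale = scale, bits = 16L)
}

#' Simulate a batch of slides and their ground truth
#'
#' Renders every sample slide in `config$simulate$samples` plus one
#' standard smear, writing per slide a 16-bit TIFF and a ground-truth CSV
#' (`nucleus_id`, `true_pg`, `shape_class`, `centroid_row`, `centroid_col`,
#' `true_area_um2`, `group_id`). Per-slide seeds derive from `config$seed`,
#' so two runs with the same configuration are byte-identical.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a data frame listing sample ids, image paths and truth
#'   paths (the standard smear has `sample_id = "standard"`).
#' @export
run_simulate <- function(config = default_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory is not writable")
  samples <- config$simulate$samples
  index <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    spec <- slide_spec_from_config(config, s$populations,
                                   seed = config$seed + i)
    ren <- render_slide(spec)
    img <- file.path(out_dir, paste0(s$sample_id, ".tif"))
    tru <- file.path(out_dir, paste0(s$sample_id, "_truth.csv"))
    write_image(ren$image, img)
    utils::write.csv(ren$truth, tru, row.names = FALSE)
    index[[i]] <- data.frame(sample_id = s$sample_id, image = img, truth = tru)
  }
  spec0 <- slide_spec_from_config(config, list(), seed = config$seed)
  std <- render_standard_smear(config$simulate$n_standard,
                               seed = config$seed, spec = spec0)
  img <- file.path(out_dir, "standard.tif")
  tru <- file.path(out_dir, "standard_truth.csv")
  write_image(std$image, img)
  utils::write.csv(std$truth, tru, row.names = FALSE)
  index[[length(index) + 1]] <-
    data.frame(sample_id = "standard", image = img, truth = tru)
  index <- do.call(rbind, index)
  write_manifest(config, out_dir, as.list(stats::setNames(index$image,
                                                          index$sample_id)))
  invisible(index)
}

quantify_one_image <- function(path, config) {
  img <- read_image(path, scale = config$scale)
  od <- transmittance_to_od(img, t_floor = config$t_floor)
  seg <- config$segmentation
  labs <- segment_nuclei(od, od_threshold = seg$od_threshold,
                         min_area_um2 = seg$min_area_um2,
                         max_area_um2 = seg$max_area_um2,
                         split_touching = isTRUE(seg$split_touching))
  excl <- labs$flags[labs$flags$flagged, ]
  if (nrow(excl)) {
    why <- apply(excl[c("border_touching", "under_min_area",
                        "over_max_area", "merged_suspect")], 1,
                 function(r) paste(names(r)[r], collapse = "+"))
    message(sprintf("%s: excluded %d flagged nuclei (%s)",
                    basename(path), nrow(excl),
                    paste(unique(why), collapse = ", ")))
  }
  measure_nuclei(od, labs)
}

flag_string <- function(df) {
  apply(df[c("border_touching", "under_min_area", "over_max_area",
             "merged_suspect")], 1,
        function(r) if (any(r)) paste(names(r)[r], collapse = ";") else "")
}

#' Quantify a batch of slide images
#'
#' The full measurement pipeline: each sample image and each standard image
#' is converted to OD and segmented, nuclei are measured, the calibration is
#' fitted on the pooled standard nuclei, and every sample IOD is converted
#' to DNA pg and fold-C. Writes `per_nucleus.csv`, `summary.csv` (one
#' descriptive row per sample plus a pooled `Total` row when there are >= 2
#' samples) and, when comparison is possible, `comparison.json` with the
#' Kruskal-Wallis + Dunn results.
#'
#' @param sample_images Named character vector of image paths (names are
#'   sample ids; unnamed paths use the file stem).
#' @param standard_images Character vector of standard-smear image paths
#'   (required: without a standard, calibration is impossible).
#' @param config Configuration list.
#' @param out_dir Output directory.
#' @return Invisibly, list with `per_nucleus`, `summary`, `calibration`,
#'   `comparison` (or `NULL`).
#' @export
run_quantify <- function(sample_images, standard_images,
                         config = default_config(), out_dir) {
  if (length(standard_images) == 0)
    stop("no standard images: calibration impossible")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(sample_images)
  if (is.null(ids)) ids <- rep("", length(sample_images))
  blank <- !nzchar(ids)
  ids[blank] <- tools::file_path_sans_ext(basename(sample_images[blank]))

  std <- do.call(rbind, lapply(standard_images, quantify_one_image,
                               config = config))
  cal <- fit_standard(std, standard_2c_pg = config$calibration$standard_2c_pg,
                      min_n = config$calibration$min_n)

  per <- list()
  for (i in seq_along(sample_images)) {
    m <- quantify_one_image(sample_images[i], config)
    if (nrow(m) == 0) {
      warning(sprintf("sample '%s': empty segmentation", ids[i]))
      next
    }
    m$sample_id <- ids[i]
    per[[length(per) + 1]] <- m
  }
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(nucleus_id = integer(), sample_id = character(),
               iod = numeric(), area_px = integer(), area_um2 = numeric(),
               od_sd = numeric())
  if (nrow(per)) {
    per$pg <- iod_to_pg(cal, per$iod)
    per$fold_c <- pg_to_fold_c(per$pg, config$c1_pg)
  } else { per$pg <- numeric(); per$fold_c <- numeric() }

  out <- data.frame(nucleus_id = per$nucleus_id, sample_id = per$sample_id,
                    iod = per$iod, area_px = per$area_px,
                    area_um2 = per$area_um2, od_sd = per$od_sd,
                    pg = per$pg, fold_c = per$fold_c,
                    flags = if (nrow(per)) flag_string(per) else character())
  utils::write.csv(out, file.path(out_dir, "per_nucleus.csv"),
                   row.names = FALSE)

  summary <- summarize_nuclei(out)
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)

  comparison <- NULL
  if (length(unique(out$sample_id)) >= 2) {
    comparison <- compare_groups(split(out$pg, out$sample_id),
                                 alpha = config$stats$alpha,
                                 p_adjust = config$stats$p_adjust)
    jsonlite::write_json(
      list(H = comparison$H, df = comparison$df, p = comparison$p,
           alpha = comparison$alpha, p_adjust = comparison$p_adjust,
           pairwise = comparison$pairwise),
      file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  write_manifest(config, out_dir,
                 list(per_nucleus = "per_nucleus.csv",
                      summary = "summary.csv"))
  invisible(list(per_nucleus = out, summary = summary, calibration = cal,
                 comparison = comparison))
}

#' Summarise a per-nucleus table (table mode)
#'
#' The statistics layer alone: takes a per-nucleus table (a data frame or a
#' CSV path with at least `sample_id`, `pg`, `area_um2`) and produces the
#' per-sample descriptive rows plus, with >= 2 samples, the pooled `Total`
#' row. Re-feeding `run_quantify()`'s own `per_nucleus.csv` reproduces its
#' `summary.csv` exactly.
#'
#' @param per_nucleus Data frame or CSV path.
#' @return Data frame of `sample_summary` rows.
#' @export
summarize_nuclei <- function(per_nucleus) {
  if (is.character(per_nucleus))
    per_nucleus <- utils::read.csv(per_nucleus)
  ids <- unique(per_nucleus$sample_id)
  rows <- lapply(ids, function(s) {
    d <- per_nucleus[per_nucleus$sample_id == s, ]
    describe_sample(d$pg, d$area_um2, sample_id = s)
  })
  summary <- do.call(rbind, rows)
  if (length(ids) >= 2)
    summary <- rbind(summary, pool_samples(summary))
  rownames(summary) <- NULL
  summary
}

#' Compare samples from a per-nucleus table
#'
#' @param per_nucleus Data frame or CSV path with `sample_id` and `pg`.
#' @param alpha,p_adjust As in [compare_groups()].
#' @return A `group_comparison`.
#' @export
compare_nuclei <- function(per_nucleus, alpha = 0.05, p_adjust = "none") {
  if (is.character(per_nucleus))
    per_nucleus <- utils::read.csv(per_nucleus)
  compare_groups(split(per_nucleus$pg, per_nucleus$sample_id),
                 alpha = alpha, p_adjust = p_adjust)
}
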
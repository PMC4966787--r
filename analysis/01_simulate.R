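#!/usr/bin/env Rscript
# Step 1 — render the synthetic study batch.
#
# Three spread-tissue slides emulating the cell populations this pipeline is
# built for, plus the chicken-RBC standard smear processed with the same
# optics:
#   artery    — adult calcified-artery-like slide: a diploid (2C = 6 pg)
#               population of round and cigar-shaped (smooth-muscle) nuclei
#               with a few hollow bell-shaped metakaryotic forms;
#   femur     — fetal-bone-like slide: multinucleated osteoclast-like
#               clusters at 2-3 pg per member nucleus among diploid cells;
#   chondroid — fetal cartilage-like slide: syncytial chains at 1-2 pg per
#               member nucleus among a few diploid cells.
# Images (16-bit TIFF, binary) go to scratch/; ground-truth tables to
# results/.

suppressMessages(library(feulgen))

img_dir <- "scratch/analysis/images"
dir.create("results", showWarnings = FALSE)

cfg <- default_config()
cfg$seed <- 20260930L %% 100000L
cfg$simulate$image_shape <- c(1700L, 1700L)
cfg$simulate$n_standard <- 200L
cfg$simulate$samples <- list(
  list(sample_id = "artery",
       populations = list(
         list(mean_pg = 6.0, sd_pg = 1.5, count = 70L, shape_class = "ellipse"),
         list(mean_pg = 6.0, sd_pg = 1.5, count = 20L, shape_class = "cigar"),
         list(mean_pg = 6.0, sd_pg = 1.5, count = 5L, shape_class = "bell"))),
  list(sample_id = "femur",
       populations = list(
         list(mean_pg = 2.5, sd_pg = 0.4, count = 60L,
              shape_class = "multinucleated"),
         list(mean_pg = 6.0, sd_pg = 1.0, count = 25L,
              shape_class = "ellipse"))),
  list(sample_id = "chondroid",
       populations = list(
         list(mean_pg = 1.5, sd_pg = 0.3, count = 60L,
              shape_class = "syncytium"),
         list(mean_pg = 6.0, sd_pg = 1.0, count = 10L,
              shape_class = "ellipse"))))

idx <- run_simulate(cfg, img_dir)
print(idx)
for (i in seq_len(nrow(idx))) {
  truth <- read.csv(idx$truth[i])
  file.copy(idx$truth[i],
            file.path("results", basename(idx$truth[i])), overwrite = TRUE)
  cat(sprintf("%-9s %3d nuclei, %5.2f pg mean true DNA\n",
              idx$sample_id[i], nrow(truth), mean(truth$true_pg)))
}
cat("images in", img_dir, "- ground truth copied to results/\n")
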
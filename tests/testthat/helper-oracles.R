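# Independent brute-force statistic oracles (loop/moment formulas written
# from first principles, never calling the package or the estimator
# functions the package uses).

oracle_mean <- function(x) sum(x) / length(x)

oracle_sd <- function(x) {
  m <- oracle_mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# adjusted Fisher-Pearson skewness G1
oracle_skewness <- function(x) {
  n <- length(x); m <- oracle_mean(x)
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# bias-corrected excess kurtosis G2
oracle_kurtosis <- function(x) {
  n <- length(x); m <- oracle_mean(x)
  m2 <- sum((x - m)^2) / n
  m4 <- sum((x - m)^4) / n
  g2 <- m4 / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

# loop-based IOD / per-pixel SD over a mask, one pixel at a time
oracle_iod <- function(od, mask) {
  s <- 0
  for (i in seq_len(nrow(od))) for (j in seq_len(ncol(od)))
    if (mask[i, j]) s <- s + od[i, j]
  s
}

# construct a vector with exact mean and SD
vector_with <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# minimal od_image + label_map pair around a given OD matrix/label matrix
make_label_map <- function(labels, flagged = NULL) {
  n <- max(labels)
  fl <- data.frame(label = seq_len(n),
                   area_px = tabulate(labels[labels > 0], nbins = n),
                   border_touching = logical(n), under_min_area = logical(n),
                   over_max_area = logical(n), merged_suspect = logical(n))
  fl$flagged <- logical(n)
  if (!is.null(flagged)) fl$flagged[flagged] <- TRUE
  structure(list(labels = labels, threshold = NA_real_, flags = fl),
            class = "label_map")
}

# nearest-truth matching: for each measured nucleus the index of the closest
# ground-truth centroid
match_truth <- function(measured, truth) {
  vapply(seq_len(nrow(measured)), function(i)
    which.min((truth$centroid_row - measured$centroid_row[i])^2 +
              (truth$centroid_col - measured$centroid_col[i])^2), integer(1))
}

# a small clean slide spec for fast tests
tiny_spec <- function(image_shape = c(512L, 512L), noise_sd = 0,
                      stain_cv = 0, area_cv = 0, seed = 42, ...) {
  slide_spec(image_shape = image_shape, noise_sd = noise_sd,
             stain_cv = stain_cv, area_cv = area_cv, seed = seed, ...)
}
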
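# Descriptive statistics, pooling, group comparison, correlation,
# fold histograms and the qPCR Ct utilities.

test_that("describe_sample matches brute-force oracles to 1e-10", {
  for (seed in 1:5) {
    set.seed(seed)
    pg <- stats::rlnorm(200, log(5), 0.4)
    ar <- stats::rlnorm(200, log(50), 0.5)
    s <- describe_sample(pg, ar, "x")
    expect_equal(s$mean_pg, oracle_mean(pg), tolerance = 1e-10)
    expect_equal(s$sd_pg, oracle_sd(pg), tolerance = 1e-10)
    expect_equal(s$skewness, oracle_skewness(pg), tolerance = 1e-10)
    expect_equal(s$kurtosis, oracle_kurtosis(pg), tolerance = 1e-10)
    expect_equal(s$cv_area, 100 * oracle_sd(ar) / oracle_mean(ar),
                 tolerance = 1e-10)
    expect_equal(s$se_area, oracle_sd(ar) / sqrt(200), tolerance = 1e-10)
    expect_equal(s$dcv, 100 * oracle_sd(pg) / oracle_mean(pg),
                 tolerance = 1e-10)
    expect_equal(c(s$ci95_lo, s$ci95_hi),
                 oracle_mean(ar) + c(-1.96, 1.96) * oracle_sd(ar) / sqrt(200),
                 tolerance = 1e-10)
  }
})

test_that("a sample with the fetal-femur area moments prints CV 53.9% and
           SE 2.1", {
  areas <- vector_with(145, 46.9, 25.3)
  s <- describe_sample(rep(3.1, 145), areas)
  expect_equal(round(s$cv_area, 1), 53.9)
  expect_equal(round(s$se_area, 1), 2.1)
})

test_that("a constant sample degenerates gracefully", {
  s <- describe_sample(rep(6, 20), rep(60, 20))
  expect_equal(s$sd_pg, 0)
  expect_equal(s$dcv, 0)
  expect_equal(s$cv_area, 0)
  expect_equal(s$skewness, 0)
  expect_true(s$degenerate)
})

test_that("shape statistics are unbiased on a large symmetric sample", {
  set.seed(202)
  x <- stats::rnorm(1e5)
  s <- describe_sample(x, abs(x) + 1)
  expect_lt(abs(s$skewness), 0.05)
  expect_lt(abs(s$kurtosis), 0.1)
})

test_that("pooling summary rows equals describing the concatenated raw data", {
  set.seed(31)
  raw <- lapply(1:4, function(i)
    list(pg = stats::rlnorm(30 + 10 * i, log(4), 0.3),
         ar = stats::rlnorm(30 + 10 * i, log(60), 0.4)))
  rows <- do.call(rbind, lapply(seq_along(raw), function(i)
    describe_sample(raw[[i]]$pg, raw[[i]]$ar, paste0("s", i))))
  pooled <- pool_samples(rows)
  direct <- describe_sample(unlist(lapply(raw, `[[`, "pg")),
                            unlist(lapply(raw, `[[`, "ar")), "Total")
  for (f in c("n", "mean_pg", "sd_pg", "mean_area_um2", "sd_area",
              "cv_area", "se_area", "ci95_lo", "ci95_hi", "dcv"))
    expect_equal(pooled[[f]], direct[[f]], tolerance = 1e-12)
})

test_that("pooling two identical samples reproduces the single-sample row", {
  r <- describe_sample(vector_with(50, 5, 1.2, seed = 4),
                       vector_with(50, 55, 20, seed = 5))
  pooled <- pool_samples(rbind(r, r))
  expect_equal(pooled$mean_area_um2, r$mean_area_um2)
  # with n-1 denominators the pooled SD carries the exact combined
  # degrees-of-freedom factor sqrt((2n-2)/(2n-1))
  expect_equal(pooled$sd_area, r$sd_area * sqrt(98 / 99), tolerance = 1e-12)
  expect_equal(pooled$n, 2 * r$n)
})

test_that("Kruskal-Wallis H and p come from the tie-corrected test and Dunn
           agrees with it for two groups", {
  set.seed(77)
  g <- list(a = round(stats::rnorm(40, 5), 1), b = round(stats::rnorm(30, 5.5), 1))
  cmp <- compare_groups(g)
  kw <- stats::kruskal.test(c(g$a, g$b), factor(rep(c("a", "b"), c(40, 30))))
  expect_equal(cmp$H, unname(kw$statistic))
  expect_equal(cmp$p, kw$p.value)
  # with k = 2 the Dunn z on pooled ranks satisfies z^2 = H
  expect_equal(cmp$pairwise$z^2, cmp$H, tolerance = 1e-10)
  expect_equal(nrow(cmp$pairwise), 1)
})

test_that("group comparison has power under a 3 pg shift and is null-safe", {
  set.seed(88)
  a <- stats::rnorm(100, 3, 1); b <- stats::rnorm(100, 6, 1)
  expect_lt(compare_groups(list(a = a, b = b))$p, 0.05)
  const <- compare_groups(list(a = rep(2, 10), b = rep(2, 15)))
  expect_equal(const$H, 0)
  expect_error(compare_groups(list(a = 1:3, b = numeric())), "empty")
})

test_that("the Kruskal-Wallis p is invariant under monotone transforms", {
  set.seed(91)
  g <- list(a = stats::rlnorm(25), b = stats::rlnorm(30, 0.3),
            c = stats::rlnorm(20, -0.2))
  p1 <- compare_groups(g)$p
  p2 <- compare_groups(lapply(g, function(x) exp(2 * x)))$p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("DNA-area correlation behaves at both extremes", {
  pg <- seq(1, 8, length.out = 40)
  expect_equal(dna_area_correlation(pg, 10.4 * pg)$r2, 1.0)
  set.seed(101)
  out <- dna_area_correlation(stats::rnorm(1000, 6), stats::rnorm(1000, 60))
  expect_lt(abs(out$r), 0.1)
  expect_error(dna_area_correlation(rep(2, 10), stats::rnorm(10)), "variance")
})

test_that("fold histograms find ploidy modes and judge modality", {
  set.seed(110)
  pure <- pg_to_fold_c(stats::rnorm(500, 6, 0.6))
  h <- fold_histogram(pure)
  expect_true(h$unimodal)
  expect_equal(h$modal_fold, 2, tolerance = 0.25)
  mix <- pg_to_fold_c(c(stats::rnorm(400, 6, 0.4), stats::rnorm(250, 12, 0.5)))
  h2 <- fold_histogram(mix)
  expect_false(h2$unimodal)
  expect_equal(length(h2$modes), 2)
  expect_equal(sort(h2$modes), c(2, 4), tolerance = 0.3)
  skewed <- stats::rexp(800, 0.4)^1.5
  h3 <- fold_histogram(skewed)
  expect_false(h3$near_gaussian)
  expect_error(fold_histogram(numeric()), "empty")
})

test_that("Ct replicate summaries and delta-Ct reproduce the qPCR table", {
  fb_gusb <- replicate_summary(c(37.06, 37.50, 37.45))
  expect_equal(unname(fb_gusb["mean"]), 37.34)
  expect_equal(unname(fb_gusb["sd"]), 0.24)
  osx <- replicate_summary(c(38.42, 38.63, 38.51))
  expect_equal(unname(osx["mean"]), 38.52)
  # the replicate SD is 0.1054; half-up rounding reports 0.11
  expect_equal(unname(osx["sd"]), 0.11)
  expect_equal(replicate_summary(c(5, 5)), c(mean = 5, sd = 0))
  expect_equal(delta_ct(osx["mean"], fb_gusb["mean"]), c(mean = 1.18))
  expect_equal(delta_ct(7, 7), 0)
  expect_equal(delta_ct(35.34, 30.24), 5.10)
})
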
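# Descriptive and inferential statistics for image-cytometry samples:
# per-sample Table-style summaries, pooled statistics, Kruskal-Wallis with
# Dunn post tests, DNA-area correlation, fold-C histograms, and the small
# qPCR Ct utilities.

# Adjusted Fisher-Pearson skewness (G1) and bias-corrected excess kurtosis
# (G2): e1071 "type 2" estimators, the convention of SAS/SPSS. For a
# zero-variance sample they are reported as 0 with a `degenerate` flag.
sample_skewness <- function(x) {
  if (length(x) < 3 || stats::sd(x) == 0) return(NA_real_)
  e1071::skewness(x, type = 2)
}
sample_kurtosis <- function(x) {
  if (length(x) < 4 || stats::sd(x) == 0) return(NA_real_)
  e1071::kurtosis(x, type = 2)
}

#' Summarise one cytometry sample
#'
#' Computes the descriptive row reported per sample: n, skewness, kurtosis,
#' mean DNA content +/- SD, mean nuclear area +/- SD, the area coefficient
#' of variation, standard error and 95% confidence interval, and the DNA
#' content variation (DCV = 100 * SD(pg) / mean(pg)). CV/SE/CI are computed
#' on nuclear areas (the convention the per-sample tables follow) and DCV on
#' DNA mass; both are reported. The CI uses the normal multiplier 1.96.
#'
#' @param pg Per-nucleus DNA content, pg.
#' @param areas Per-nucleus nuclear area, um^2 (same length as `pg`).
#' @param sample_id Sample label.
#' @return A one-row data frame of class `sample_summary`: `sample_id`, `n`,
#'   `skewness`, `kurtosis` (excess, on pg), `mean_pg`, `sd_pg`, `dcv`,
#'   `mean_area_um2`, `sd_area`, `cv_area`, `se_area`, `ci95_lo`, `ci95_hi`,
#'   `degenerate`. With n < 2 the SD-based fields are `NA`; a zero-variance
#'   sample reports skewness/kurtosis as 0 with `degenerate = TRUE`.
#' @export
describe_sample <- function(pg, areas, sample_id = "sample") {
  stopifnot(length(pg) == length(areas), length(pg) >= 1)
  n <- length(pg)
  degen <- n >= 2 && (stats::sd(pg) == 0)
  sk <- sample_skewness(pg); ku <- sample_kurtosis(pg)
  if (degen) { sk <- 0; ku <- 0 }
  sd_pg <- if (n >= 2) stats::sd(pg) else NA_real_
  sd_a <- if (n >= 2) stats::sd(areas) else NA_real_
  m_pg <- mean(pg); m_a <- mean(areas)
  se_a <- sd_a / sqrt(n)
  out <- data.frame(
    sample_id = sample_id, n = n,
    skewness = sk, kurtosis = ku,
    mean_pg = m_pg, sd_pg = sd_pg,
    dcv = if (m_pg > 0) 100 * sd_pg / m_pg else NA_real_,
    mean_area_um2 = m_a, sd_area = sd_a,
    cv_area = if (m_a > 0) 100 * sd_a / m_a else NA_real_,
    se_area = se_a,
    ci95_lo = m_a - 1.96 * se_a, ci95_hi = m_a + 1.96 * se_a,
    degenerate = degen)
  class(out) <- c("sample_summary", "data.frame")
  out
}

#' Pool per-sample summaries into a combined row
#'
#' Combines k summaries exactly as if the raw data had been concatenated:
#' pooled n is the total count, pooled mean the count-weighted mean, and the
#' pooled SD comes from the combined sum of squares
#' `[sum (n_i - 1) s_i^2 + sum n_i (xbar_i - xbar)^2] / (N - 1)`. SE and the
#' 95% CI are recomputed from the pooled values. Shape statistics
#' (skewness/kurtosis) are not poolable from second moments and are `NA`.
#'
#' @param summaries A data frame of `sample_summary` rows (>= 2), or a data
#'   frame with columns `n`, `mean_pg`, `sd_pg`, `mean_area_um2`, `sd_area`.
#' @param sample_id Label for the pooled row (default "Total").
#' @return A one-row `sample_summary`.
#' @export
pool_samples <- function(summaries, sample_id = "Total") {
  stopifnot(nrow(summaries) >= 2)
  pool1 <- function(n, m, s) {
    N <- sum(n)
    mm <- sum(n * m) / N
    ss <- sum((n - 1) * s^2) + sum(n * (m - mm)^2)
    c(N = N, mean = mm, sd = sqrt(ss / (N - 1)))
  }
  pa <- pool1(summaries$n, summaries$mean_area_um2, summaries$sd_area)
  has_pg <- all(is.finite(summaries$mean_pg)) && all(is.finite(summaries$sd_pg))
  pp <- if (has_pg) pool1(summaries$n, summaries$mean_pg, summaries$sd_pg)
        else c(N = pa[["N"]], mean = NA_real_, sd = NA_real_)
  N <- pa[["N"]]
  se_a <- pa[["sd"]] / sqrt(N)
  out <- data.frame(
    sample_id = sample_id, n = as.integer(N),
    skewness = NA_real_, kurtosis = NA_real_,
    mean_pg = pp[["mean"]], sd_pg = pp[["sd"]],
    dcv = if (has_pg) 100 * pp[["sd"]] / pp[["mean"]] else NA_real_,
    mean_area_um2 = pa[["mean"]], sd_area = pa[["sd"]],
    cv_area = 100 * pa[["sd"]] / pa[["mean"]],
    se_area = se_a,
    ci95_lo = pa[["mean"]] - 1.96 * se_a, ci95_hi = pa[["mean"]] + 1.96 * se_a,
    degenerate = FALSE)
  class(out) <- c("sample_summary", "data.frame")
  out
}

#' Compare DNA content between samples (Kruskal-Wallis + Dunn)
#'
#' Tie-corrected Kruskal-Wallis H with its chi-square p value
#' (via [stats::kruskal.test()]), followed by Dunn's post tests: pairwise z
#' statistics on the pooled ranks,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with the
#' tie term `T = sum(t^3 - t) / (12 (N - 1))`. P-value adjustment is
#' configurable (none by default).
#'
#' @param groups Named list of numeric vectors (one per sample, each n >= 1,
#'   at least 2 groups).
#' @param alpha Significance level recorded in the result.
#' @param p_adjust Method passed to [stats::p.adjust()] ("none",
#'   "bonferroni", "holm", ...).
#' @return A `group_comparison`: `H`, `df`, `p`, `alpha`, `p_adjust` and
#'   `pairwise`, a data frame with one row per unordered pair (`group1`,
#'   `group2`, `z`, `p_raw`, `p_adj`, `significant`).
#' @export
compare_groups <- function(groups, alpha = 0.05, p_adjust = "none") {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) == 0)) stop("empty group")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  N <- length(x)
  if (stats::var(x) == 0) {
    kw <- list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
               parameter = c(df = length(groups) - 1), p.value = 1)
  } else {
    kw <- stats::kruskal.test(x, g)
  }
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n_g <- tabulate(g)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(levels(g), 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- match(pairs[1, k], levels(g)); j <- match(pairs[2, k], levels(g))
    se <- sqrt(v0 * (1 / n_g[i] + 1 / n_g[j]))
    z[k] <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    p_raw[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  p_adj <- stats::p.adjust(p_raw, method = p_adjust)
  structure(list(
    H = unname(kw$statistic), df = unname(kw$parameter),
    p = kw$p.value, alpha = alpha, p_adjust = p_adjust,
    pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                          z = z, p_raw = p_raw, p_adj = p_adj,
                          significant = p_adj < alpha)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.3g\n",
              x$H, x$df, x$p))
  cat(sprintf("Dunn post tests (%s adjustment, alpha = %g):\n",
              x$p_adjust, x$alpha))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Correlation between DNA content and nuclear area
#'
#' Pearson correlation between per-nucleus DNA mass and nuclear area, with
#' r^2 and the two-sided p value — the check that nuclear structure is
#' preserved (nuclear size directly proportional to DNA content).
#'
#' @param pg,area_um2 Paired per-nucleus values (n >= 3).
#' @return List with `r`, `r2`, `p`, `n`.
#' @export
dna_area_correlation <- function(pg, area_um2) {
  stopifnot(length(pg) == length(area_um2), length(pg) >= 3)
  if (stats::sd(pg) == 0 || stats::sd(area_um2) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(pg, area_um2, method = "pearson")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = length(pg))
}

#' Histogram of fold-C DNA content with a unimodality check
#'
#' Bins fold-C values at a fixed bin width, locates modes (local maxima of
#' the binned counts with at least 10% of the peak count) and flags a
#' near-Gaussian distribution when |skewness| <= `max_abs_skew` and
#' |excess kurtosis| <= `max_abs_kurt`.
#'
#' @param fold Fold-C values (nonempty).
#' @param bin_width Histogram bin width in fold-C units.
#' @param max_abs_skew,max_abs_kurt Near-Gaussian thresholds (defaults 2
#'   and 3; configurable, not canonical).
#' @return List with `breaks`, `mids`, `counts`, `modal_fold` (midpoint of
#'   the tallest bin), `modes` (midpoints of all detected modes),
#'   `unimodal`, `skewness`, `kurtosis`, `near_gaussian`.
#' @export
fold_histogram <- function(fold, bin_width = 0.25,
                           max_abs_skew = 2, max_abs_kurt = 3) {
  if (length(fold) == 0) stop("empty input")
  stopifnot(bin_width > 0)
  lo <- floor(min(fold) / bin_width) * bin_width
  hi <- ceiling(max(fold) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  counts <- as.integer(table(cut(fold, breaks, include.lowest = TRUE,
                                 right = FALSE)))
  mids <- breaks[-length(breaks)] + bin_width / 2
  nb <- length(counts)
  pad <- c(-1L, counts, -1L)
  # strictly above the left neighbour, at least the right: a plateau counts
  # once, at its first bin
  is_mode <- vapply(seq_len(nb), function(i)
    counts[i] > pad[i] && counts[i] >= pad[i + 2] &&
      counts[i] >= 0.1 * max(counts), logical(1))
  sk <- sample_skewness(fold); ku <- sample_kurtosis(fold)
  list(breaks = breaks, mids = mids, counts = counts,
       modal_fold = mids[which.max(counts)],
       modes = mids[is_mode],
       unimodal = sum(is_mode) == 1,
       skewness = sk, kurtosis = ku,
       near_gaussian = is.finite(sk) && is.finite(ku) &&
         abs(sk) <= max_abs_skew && abs(ku) <= max_abs_kurt)
}

#' Summarise a qPCR replicate set
#'
#' Arithmetic mean and n-1 SD of threshold-cycle (Ct) replicates, reported
#' to 2 decimals as Ct values conventionally are.
#'
#' @param ct Numeric vector of Ct replicates (>= 2).
#' @return Named vector `c(mean, sd)`, rounded to 2 decimals.
#' @export
replicate_summary <- function(ct) {
  stopifnot(length(ct) >= 2, all(is.finite(ct)))
  c(mean = round(mean(ct), 2), sd = round(stats::sd(ct), 2))
}

#' Delta-Ct relative expression
#'
#' `delta Ct = mean Ct(target) - mean Ct(reference)`; the reference is a
#' housekeeping gene (e.g. GUSB).
#'
#' @param mean_ct_target,mean_ct_reference Mean Ct values.
#' @return The delta-Ct difference.
#' @export
delta_ct <- function(mean_ct_target, mean_ct_reference) {
  stopifnot(is.finite(mean_ct_target), is.finite(mean_ct_reference))
  mean_ct_target - mean_ct_reference
}
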
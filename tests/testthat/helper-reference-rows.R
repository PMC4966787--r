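# Published per-sample descriptive statistics of the seven-sample
# adult/fetal spread-tissue Feulgen series (plus its printed pooled row and
# the cRBC standard row), used as inputs when validating the descriptive and
# pooling arithmetic. Columns: nuclei count, skewness, excess kurtosis, DNA
# content mean/SD (pg), nuclear area mean/SD (um^2), printed CV (%), SE
# (um^2) and 95% CI bounds (um^2).
reference_rows <- data.frame(
  sample_id = c("adult_hard_1", "adult_soft_2", "adult_soft_3",
                "adult_soft_4", "fetus_hard_5", "fetus_hard_6",
                "fetus_soft_7"),
  n = c(137L, 306L, 48L, 92L, 145L, 46L, 120L),
  skewness = c(0.4, 1.1, 1.4, 0.6, 1.6, 1.5, 1.1),
  kurtosis = c(-0.6, 1.8, 2.8, 0.5, 2.7, 1.7, 0.5),
  mean_pg = c(6.0, 4.3, 5.6, 7.0, 3.1, 1.7, 4.8),
  sd_pg = c(3.1, 2.1, 2.2, 2.8, 1.6, 0.9, 2.4),
  mean_area_um2 = c(72.7, 57.5, 66.1, 68.4, 46.9, 31.4, 63.8),
  sd_area = c(36.9, 25.9, 24.7, 27.4, 25.3, 16.8, 32.7),
  cv_printed = c(50.8, 45.2, 36.8, 0.4, 53.9, 53.5, 51.2),
  se_printed = c(3.2, 1.5, 3.5, 2.9, 2.1, 2.5, 2.9),
  ci_lo = c(66.5, 54.6, 59.0, 62.7, 42.7, 26.4, 57.9),
  ci_hi = c(79.0, 60.4, 73.1, 74.1, 51.0, 36.3, 69.7))

reference_total <- list(n = 894L, mean_area_um2 = 59.2, sd_area = 30.2,
                        cv = 51.1, se = 1.0, ci_lo = 57.2, ci_hi = 61.2)
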
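---
title: "Feulgen image densitometry: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feulgen image densitometry: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feulgen)
```

## The measurement model

The Feulgen reaction binds a Schiff-type dye to DNA stoichiometrically and
stains nothing else, so the mass of bound dye in a nucleus is proportional to
its DNA mass. Under transmitted light, dye absorbs according to
Beer–Lambert: a pixel that receives intensity $I$ against a clear-glass
reference $I_0$ has transmittance $T = I/I_0$ and optical density

$$\mathrm{OD} = \log_{10}(1/T).$$

Chromatin is heterogeneous, so a single-point OD is not representative of a
nucleus; the quantity that tracks total DNA is the *integrated* optical
density over the whole nuclear footprint,

$$\mathrm{IOD} = \sum_{i=1}^{n} \log_{10}(1/T_i),$$

together with the densitometric area ($n$ pixels, converted to µm² through
the areal scale, 95.04 px/µm² by default) and the densitometric standard
deviation (the per-pixel OD SD inside the mask, $n-1$ denominator). These
three quantities per nucleus are exactly what `measure_nuclei()` reports.
No background is subtracted inside the mask beyond the white-reference
normalisation: IOD is defined as the plain summed log-ratio.

## Internal-standard calibration

IOD is in arbitrary absorbance units; an internal standard of nucleated
chicken red blood cells converts it to picograms. cRBC nuclei carry a
constant diploid DNA mass of 2C = 2.5 pg (1C = 1.25 pg), so a smear
processed in the same staining batch anchors a one-point standard curve
through the origin:

$$\mathrm{DNA\ pg} = \frac{2.5\ \mathrm{pg}}{\overline{\mathrm{IOD}}_{\mathrm{standard}}} \times \mathrm{IOD}_{\mathrm{sample}}.$$

`fit_standard()` stores the curve points so a multi-standard line through
the origin remains possible, but quantification uses the single-ratio
formula. Two consequences are worth internalising: the conversion is exactly
linear (so fold-differences in IOD are fold-differences in pg), and any
global change of staining intensity cancels between sample and standard —
doubling the stain deposits twice the absorbance on both, leaving recovered
pg unchanged. Results are expressed as fold of the haploid C-value
(`pg_to_fold_c()`; human 1C = 3 pg, so a diploid nucleus sits at fold 2).

The standard also carries quality control: its IOD coefficient of variation
(typically ~23% in well-stained batches) is reported by `fit_standard()`,
and a floor of 10 unflagged standard nuclei (configurable) guards against
underpowered calibrations.

## What the synthetic-slide generator emulates

No raw microscope data ship with this package; every pipeline stage is
instead exercised on synthetic slides with known ground truth
(`slide_spec()`, `render_slide()`, `render_standard_smear()`). The forward
model is the measurement model run in reverse:

* each nucleus deposits total absorbance `stain_factor * true_pg`
  (OD·px per pg; default 300), distributed over its footprint by a smooth
  centre-weighted chromatin profile (1.5 at the centre to 0.5 at the rim,
  normalised per nucleus) so the densitometric SD is nonzero; for hollow
  bell-shaped nuclei the profile peaks mid-annulus;
* the camera sees `I = i0 * illumination * 10^(-A) + noise`, with additive
  Gaussian intensity noise (default SD 50 on `i0 = 10000`) clipped to
  `[0, i0]`, and an optional low-order illumination gradient;
* nuclear area is proportional to DNA content (`area_per_pg`, default
  10.36 µm²/pg so a 2.5 pg cRBC nucleus spreads to ~25.9 µm², and a 6 pg
  diploid human nucleus to ~62 µm²) with a 12% lognormal scatter;
* per-nucleus staining efficiency varies as a mean-one lognormal with
  CV `stain_cv = 0.23`. This is the generator's account of the ~23% IOD CV
  observed on real cRBC standards, whose true DNA content is constant: the
  spread must come from staining stoichiometry and chromatin packing, not
  from DNA. It applies to sample nuclei as well, since they pass through
  the same reaction. `true_pg` in the ground-truth table is unaffected;
  the deposited absorbance including the jitter is recorded separately as
  `true_iod`, which lets tests separate generation noise from measurement
  error;
* shape classes stress segmentation with the nuclear forms spread
  preparations contain: near-round ellipses (eccentricity ≤ 0.6), elongated
  cigar-shaped smooth-muscle nuclei (eccentricity ≥ 0.9), hollow bell
  (metakaryotic) templates, syncytial chains of 4–10 member nuclei and
  multinucleated osteoclast-like clusters of 2–20. Group members are spaced
  by their largest semi-axis so footprints stay disjoint; no claim of
  biological realism is made beyond these geometries.

Nuclei are placed uniformly at random without overlap (≥ 2 px gap, 1 px
halo); a nucleus that cannot be placed within the retry budget is skipped
with a warning and omitted from the truth table, and a footprint larger
than the image is an error. With zero noise, flat illumination and
`stain_cv = 0`, the rendered integrated OD of a nucleus equals
`stain_factor * true_pg` exactly, because the chromatin profile is
normalised per nucleus — this identity is the linearity oracle the tests
lean on.

What the generator does *not* emulate — and what passing tests therefore do
not show about real slides: overlapping or folded nuclei, out-of-focus
blur, glare and vignetting beyond a linear gradient, shot noise (not
identifiable from densitometry summaries alone), real chromatin texture,
debris and stain precipitate, and fixation artefacts. Segmentation accuracy
on clean synthetic slides (100% recall/precision in the tests) is an upper
bound, not a field estimate.

## From image to measurements

`estimate_white_reference()` takes the median of the pixels in the top
decile of the intensity range — robust as long as a reasonable fraction of
the image is clear background; a fully dark image is an error, a saturated
one a warning. `transmittance_to_od()` clamps transmittance to
`[t_floor, 1]` with `t_floor = 1e-3` (OD cap 3.0) so glare-free dark pixels
do not produce infinite absorbance.

`segment_nuclei()` in auto mode uses Otsu's threshold on the OD histogram
to find seed pixels, then floods the foreground out to a weak threshold
just above the background OD noise (≥ 0.02 OD, hysteresis). The weak pass
matters: on a dark-foreground/clear-background OD image a single Otsu cut
systematically shaves the rims of weakly stained nuclei. On synthetic
slides, a single cut captured as little as 36% of a faint nucleus's
absorbance and inflated the standard's IOD CV from 23% to 29%; with
hysteresis, measured IOD over deposited absorbance is 1.000 across all
populations. A user-supplied `od_threshold` is applied as a plain single
cut for reproducibility of explicit settings.

Components are QC-flagged rather than silently dropped: `border_touching`
(clipped footprints underestimate IOD), `under_min_area` (default 8 µm²,
debris), `over_max_area` (default 400 µm², clumps — sample means in spread
preparations run 25.9–72.7 µm²), and `merged_suspect` (the component would
watershed into ≥ 2 plausible nuclei). Flagged labels are excluded from
measurement by default. Watershed splitting of touching nuclei is opt-in
(`split_touching`), because spread preparations are monolayers by design.
Coordinates are 0-based row/column pixel centres; areas are whole-pixel
counts.

## Statistics layer

`describe_sample()` reports the conventional per-sample row: n, skewness,
kurtosis, mean DNA pg ± SD, mean area ± SD, CV, SE and 95% CI. Conventions,
chosen once and recorded here:

* the printed CV/SE/CI columns of such tables track the *area* statistics
  (SD(area)/mean(area) reconciles with published rows; e.g. 25.3/46.9 →
  53.9%), while "DNA content variation" is the CV of per-nucleus pg — the
  package reports both (`cv_area`, `dcv`) and claims neither as the other;
* skewness is the adjusted Fisher–Pearson $G_1$ and kurtosis the
  bias-corrected excess $G_2$ (the SAS/SPSS convention, e1071 type 2); the
  convention behind any particular published table is generally
  unverifiable without raw data, so it is stated in the output metadata;
* the 95% CI uses the normal multiplier 1.96, which reproduces published
  pooled intervals, not a t quantile;
* `pool_samples()` combines rows by the exact combined sum of squares
  $[\sum(n_i-1)s_i^2 + \sum n_i(\bar x_i - \bar x)^2]/(N-1)$, so pooling
  per-sample statistics is identical to describing the concatenated raw
  data; skewness/kurtosis are not poolable from second moments and are NA
  in pooled rows;
* `compare_groups()` takes tie-corrected Kruskal–Wallis H and p from
  `stats::kruskal.test()` and computes Dunn's pairwise z on pooled ranks
  with the tie term $\sum(t^3-t)/(12(N-1))$; p-adjustment defaults to
  "none" (Bonferroni/Holm by flag), matching the common practice of
  reporting unadjusted Dunn post tests;
* `fold_histogram()` flags near-Gaussian distributions at |skewness| ≤ 2
  and |excess kurtosis| ≤ 3 — invented, configurable thresholds, not
  canonical ones;
* Ct replicate summaries round to 2 decimals (the convention for reported
  threshold cycles) before ΔCT differences are taken, which is how
  published ΔCT values reconcile.

## Numerical and degenerate-input choices

Zero-variance samples report skewness/kurtosis as 0 with a `degenerate`
flag; single-pixel labels report `od_sd = 0`; an empty foreground is a
warning ("acellular"), not an error; a missing standard is an error, since
calibration is impossible. Histogram plateaus count as one mode, at their
first bin. All randomness flows from a single integer seed per spec;
identical spec and seed reproduce images and truth tables bit for bit,
with the caller's RNG state restored afterwards.

## Problem sizes

The test-suite and acceptance runs use sizes chosen to make sampling error
small relative to the tolerances while keeping a default run comfortably
interactive: standard smears of 200 nuclei (the scale of real standard
series), sample slides of 140–200 nuclei at 1600–2400 px square, five
replicate mixture slides for the population-recovery property, and 1000
null simulations for the Kruskal–Wallis type-I-error check. At these sizes
the staining-jitter contribution to a 200-nucleus mean is ~1.6% (0.23/√200),
which is why the end-to-end recovery tolerance of 3% is attainable and why
recovery checks on ~50-nucleus groups are asserted in SE units rather than
as fixed percentages.

## Known limitations

The calibration assumes sample and standard share one staining batch;
per-slide spiked standards are not modelled, and batch matching is the
caller's responsibility. Segmentation has no declumping beyond the opt-in
watershed and no focus/blur model. The white-reference estimator needs
visible background (≥ ~20% of pixels is safe). The bell/syncytium/
multinucleated geometries are segmentation stress shapes, not morphometric
models of metakaryotic biology. And the fold-C mode finder is a binned
local-maximum detector: with small samples and narrow bins it will report
shot-noise modes, so choose `bin_width` with the sample size in mind.
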
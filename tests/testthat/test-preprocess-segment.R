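# OD transform, white-reference estimation and nucleus segmentation.

test_that("white reference is the background level", {
  expect_equal(estimate_white_reference(matrix(10000, 20, 20)), 10000)
  expect_error(estimate_white_reference(matrix(0, 20, 20)), "no background")
  expect_warning(
    est <- estimate_white_reference(tl_image(matrix(255, 8, 8), bits = 8L)),
    "saturated")
  expect_equal(est, 255)
  # on a synthetic slide the estimate lands within the noise SD of true i0
  sp <- slide_spec(image_shape = c(512L, 512L), noise_sd = 50,
                   populations = nucleus_population(6, 1, 10), seed = 3)
  r <- render_slide(sp)
  expect_lt(abs(estimate_white_reference(r$image) - 10000), 50)
})

test_that("the OD transform follows log10(1/T) with clamping", {
  img <- matrix(c(1000, 100, 0, 2000), 2, 2)
  od <- transmittance_to_od(img, white_reference = 1000, t_floor = 1e-3)
  expect_equal(od$od[1, 1], 0)          # I = I0
  expect_equal(od$od[2, 1], 1.0)        # I = I0 / 10
  expect_equal(od$od[1, 2], 3.0)        # I = 0, clamped at the floor
  expect_equal(od$od[2, 2], 0)          # brighter than the reference
  expect_true(all(od$od >= 0))
})

test_that("OD is monotone in intensity and shifts by log10(2) when the
           reference doubles", {
  I <- matrix(seq(1, 1000, length.out = 100), 10, 10)
  od1 <- transmittance_to_od(I, white_reference = 1000)$od
  expect_true(all(diff(as.vector(od1)[1:100]) <= 0))
  od2 <- transmittance_to_od(I, white_reference = 2000)$od
  unclamped <- od2 < 3  # the clamp caps the shift at the floor
  expect_equal(od2[unclamped] - od1[unclamped],
               rep(log10(2), sum(unclamped)), tolerance = 1e-12)
})

test_that("clean non-overlapping nuclei are segmented with full recall and
           precision", {
  sp <- slide_spec(image_shape = c(1600L, 1600L), noise_sd = 0, stain_cv = 0,
                   area_cv = 0.1,
                   populations = nucleus_population(6, 1, 50), seed = 17)
  r <- render_slide(sp)
  od <- transmittance_to_od(r$image)
  labs <- segment_nuclei(od)
  m <- measure_nuclei(od, labs)
  expect_equal(nrow(m), 50)                       # precision: no spurious labels
  idx <- match_truth(m, r$truth)
  expect_equal(sort(idx), 1:50)                   # recall: every nucleus found once
  # footprints recovered essentially exactly (far beyond IoU 0.8)
  expect_true(all(abs(m$area_um2 / r$truth$true_area_um2[idx] - 1) < 0.05))
  expect_true(all(sqrt((m$centroid_row - r$truth$centroid_row[idx])^2 +
                       (m$centroid_col - r$truth$centroid_col[idx])^2) < 2))
})

test_that("segmentation stays exact under default imaging noise
           (contrast >> noise)", {
  sp <- slide_spec(image_shape = c(1600L, 1600L),
                   populations = nucleus_population(6, 1, 50), seed = 18)
  r <- render_slide(sp)
  od <- transmittance_to_od(r$image)
  m <- measure_nuclei(od, segment_nuclei(od))
  expect_equal(nrow(m), 50)
  expect_equal(sort(match_truth(m, r$truth)), 1:50)
})

test_that("a blank image yields zero labels with a warning", {
  od <- transmittance_to_od(matrix(10000, 64, 64), white_reference = 10000)
  expect_warning(labs <- segment_nuclei(od), "acellular|empty")
  expect_equal(nrow(labs$flags), 0)
  expect_true(all(labs$labels == 0))
})

test_that("QC flags mark border-touching and undersized components", {
  od <- matrix(0, 100, 100)
  od[1:20, 40:60] <- 1          # clipped by the image border
  od[60:61, 60:61] <- 1         # 4 px of debris
  oi <- od_image(od, scale = 95.04)
  labs <- segment_nuclei(oi, od_threshold = 0.5)
  expect_equal(nrow(labs$flags), 2)
  expect_true(any(labs$flags$border_touching))
  expect_true(any(labs$flags$under_min_area))
  expect_true(all(labs$flags$flagged))
  # flagged labels are excluded from measurement by default
  expect_equal(nrow(measure_nuclei(oi, labs)), 0)
  expect_equal(nrow(measure_nuclei(oi, labs, include_flagged = TRUE)), 2)
})

test_that("segmentation is invariant to a common intensity rescaling", {
  sp <- tiny_spec(populations = nucleus_population(6, 0, 5), seed = 30)
  r <- render_slide(sp)
  od1 <- transmittance_to_od(r$image$intensity, white_reference = 10000)
  od2 <- transmittance_to_od(r$image$intensity * 3.7, white_reference = 37000)
  od1$scale <- od2$scale <- 95.04
  l1 <- segment_nuclei(od1); l2 <- segment_nuclei(od2)
  expect_identical(l1$labels, l2$labels)
  expect_equal(l1$flags, l2$flags)
})
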
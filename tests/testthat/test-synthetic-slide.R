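# The slide generator: Beer-Lambert rendering with per-nucleus ground truth.

test_that("a spec with no populations renders a uniform field at i0", {
  sp <- tiny_spec()
  r <- render_slide(sp)
  expect_equal(nrow(r$truth), 0)
  expect_true(all(r$image$intensity == sp$i0))
})

test_that("deposited absorbance is proportional to DNA content", {
  # noiseless renders of single nuclei: the summed OD field equals
  # stain_factor * pg, so a 1:2 pg ratio gives a 1:2 integrated-OD ratio
  total_od <- function(pg, seed) {
    sp <- tiny_spec(populations = nucleus_population(pg, 0, 1), seed = seed)
    r <- render_slide(sp)
    od <- transmittance_to_od(r$image, white_reference = sp$i0)
    sum(od$od)
  }
  expect_equal(total_od(2.5, 3), 2.5 * 300, tolerance = 1e-8)
  o1 <- total_od(3, 4); o2 <- total_od(6, 5)
  expect_equal(o2 / o1, 2, tolerance = 0.01)
})

test_that("identical spec and seed reproduce the render bit for bit", {
  sp <- slide_spec(image_shape = c(640L, 640L),
                   populations = nucleus_population(6, 1, 8), seed = 99)
  a <- render_slide(sp); b <- render_slide(sp)
  expect_identical(a$image$intensity, b$image$intensity)
  expect_identical(a$truth, b$truth)
})

test_that("truth records are unique and conserve the areal scale", {
  sp <- slide_spec(image_shape = c(700L, 700L),
                   populations = list(nucleus_population(6, 1, 10),
                                      nucleus_population(3, 0.5, 5, "cigar")),
                   seed = 21)
  r <- render_slide(sp)
  expect_equal(nrow(r$truth), 15)
  expect_false(any(duplicated(r$truth$nucleus_id)))
  # true_area_um2 * scale is an exact whole-pixel count
  px <- r$truth$true_area_um2 * sp$scale
  expect_equal(px, round(px), tolerance = 1e-9)
})

test_that("shape classes produce their structural signatures", {
  sp <- tiny_spec(populations = nucleus_population(6, 0, 1, "bell"), seed = 8)
  r <- render_slide(sp)
  od <- transmittance_to_od(r$image, white_reference = sp$i0)
  # a bell/metakaryotic nucleus is hollow: no absorbance at its centroid
  cr <- round(r$truth$centroid_row) + 1; cc <- round(r$truth$centroid_col) + 1
  expect_equal(od$od[cr, cc], 0)

  sp2 <- slide_spec(image_shape = c(900L, 900L), noise_sd = 0,
                    populations = nucleus_population(1.5, 0.3, 24, "syncytium"),
                    seed = 9)
  r2 <- render_slide(sp2)
  sizes <- table(r2$truth$group_id)
  expect_equal(sum(sizes), 24)
  expect_true(all(sizes <= 10))

  sp3 <- slide_spec(image_shape = c(900L, 900L), noise_sd = 0,
                    populations = nucleus_population(2.5, 0.4, 30,
                                                     "multinucleated"),
                    seed = 10)
  r3 <- render_slide(sp3)
  expect_true(all(table(r3$truth$group_id) <= 20))
  expect_false(any(is.na(r3$truth$group_id)))

  # group members stay disjoint: segmentation resolves every member nucleus
  for (r in list(r2, r3)) {
    od <- transmittance_to_od(r$image)
    labs <- segment_nuclei(od)
    expect_equal(nrow(labs$flags), nrow(r$truth))
    expect_false(any(labs$flags$merged_suspect))
  }
})

test_that("impossible placements fail loudly or are skipped with a warning", {
  sp <- tiny_spec(populations = nucleus_population(500, 0, 1))
  expect_error(render_slide(sp), "larger than the image")
  crowded <- slide_spec(image_shape = c(128L, 128L), noise_sd = 0,
                        populations = nucleus_population(2.5, 0, 60), seed = 2)
  warns <- testthat::capture_warnings(r <- render_slide(crowded))
  expect_true(any(grepl("skipped", warns)))
  expect_lt(nrow(r$truth), 60)
})

test_that("the standard smear carries the chicken 2C ground truth", {
  expect_error(render_standard_smear(0), "at least one")
  r1 <- render_standard_smear(1, seed = 5,
                              spec = tiny_spec(stain_cv = 0, noise_sd = 0))
  od <- transmittance_to_od(r1$image, white_reference = 10000)
  expect_equal(sum(od$od) / 300, 2.5, tolerance = 1e-8)

  r <- render_standard_smear(339, seed = 6)
  expect_equal(nrow(r$truth), 339)
  expect_true(all(r$truth$true_pg == 2.5))
  expect_equal(mean(r$truth$true_area_um2), 25.9, tolerance = 0.1)
})
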
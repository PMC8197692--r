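# Region growing, fixed 40% threshold, background estimation and COA.

make_sphere_image <- function(value_in = 10, value_bg = 1, r_mm = 8,
                              spacing = 2, box = 40) {
  les <- lesion_spec(solid_sphere(rep(box / 2, 3), r_mm), value_in, 1)
  sc <- scene_lesion_bed(les, c_bg = value_bg, margin_mm = box / 2 - r_mm)
  built <- build_scene(sc, spacing_mm = spacing)
  list(pet = volume_grid(built$activity$values, spacing),
       ct = built$pseudo_ct, truth = built$truth[[1]])
}

test_that("region growing recovers a clean lesion exactly and respects connectivity", {
  im <- make_sphere_image()
  seedv <- round(colMeans(arrayInd(which(im$truth$mask), dim(im$truth$mask))))
  gt <- segment_region_growing(im$ct, smooth_radius_vox = 0, seed_vox = seedv)
  expect_identical(gt$mask, im$truth$mask)
  expect_s3_class(gt, "seg_mask")
  expect_equal(gt$method, "gt")

  # two disjoint lesions: only the seeded one is returned
  ct2 <- im$ct
  ct2$values[1:3, 1:3, 1:3] <- 100
  gt2 <- segment_region_growing(ct2, smooth_radius_vox = 0, seed_vox = seedv)
  expect_identical(gt2$mask, im$truth$mask)
  expect_error(segment_region_growing(im$ct, seed_vox = c(1, 1, 1)),
               "outside the initialization window")
})

test_that("region growing with smoothing stays within one boundary layer of truth", {
  im <- make_sphere_image(r_mm = 10)
  seedv <- round(colMeans(arrayInd(which(im$truth$mask), dim(im$truth$mask))))
  gt <- segment_region_growing(im$ct, smooth_radius_vox = 2, seed_vox = seedv)
  grown <- phantomrad:::dilate_mask(im$truth$mask, 1)
  eroded <- !phantomrad:::dilate_mask(!im$truth$mask, 1)
  expect_true(all(gt$mask[eroded]))          # contains the eroded truth
  expect_true(all(grown[gt$mask]))           # inside the dilated truth
})

test_that("threshold40 segments a clean hot sphere exactly and scales invariantly", {
  im <- make_sphere_image(value_in = 10, value_bg = 1)
  roi <- roi_from_mask(im$truth$mask)
  s <- segment_threshold40(im$pet, roi)
  expect_identical(s$mask, im$truth$mask)
  scaled <- volume_grid(im$pet$values * 7.3, im$pet$spacing_mm)
  expect_identical(segment_threshold40(scaled, roi)$mask, s$mask)
  expect_warning(
    segment_threshold40(volume_grid(array(2, dim(im$pet$values)),
                                    im$pet$spacing_mm), roi),
    "constant")
})

test_that("threshold40 rejects the cold rim of an unblurred two-layer lesion", {
  les <- lesion_spec(solid_cylinder(c(25, 25, 25), 12, 24), c(1, 6),
                     layer_fracs = c(1, 0.5))
  sc <- scene_lesion_bed(les, c_bg = 0.1, margin_mm = 13)
  built <- build_scene(sc, spacing_mm = 2)
  pet <- volume_grid(built$activity$values, 2)
  truth <- built$truth[[1]]
  s <- segment_threshold40(pet, roi_from_mask(truth$mask))
  # T = 2.4: only the inner C_H = 6 layer survives
  inner <- truth$layer_map == 2L
  expect_identical(s$mask, inner)
  expect_lt(s$volume_ml, truth$volume_ml)
})

test_that("background estimation returns the dominant intensity mode", {
  u <- volume_grid(array(3.3, c(10, 10, 10)), 2)
  expect_equal(estimate_background(u), 3.3)
  set.seed(7)
  vals <- array(rnorm(20^3, mean = 1, sd = 0.05), c(20, 20, 20))
  lesion <- array(FALSE, c(20, 20, 20)); lesion[8:12, 8:12, 8:12] <- TRUE
  vals[lesion] <- 10
  bg <- estimate_background(volume_grid(pmax(vals, 0), 2), exclusion = lesion)
  expect_gt(bg, 0.97); expect_lt(bg, 1.03)
})

test_that("COA threshold follows the hand-computed contrast model", {
  im <- make_sphere_image(value_in = 10, value_bg = 1)
  roi <- roi_from_mask(im$truth$mask)
  s <- segment_coa(im$pet, roi, coa_params(0.5, 0.5), bg = 1)
  # I70 = 10, T = 5.5 -> exactly the sphere
  expect_identical(s$mask, im$truth$mask)
  # bg = 0, a = 0.4 degenerates to a 40%-of-I70 threshold
  s2 <- segment_coa(im$pet, roi, coa_params(0.4, 0), bg = 0)
  s40 <- segment_threshold40(im$pet, roi)
  expect_identical(s2$mask, s40$mask)
  # joint scale invariance
  scaled <- volume_grid(im$pet$values * 3, im$pet$spacing_mm)
  s3 <- segment_coa(scaled, roi, coa_params(0.5, 0.5), bg = 3)
  expect_identical(s3$mask, s$mask)
  # threshold above the maximum: per-lesion error, catchable
  expect_error(segment_coa(im$pet, roi, coa_params(1, 0), bg = 0),
               class = "phantomrad_empty_mask")
})

test_that("recovery coefficient is a plain volume ratio", {
  a <- list(volume_ml = 8)
  b <- list(volume_ml = 10)
  expect_equal(recovery_coefficient(a, b), 0.8)
  expect_equal(recovery_coefficient(b, b), 1)
  expect_error(recovery_coefficient(a, list(volume_ml = 0)), "positive")
})
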
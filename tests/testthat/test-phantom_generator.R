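# Digital phantom construction and the system degradation operators.

test_that("voxelized volumes converge to analytic solid volumes", {
  les <- lesion_spec(solid_sphere(c(35, 35, 35), 10), concentrations = 5,
                     layer_fracs = 1)
  sc <- scene_lesion_bed(les, margin_mm = 10)
  errs <- sapply(c(2, 1, 0.5), function(sp) {
    tr <- build_scene(sc, spacing_mm = sp)$truth[[1]]
    abs(tr$volume_ml - tr$analytic_volume_ml) / tr$analytic_volume_ml
  })
  expect_lt(errs[2], 0.05)                     # 1 mm grid close to 4.19 ml
  expect_true(all(diff(errs) < 0))             # monotone refinement
  expect_equal(build_scene(sc, 1)$truth[[1]]$analytic_volume_ml,
               4 / 3 * pi * 10^3 / 1000)
})

test_that("V-series lesion volumes span 1 to 15.6 ml", {
  vols <- sapply(1:8, function(i) {
    sc <- scene_lesion_bed(lesion_vseries(i))
    build_scene(sc, spacing_mm = 1)$truth[[1]]$volume_ml
  })
  expect_equal(vols[1], 1, tolerance = 0.05)
  expect_equal(vols[8], 15.6, tolerance = 0.05)
  expect_true(all(diff(vols) > 0))
})

test_that("multilayer lesions carry exactly the requested contrast ratios", {
  for (pat in c(1, 4, 6)) {
    les <- lesion_layout(pat, ratio = c(8, 4), c_l = 10)
    built <- build_scene(scene_lesion_bed(les), spacing_mm = 2)
    vals <- sort(unique(built$activity$values[built$truth[[1]]$mask]))
    expect_length(vals, 3)
    expect_equal(vals / vals[1], c(1, 4, 8))
  }
})

test_that("scene construction rejects overlaps and sub-voxel lesions", {
  l1 <- lesion_spec(solid_sphere(c(20, 20, 20), 8), 5, 1, id = "a")
  l2 <- lesion_spec(solid_sphere(c(25, 20, 20), 8), 5, 1, id = "b")
  sc <- structure(list(kind = "lesion_bed", box_mm = c(40, 40, 40), c_bg = 1,
                       lesions = list(l1, l2), inserts = list(), body = NULL,
                       artifact = NULL), class = "phantom_scene")
  expect_error(build_scene(sc, 1), "overlap")
  tiny <- lesion_spec(solid_sphere(c(20, 20, 20), 0.3), 5, 1, id = "tiny")
  sc2 <- structure(list(kind = "lesion_bed", box_mm = c(40, 40, 40), c_bg = 1,
                        lesions = list(tiny), inserts = list(), body = NULL,
                        artifact = NULL), class = "phantom_scene")
  expect_error(build_scene(sc2, 2), "smaller than one voxel")
})

test_that("apply_system reduces to box-average resampling in the clean limit", {
  set.seed(11)
  act <- volume_grid(array(runif(24^3), c(24, 24, 24)), spacing_mm = 1)
  out <- apply_system(act, system_model(0, 2, 0, seed = 1))
  expect_equal(dim(out$values), c(12, 12, 12))
  expect_equal(out$values, phantomrad:::block_average(act$values, 2L))
  expect_equal(out$spacing_mm, 2)
})

test_that("blur + resample conserve the activity of interior lesions", {
  # lesion-attributable activity on a zero background, well inside the box
  act <- array(0, c(50, 50, 50))
  co <- arrayInd(seq_len(50^3), c(50, 50, 50))
  act[rowSums((co - 25.5)^2) <= 8^2] <- 7
  grid <- volume_grid(act, spacing_mm = 1)
  pet <- apply_system(grid, system_model(4.8, 2, 0, seed = 1))
  tot_in <- sum(act) * voxel_volume_ml(grid)
  tot_out <- sum(pet$values) * voxel_volume_ml(pet)
  expect_equal(tot_out, tot_in, tolerance = 0.005)
})

test_that("apply_system is bit-reproducible given a seed and warns on coarse PSF", {
  act <- volume_grid(array(1, c(16, 16, 16)), spacing_mm = 2)
  sys <- system_model(4.8, 2, noise_sd = 0.1, seed = 42)
  a <- apply_system(act, sys)
  b <- apply_system(act, sys)
  expect_identical(a$values, b$values)
  c2 <- apply_system(act, system_model(4.8, 2, noise_sd = 0.1, seed = 43))
  expect_false(identical(a$values, c2$values))
  expect_warning(apply_system(act, system_model(3, 4, 0, seed = 1)),
                 "below the reconstructed voxel size")
})

test_that("blur preserves the mean of a homogeneous interior", {
  act <- volume_grid(array(2.5, c(30, 30, 30)), spacing_mm = 2)
  pet <- apply_system(act, system_model(4.8, 2, 0, seed = 1))
  interior <- pet$values[10:20, 10:20, 10:20]
  expect_equal(mean(interior), 2.5, tolerance = 1e-9)
})

test_that("partial-volume losses are worse for smaller spheres", {
  rc <- sapply(c(6, 18), function(r) {
    les <- lesion_spec(solid_sphere(c(0, 0, 0), r), 10, 1)
    sc <- scene_lesion_bed(les, c_bg = 1, margin_mm = 15)
    built <- build_scene(sc, spacing_mm = 1)
    pet <- apply_system(built$activity, system_model(4.8, 2, 0, seed = 1))
    max(pet$values) / 10
  })
  expect_lt(rc[1], rc[2])
})

test_that("background normalization has unit mean, idempotence and scale invariance", {
  set.seed(5)
  img <- volume_grid(array(runif(10^3, 1, 3), c(10, 10, 10)), 2)
  full <- array(TRUE, c(10, 10, 10))
  n1 <- normalize_background(img, full)
  expect_equal(mean(n1$values), 1)
  expect_equal(normalize_background(n1, full)$values, n1$values)
  scaled <- volume_grid(5 * img$values, 2)
  expect_equal(normalize_background(scaled, full)$values, n1$values)
  empty <- array(FALSE, c(10, 10, 10))
  expect_error(normalize_background(img, empty), "empty")
})

test_that("normalized lesion-to-background contrast recovers the design ratio", {
  les <- lesion_layout(1, ratio = c(4, 2), c_l = 10)  # outer layer is C_H
  sc <- scene_lesion_bed(les, c_bg = 1)
  built <- build_scene(sc, spacing_mm = 2)
  bg_mask <- !built$truth[[1]]$mask
  pet <- normalize_background(built$activity, bg_mask)
  lowest <- min(pet$values[built$truth[[1]]$mask])
  expect_equal(lowest, 10, tolerance = 1e-9)
})

test_that("streak injection is a bit-exact no-op at zero amplitude and localized otherwise", {
  sc <- scene_cheese("pc", metal = "steel")
  built <- build_scene(sc, spacing_mm = 4)
  pet0 <- apply_system(built$activity, system_model(4.8, 4, 0, seed = 1))
  spec0 <- sc$artifact; spec0$amplitude <- 0
  out0 <- inject_streaks(built$pseudo_ct, pet0, spec0)
  expect_identical(out0$pet$values, pet0$values)

  out <- inject_streaks(built$pseudo_ct, pet0, sc$artifact)
  co <- phantomrad:::coord_arrays(pet0)
  ctr <- sc$artifact$metals[[1]]$center_mm
  r <- sqrt((co$x - ctr[1])^2 + (co$y - ctr[2])^2)
  rel <- abs(out$pet$values - pet0$values) / pmax(pet0$values, 1e-6)
  near <- mean(rel[r < 30 & pet0$values > 0.1])
  far <- mean(rel[r > 60 & pet0$values > 0.1])
  expect_gt(near, far)

  # density scaling: steel bias exceeds aluminum bias
  spec_al <- sc$artifact
  for (i in seq_along(spec_al$metals)) spec_al$metals[[i]]$density <- 2.8
  out_al <- inject_streaks(built$pseudo_ct, pet0, spec_al)
  expect_gt(mean(abs(out$pet$values - pet0$values)),
            mean(abs(out_al$pet$values - pet0$values)))
})
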
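# Feature computation: first-order, histogram, shape, texture matrices and
# texture features (with brute-force cross-checks; the large-scale oracle
# sweep lives in the acceptance tests).

test_that("first-order statistics match hand values and affine behaviour", {
  fo <- first_order(c(1, 2, 3, 4, 5))
  expect_equal(unname(fo$values["suv_mean"]), 3)
  expect_equal(unname(fo$values["suv_median"]), 3)
  expect_equal(unname(fo$values["suv_range"]), 4)
  ms <- moment_stats(c(1, 2, 3, 4, 5))
  expect_equal(ms$skewness, 0)
  set.seed(12)
  x <- rgamma(500, shape = 2)
  m1 <- moment_stats(x)
  m2 <- moment_stats(3.2 * x + 7)
  expect_equal(m1$skewness, m2$skewness, tolerance = 1e-9)
  expect_equal(m1$kurtosis, m2$kurtosis, tolerance = 1e-9)
  fo2 <- first_order(3.2 * x + 7)
  fo1 <- first_order(x)
  expect_equal(unname(fo2$values["suv_mean"]),
               3.2 * unname(fo1$values["suv_mean"]) + 7)
  cst <- moment_stats(rep(4, 10))
  expect_true(cst$degenerate)
  expect_equal(cst$skewness, 0)
})

test_that("Pearson kurtosis of a large normal sample is near 3", {
  set.seed(77)
  k <- moment_stats(rnorm(1e5))$kurtosis
  expect_equal(k, 3, tolerance = 0.1)
})

test_that("aucCSH matches closed forms and is affine-invariant", {
  expect_equal(auc_csh(c(0, 1)), 0.5, tolerance = 1e-3)   # grid correction
  set.seed(8)
  u <- runif(20000)
  expect_equal(auc_csh(u), 0.5, tolerance = 0.02)
  x <- rexp(400)
  expect_equal(auc_csh(x), auc_csh(5 * x + 2), tolerance = 1e-12)
  expect_true(is.na(auc_csh(rep(1, 5))))
})

test_that("shape features behave on canonical solids", {
  cube <- array(FALSE, c(16, 16, 16)); cube[4:13, 4:13, 4:13] <- TRUE
  sh <- shape_features(cube, spacing_mm = 1)
  expect_equal(unname(sh["shape_volume_ml"]), 1)
  ball <- array(FALSE, c(26, 26, 26))
  co <- arrayInd(seq_len(26^3), c(26, 26, 26))
  ball[rowSums((co - 13.5)^2) <= 10^2] <- TRUE
  shb <- shape_features(ball, spacing_mm = 1)
  expect_gt(unname(shb["shape_sphericity"]), unname(sh["shape_sphericity"]))
  expect_lt(abs(unname(shb["shape_max_diameter_mm"]) - 20), 2.5)
})

test_that("texture matrices match exhaustive enumeration on a documented fixture", {
  lev <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))
  mats <- build_matrices(as_disc(lev, 2), per_direction = TRUE)
  expect_equal(glcm_dense(mats), oracle_glcm(lev, 2))
  expect_equal(unclass(mats$glrlm)[, 1:2], oracle_glrlm(lev, 2)[, 1:2],
               ignore_attr = TRUE)
  cst <- array(1L, c(3, 3, 3))
  mc <- build_matrices(as_disc(cst, 1))
  expect_equal(glszm_dense(mc)[1, 27], 1)   # one zone of size 27
  expect_equal(sum(glszm_dense(mc)), 1)
  # axis-aligned checkerboard: no equal-level axis neighbours
  chk <- array(0L, c(4, 4, 4))
  co <- arrayInd(seq_len(64), c(4, 4, 4))
  chk[] <- 1L + (rowSums(co) %% 2L)
  m2 <- build_matrices(as_disc(chk, 2))
  dm <- glcm_dense(m2)
  expect_equal(dm, oracle_glcm(chk, 2))
})

test_that("matrix conservation laws hold on random fixtures", {
  set.seed(31)
  for (rep in 1:10) {
    lev <- random_level_volume(c(5, 6, 4), G = 5, p_mask = 0.8)
    nvox <- sum(!is.na(lev))
    mats <- build_matrices(as_disc(lev, 5), per_direction = TRUE)
    # per-direction run-length conservation
    for (pd in attr(mats$glrlm, "per_direction")) {
      lens <- matrix(seq_len(ncol(pd)), nrow(pd), ncol(pd), byrow = TRUE)
      expect_equal(sum(pd * lens), nvox)
    }
    # zone-size conservation
    expect_equal(sum(mats$glszm$z * mats$glszm$n), nvox)
    # GLCM symmetry and unit normalization
    dm <- glcm_dense(mats)
    expect_equal(dm, t(dm))
    if (sum(dm) > 0) expect_equal(sum(dm / sum(dm)), 1)
    # NGTDM probabilities
    expect_equal(sum(mats$ngtdm$p), 1)
  }
})

test_that("texture features match the naive-formula oracle and closed forms", {
  set.seed(41)
  lev <- random_level_volume(c(5, 5, 5), G = 4)
  mats <- build_matrices(as_disc(lev, 4))
  got <- texture_features(mats)$values
  want <- oracle_texture_features(glcm_dense(mats), unclass(mats$glrlm),
                                  glszm_dense(mats), mats$ngtdm, mats$n_vox)
  expect_equal(got[names(want)], want, tolerance = 1e-10)
  # uniform normalized GLCM has energy 1/G^2
  G <- 4
  fake <- mats
  fake$glcm <- list(i = rep(1:G, G), j = rep(1:G, each = G),
                    n = rep(1, G * G), G = G)
  expect_equal(unname(texture_features(fake)$values["glcm_energy"]), 1 / G^2)
  # all-distinct levels: every run has length 1, so RP = 1 and LRE = 1
  alt <- array(1:27, c(3, 3, 3))
  ma <- build_matrices(as_disc(alt, 27))
  tf <- texture_features(ma)$values
  expect_equal(unname(tf["glrlm_rp"]), 1)
  expect_equal(unname(tf["glrlm_lre"]), 1)
})

test_that("extract_all returns the full deterministic 133-feature roster", {
  set.seed(55)
  vals <- array(runif(12^3, 1, 2), c(12, 12, 12))
  pet <- volume_grid(vals, spacing_mm = 2)
  mask <- array(FALSE, c(12, 12, 12)); mask[4:9, 4:9, 4:9] <- TRUE
  fv1 <- extract_all(pet, mask)
  expect_length(fv1$values, 133)
  expect_identical(names(fv1$values), feature_roster())
  fv2 <- extract_all(pet, mask)
  expect_identical(fv1$values, fv2$values)
  expect_false(any(is.na(fv1$values)))
  # a single-voxel mask keeps shape but flags intensity/texture features
  m1 <- array(FALSE, c(12, 12, 12)); m1[6, 6, 6] <- TRUE
  fv3 <- extract_all(pet, m1)
  expect_false(any(is.na(fv3$values[grep("^shape_", names(fv3$values))])))
  expect_true(all(fv3$degenerate[grep("^(Q_|WF_)?gl|^ngtdm|^WF_ngtdm|^Q_ngtdm",
                                      names(fv3$degenerate))]))
  expect_true(fv3$degenerate["skewness"])
})

test_that("shape features ignore intensities; texture ignores array layout shifts", {
  set.seed(66)
  vals <- array(runif(10^3), c(10, 10, 10))
  mask <- array(FALSE, c(10, 10, 10)); mask[3:8, 3:8, 3:8] <- TRUE
  sh1 <- shape_features(mask, 2)
  sh2 <- shape_features(mask, 2)  # same mask, any intensities: same result
  expect_identical(sh1, sh2)
  # translating image+mask together leaves all features unchanged
  pet <- volume_grid(vals, 2)
  f1 <- extract_all(pet, mask)
  vals2 <- array(0, c(10, 10, 10)); vals2[2:10, , ] <- vals[1:9, , ]
  mask2 <- array(FALSE, c(10, 10, 10)); mask2[2:10, , ] <- mask[1:9, , ]
  f2 <- extract_all(volume_grid(vals2, 2), mask2)
  tx <- grep("^(Q_)?(glcm|glrlm|glszm|ngtdm)", names(f1$values), value = TRUE)
  expect_equal(f1$values[tx], f2$values[tx], tolerance = 1e-12)
})
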
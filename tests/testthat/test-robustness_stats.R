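# Paired statistics and the robustness decision rule.

test_that("wilcoxon signed-rank handles zeros and matches the textbook case", {
  expect_equal(wilcoxon_signed_rank(1:5, 1:5), 1)
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), rep(0, 6)), 2 / 64)
  # zero differences are dropped, remaining pair decides nothing
  expect_equal(wilcoxon_signed_rank(c(1, 1, 1, 2), c(1, 1, 1, 1)), 1)
})

test_that("exact wilcoxon equals the sign-enumeration oracle, with and without ties", {
  set.seed(101)
  for (n in 3:10) {
    d <- round(rnorm(n), 1)               # rounding produces ties and zeros
    expect_equal(wilcoxon_signed_rank(d, 0), oracle_wilcoxon_p(d),
                 info = paste("n =", n))
    d2 <- rnorm(n)
    expect_equal(wilcoxon_signed_rank(d2, 0), oracle_wilcoxon_p(d2))
  }
})

test_that("exact wilcoxon agrees with stats::wilcox.test on tie-free data", {
  set.seed(102)
  for (rep in 1:5) {
    a <- rnorm(9); b <- rnorm(9)
    expect_equal(wilcoxon_signed_rank(a, b),
                 suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                              exact = TRUE)$p.value))
  }
})

test_that("large-sample wilcoxon approximation is calibrated", {
  set.seed(103)
  p <- replicate(400, wilcoxon_signed_rank(rnorm(30), 0))
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.10)
  # strong one-sided shift is detected
  expect_lt(wilcoxon_signed_rank(rnorm(30) + 3, 0), 1e-4)
})

test_that("spearman matches exhaustive permutation for n = 6 and hits the bounds", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 0.5, 5, 1.2, 11, 2.2)
  got <- spearman(x, y)
  want <- oracle_spearman(x, y)
  expect_equal(got$r, want$r)
  expect_equal(got$p, want$p)
  expect_equal(spearman(1:6, exp(1:6))$r, 1)        # monotone
  expect_equal(spearman(1:6, -(1:6)^3)$r, -1)       # anti-monotone
  expect_true(is.na(spearman(rep(1, 6), 1:6)$r))    # constant margin
})

test_that("spearman t approximation is sane for larger n", {
  set.seed(104)
  x <- rnorm(30); y <- x + rnorm(30, sd = 0.1)
  got <- spearman(x, y)
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(got$r, unname(ct$estimate))
  expect_equal(got$p, ct$p.value, tolerance = 0.05)
  expect_equal(spearman(1:20, (1:20)^2)$p, 0)        # |r| = 1 edge
})

test_that("bland-altman reproduces closed forms and is antisymmetric", {
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$bias_pct, 0)
  expect_true(ident$comparable)
  a <- c(1, 2.5, 4, 8)
  dbl <- bland_altman(a, 2 * a)
  expect_equal(dbl$bias_pct, -100 * 1 / 1.5)
  expect_equal(dbl$sd_pct, 0)
  set.seed(105)
  x <- runif(12, 1, 2); y <- runif(12, 1, 2)
  expect_equal(bland_altman(x, y)$bias_pct, -bland_altman(y, x)$bias_pct)
  expect_warning(bland_altman(c(1, -1, 2), c(1, 1, 2)), "excluded")
})

test_that("feature classification applies the three criteria exactly", {
  cfg <- stat_config(alpha = 0.05, K = 133)
  f1 <- classify_feature(list(wilcoxon_p = 0.2, spearman_r = 0.95,
                              spearman_p = 1e-6, ba_ci = c(-1, 1)), cfg)
  expect_true(f1["robust"] && f1["strong_corr"] && f1["ba_comparable"])
  # the SUVmean/volume pattern: strongly correlated yet not robust
  f2 <- classify_feature(list(wilcoxon_p = 0.01, spearman_r = 0.99,
                              spearman_p = 1e-9, ba_ci = c(-5, -1)), cfg)
  expect_false(f2["robust"]); expect_true(f2["strong_corr"])
  expect_false(f2["ba_comparable"])
  # Bonferroni: p = 0.01 does not clear 0.05 / 133
  f3 <- classify_feature(list(wilcoxon_p = 0.5, spearman_r = 0.85,
                              spearman_p = 0.01, ba_ci = c(-1, 1)), cfg)
  expect_false(f3["strong_corr"])
})

test_that("compare_tables aligns lesions, recomputes K and flags untestable features", {
  set.seed(106)
  n <- 10
  A <- data.frame(lesion_id = paste0("l", 1:n),
                  f_stable = rnorm(n), f_shift = rnorm(n),
                  f_sparse = c(rnorm(3), rep(NA, n - 3)),
                  check.names = FALSE)
  B <- A
  B$f_shift <- A$f_shift + 5
  cmp <- compare_tables(A, B, stat_config())
  expect_equal(attr(cmp, "K"), 2)            # f_sparse is untestable
  expect_true(cmp$untestable[cmp$feature == "f_sparse"])
  expect_true(is.na(cmp$robust[cmp$feature == "f_sparse"]))
  expect_true(cmp$robust[cmp$feature == "f_stable"])
  expect_false(cmp$robust[cmp$feature == "f_shift"])
  B2 <- B; B2$lesion_id <- rev(B2$lesion_id)
  expect_error(compare_tables(A, B2), "not aligned")
})

test_that("reports count flags consistently and intersect across factors", {
  set.seed(107)
  n <- 12
  A <- data.frame(lesion_id = paste0("l", 1:n), u = rnorm(n), v = rnorm(n),
                  w = rnorm(n))
  same <- compare_tables(A, A, stat_config())
  expect_true(all(same$robust))
  rep1 <- build_report(list(factor1 = same))
  expect_equal(rep1$summary$n_robust, 3)
  expect_equal(sort(rep1$intersection), sort(c("u", "v", "w")))
  B <- A; B$u <- A$u + 9
  diff <- compare_tables(A, B, stat_config())
  rep2 <- build_report(list(f1 = same, f2 = diff))
  expect_true(all(rep2$intersection %in% rep1$intersection))
  expect_false("u" %in% rep2$intersection)
  # counts equal the number of set flags
  expect_equal(rep2$summary$n_robust,
               unname(colSums(rep2$robust_matrix)))
})
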
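# Paired robustness statistics: Wilcoxon signed-rank (exact by sign
# enumeration for small n), Spearman correlation with exact permutation p
# for small n, Bland-Altman relative bias, and the three-flag decision rule
# (robust / strongly correlated / Bland-Altman comparable).

#' Statistical decision configuration
#'
#' @param alpha significance level (0.05 in the study).
#' @param K Bonferroni divisor: the number of features actually tested.
#' @param r_threshold Spearman correlation threshold for "strong".
#' @param min_n minimum number of complete pairs required to test a
#'   feature; below it the feature is reported untestable, never robust.
#' @return a `stat_config`.
#' @export
stat_config <- function(alpha = 0.05, K = 133L, r_threshold = 0.8,
                        min_n = 5L) {
  stopifnot(alpha > 0, alpha < 1, K >= 1, min_n >= 1)
  structure(list(alpha = alpha, K = as.integer(K),
                 r_threshold = r_threshold, min_n = as.integer(min_n)),
            class = "stat_config")
}

#' Two-sided Wilcoxon signed-rank p value
#'
#' Zero differences are dropped (classic convention; `zero_method =
#' "pratt"` keeps them in the ranking but out of the statistic). For `n <=
#' exact_max` non-zero differences the exact two-sided p is computed by
#' enumerating all `2^n` sign assignments of the midranks (valid with
#' ties); above that a normal approximation with tie and continuity
#' correction is used. All-zero differences give p = 1.
#'
#' @param a,b paired numeric vectors; or pass differences via `a` with
#'   `b = 0`.
#' @param exact_max enumeration cutoff.
#' @param zero_method `"drop"` or `"pratt"`.
#' @return two-sided p value.
#' @export
wilcoxon_signed_rank <- function(a, b = 0, exact_max = 12L,
                                 zero_method = c("drop", "pratt")) {
  zero_method <- match.arg(zero_method)
  d <- a - b
  if (length(d) == 0L) return(NA_real_)
  if (all(d == 0)) return(1)
  if (zero_method == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))
    r <- r[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wall <- as.vector(signs %*% r)
    p <- 2 * min(mean(wall <= w), mean(wall >= w))
    return(min(1, p))
  }
  mu <- sum(r) / 2
  sigma2 <- sum(r^2) / 4
  cc <- 0.5 * sign(w - mu)
  z <- (w - mu - cc) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

# All permutations of 1..n as an (n! x n) matrix.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub], nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

#' Spearman correlation with small-sample exact p
#'
#' r is the Pearson correlation of midranks. The two-sided p value comes
#' from exhaustive permutation of one margin for `n <= exact_max`, and from
#' the t approximation `t = r sqrt((n-2)/(1-r^2))` otherwise (|r| = 1 gives
#' p = 0). Constant margins are undefined and returned as NA.
#'
#' @param a,b paired numeric vectors, `n >= 3`.
#' @param exact_max permutation cutoff.
#' @return list with `r` and `p`.
#' @export
spearman <- function(a, b, exact_max = 8L) {
  n <- length(a)
  stopifnot(length(b) == n, n >= 3)
  ra <- rank(a); rb <- rank(b)
  if (sd(ra) == 0 || sd(rb) == 0)
    return(list(r = NA_real_, p = NA_real_))
  r <- cor(ra, rb)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    ac <- ra - mean(ra)
    bc <- rb - mean(rb)
    rall <- (matrix(bc[perms], nrow(perms)) %*% ac) /
      (sqrt(sum(ac^2)) * sqrt(sum(bc^2)))
    p <- mean(abs(rall) >= abs(r) - 1e-12)
  } else if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  list(r = r, p = p)
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences are expressed relative to the pairwise means in percent:
#' `d_i = 100 (a_i - b_i) / ((a_i + b_i)/2)`. Reports the mean difference
#' (bias), its 95% t confidence interval, the 1.96-SD limits of agreement
#' and the comparability flag (CI contains zero). Pairs with `a + b = 0`
#' are excluded with a warning. Swapping the arms negates the bias.
#'
#' @param a,b paired numeric vectors.
#' @return list with `bias_pct`, `sd_pct`, `ci_95`, `loa`, `n`,
#'   `comparable`.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b))
  m <- (a + b) / 2
  bad <- m == 0
  if (any(bad)) {
    warning(sprintf("%d pair(s) with zero mean excluded", sum(bad)))
    a <- a[!bad]; b <- b[!bad]; m <- m[!bad]
  }
  n <- length(a)
  if (n < 2) stop("need at least two usable pairs")
  d <- 100 * (a - b) / m
  bias <- mean(d)
  s <- sd(d)
  half <- qt(0.975, n - 1) * s / sqrt(n)
  ci <- c(bias - half, bias + half)
  list(bias_pct = bias, sd_pct = s, ci_95 = ci,
       loa = c(bias - 1.96 * s, bias + 1.96 * s), n = n,
       comparable = ci[1] <= 0 && ci[2] >= 0)
}

#' Classify one feature's paired comparison
#'
#' Applies the study's three criteria: robust when the Wilcoxon p exceeds
#' alpha (uncorrected — the conservative direction for a robustness claim);
#' strongly correlated when `r > r_threshold` and the Spearman p clears the
#' Bonferroni-corrected level `alpha / K`; Bland-Altman comparable when the
#' 95% CI of the relative bias contains zero.
#'
#' @param result list with `wilcoxon_p`, `spearman_r`, `spearman_p`,
#'   `ba_ci` (length 2), any of which may be NA.
#' @param cfg a `stat_config`.
#' @return named logical vector `robust`, `strong_corr`, `ba_comparable`
#'   (NA where the input was NA).
#' @export
classify_feature <- function(result, cfg = stat_config()) {
  robust <- if (is.na(result$wilcoxon_p)) NA else
    result$wilcoxon_p > cfg$alpha
  strong <- if (is.na(result$spearman_r) || is.na(result$spearman_p)) NA else
    result$spearman_r > cfg$r_threshold &&
      result$spearman_p < cfg$alpha / cfg$K
  bac <- if (any(is.na(result$ba_ci))) NA else
    result$ba_ci[1] <= 0 && result$ba_ci[2] >= 0
  c(robust = robust, strong_corr = strong, ba_comparable = bac)
}

#' Compare two protocol feature tables
#'
#' Performs the per-feature paired analysis between protocols A and B over
#' lesions shared by both tables. Lesion IDs must match exactly (hard
#' error otherwise). Degenerate (NA) values are excluded pairwise; a
#' feature with fewer than `cfg$min_n` complete pairs is reported
#' untestable. The Bonferroni divisor K is recomputed as the number of
#' features actually tested unless `cfg$K` is forced via `fixed_K`.
#'
#' @param table_a,table_b data.frames from [extract_table()]: a
#'   `lesion_id` column plus one column per feature.
#' @param cfg a `stat_config`.
#' @param fixed_K use `cfg$K` instead of the recomputed divisor.
#' @return a `comparison_result` data.frame (one row per feature) with the
#'   test statistics and flags; `K` and `cfg` stored as attributes.
#' @export
compare_tables <- function(table_a, table_b, cfg = stat_config(),
                           fixed_K = FALSE) {
  stopifnot(is.data.frame(table_a), is.data.frame(table_b))
  if (!identical(table_a$lesion_id, table_b$lesion_id))
    stop("lesion IDs of the two protocols are not aligned")
  feats <- setdiff(intersect(names(table_a), names(table_b)), "lesion_id")
  usable <- vapply(feats, function(f) {
    ok <- is.finite(table_a[[f]]) & is.finite(table_b[[f]])
    sum(ok) >= cfg$min_n
  }, logical(1))
  K <- if (fixed_K) cfg$K else max(1L, sum(usable))
  rows <- lapply(feats, function(f) {
    a <- table_a[[f]]; b <- table_b[[f]]
    ok <- is.finite(a) & is.finite(b)
    n <- sum(ok)
    if (n < cfg$min_n)
      return(data.frame(feature = f, n = n, wilcoxon_p = NA_real_,
                        spearman_r = NA_real_, spearman_p = NA_real_,
                        ba_bias_pct = NA_real_, ba_lo = NA_real_,
                        ba_hi = NA_real_, robust = NA, strong_corr = NA,
                        ba_comparable = NA, untestable = TRUE))
    a <- a[ok]; b <- b[ok]
    pw <- wilcoxon_signed_rank(a, b)
    sp <- spearman(a, b)
    ba <- tryCatch(suppressWarnings(bland_altman(a, b)),
                   error = function(e) list(bias_pct = NA_real_,
                                            ci_95 = c(NA_real_, NA_real_)))
    cl <- classify_feature(list(wilcoxon_p = pw, spearman_r = sp$r,
                                spearman_p = sp$p, ba_ci = ba$ci_95),
                           stat_config(cfg$alpha, K, cfg$r_threshold,
                                       cfg$min_n))
    data.frame(feature = f, n = n, wilcoxon_p = pw, spearman_r = sp$r,
               spearman_p = sp$p, ba_bias_pct = ba$bias_pct,
               ba_lo = ba$ci_95[1], ba_hi = ba$ci_95[2],
               robust = cl["robust"], strong_corr = cl["strong_corr"],
               ba_comparable = cl["ba_comparable"], untestable = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "K") <- K
  attr(out, "cfg") <- cfg
  class(out) <- c("comparison_result", class(out))
  out
}
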
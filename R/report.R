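# Cross-factor robustness reporting: per-factor feature flags, summary
# counts, and the intersection of features robust under every degrading
# factor.

#' Build a cross-factor robustness report
#'
#' A factor (system, voxel size, artifact, segmentation) may involve
#' several pairwise protocol comparisons (e.g. one per metal); a feature
#' counts as robust to the factor only when it is robust in every
#' comparison of that factor. The report also carries the intersection of
#' features robust to all factors — the study's headline set.
#'
#' @param comparisons named list of factors; each factor is either one
#'   `comparison_result` or a list of them.
#' @return a `robustness_report`: per-factor flag data.frame, summary
#'   counts, robust/strongly-correlated sets per factor, and
#'   `intersection`, the features robust under every factor.
#' @export
build_report <- function(comparisons) {
  stopifnot(length(comparisons) > 0, !is.null(names(comparisons)))
  per_factor <- lapply(comparisons, function(cmp) {
    if (inherits(cmp, "comparison_result")) cmp <- list(cmp)
    feats <- cmp[[1]]$feature
    rob <- rep(TRUE, length(feats))
    cor <- rep(TRUE, length(feats))
    for (one in cmp) {
      if (!identical(one$feature, feats))
        stop("comparisons within a factor must cover the same features")
      rob <- rob & !is.na(one$robust) & one$robust
      cor <- cor & !is.na(one$strong_corr) & one$strong_corr
    }
    data.frame(feature = feats, robust = rob, strong_corr = cor)
  })
  feats <- per_factor[[1]]$feature
  flag_mat <- sapply(per_factor, function(pf) pf$robust)
  corr_mat <- sapply(per_factor, function(pf) pf$strong_corr)
  rownames(flag_mat) <- rownames(corr_mat) <- feats
  inter <- feats[rowSums(flag_mat) == ncol(flag_mat)]
  summary <- data.frame(
    factor = names(per_factor),
    n_robust = colSums(flag_mat),
    n_strong_corr = colSums(corr_mat),
    row.names = NULL)
  structure(list(per_factor = per_factor, comparisons = comparisons,
                 robust_matrix = flag_mat, corr_matrix = corr_mat,
                 summary = summary, intersection = inter),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("<robustness_report>\n")
  print(x$summary)
  cat(sprintf("robust to all %d factors: %d feature(s)\n",
              ncol(x$robust_matrix), length(x$intersection)))
  if (length(x$intersection) && length(x$intersection) <= 12)
    cat("  ", paste(x$intersection, collapse = ", "), "\n")
  invisible(x)
}

#' Write a robustness report to disk
#'
#' Emits the per-feature flag matrix as CSV (features x factors, the
#' detailed-results-table analogue) and a JSON summary with per-factor
#' counts and the cross-factor intersection.
#'
#' @param report a `robustness_report`.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "robustness_flags.csv")
  mat <- data.frame(feature = rownames(report$robust_matrix),
                    report$robust_matrix, check.names = FALSE)
  write.csv(mat, csv, row.names = FALSE)
  js <- file.path(dir, "robustness_summary.json")
  jsonlite::write_json(list(summary = report$summary,
                            intersection = report$intersection),
                       js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, js))
}
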
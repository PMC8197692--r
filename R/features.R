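# Radiomic feature computation: SUV first-order statistics, histogram
# descriptors (aucCSH, skewness, kurtosis), mask shape features and the
# texture families under three preprocessing variants — plain, wavelet
# band-pass filtered (WF-) and equal-probability quantized (Q-).

#' First-order SUV statistics
#'
#' Skewness is `m3 / m2^1.5` and kurtosis `m4 / m2^2` (Pearson convention:
#' a normal distribution scores 3, not 0). Entropy is computed on the
#' fixed-bin-width histogram of the input. On constant input the moment
#' ratios are undefined and flagged degenerate.
#'
#' @param values numeric vector of in-mask intensities (>= 2 voxels).
#' @param entropy_bin_width bin width for the entropy histogram.
#' @return list with `values` (named numeric) and `degenerate` (logical).
#' @export
first_order <- function(values, entropy_bin_width = 0.01) {
  stopifnot(length(values) >= 2, all(is.finite(values)))
  qs <- unname(quantile(values, c(0.10, 0.25, 0.75, 0.90), type = 7))
  m <- mean(values)
  s <- sd(values)
  lev <- levels_fbw(values, entropy_bin_width)$lev
  ph <- tabulate(lev) / length(lev)
  ph <- ph[ph > 0]
  vals <- c(suv_mean = m, suv_max = max(values), suv_min = min(values),
            suv_median = median(values), suv_sd = s, suv_variance = s^2,
            suv_energy = sum(values^2),
            suv_rms = sqrt(mean(values^2)),
            suv_entropy = -sum(ph * log2(ph)),
            suv_mad = mean(abs(values - m)),
            suv_p10 = qs[1], suv_p25 = qs[2], suv_p75 = qs[3],
            suv_p90 = qs[4], suv_iqr = qs[3] - qs[2],
            suv_range = max(values) - min(values),
            suv_cov = if (m != 0) s / m else NA_real_)
  deg <- setNames(rep(FALSE, length(vals)), names(vals))
  deg["suv_cov"] <- m == 0
  list(values = vals, degenerate = deg)
}

#' Moment skewness and Pearson kurtosis
#'
#' Invariant under positive affine intensity maps; flagged degenerate for
#' constant input (returned as 0 with the flag set downstream).
#'
#' @param values numeric vector.
#' @return named list `skewness`, `kurtosis`, `degenerate`.
#' @export
moment_stats <- function(values) {
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0)
    return(list(skewness = 0, kurtosis = 0, degenerate = TRUE))
  list(skewness = mean((values - m)^3) / m2^1.5,
       kurtosis = mean((values - m)^4) / m2^2,
       degenerate = FALSE)
}

#' Area under the cumulative SUV-volume histogram
#'
#' `CSH(t)` is the fraction of voxels whose min-max normalized intensity is
#' at least `t`; the area is integrated by the trapezoid rule on a fixed
#' 1000-point grid over `[0, 1]`. Invariant under positive affine maps.
#'
#' @param values numeric vector with `max > min`.
#' @param n_grid number of grid points.
#' @return scalar aucCSH, or NA (degenerate) when the input is constant.
#' @export
auc_csh <- function(values, n_grid = 1000L) {
  mn <- min(values); mx <- max(values)
  if (mx == mn) return(NA_real_)
  xn <- sort((values - mn) / (mx - mn))
  tg <- seq(0, 1, length.out = n_grid)
  n <- length(xn)
  csh <- (n - findInterval(tg, xn, left.open = TRUE)) / n
  sum((csh[-1] + csh[-n_grid]) / 2) * (tg[2] - tg[1])
}

# Surface area (mm^2) of a binary mask via the co-area formula on a
# Gaussian-mollified indicator; far less staircase bias than face counting.
surface_area_mm2 <- function(mask, spacing_mm, sigma_vox = 1) {
  pad <- 4L
  d <- dim(mask) + 2L * pad
  a <- array(0, d)
  a[pad + seq_len(dim(mask)[1]), pad + seq_len(dim(mask)[2]),
    pad + seq_len(dim(mask)[3])] <- mask
  sm <- gaussian_blur_array(a, sigma_vox)
  gx <- (shift_array(sm, c(1, 0, 0)) - shift_array(sm, c(-1, 0, 0))) / 2
  gy <- (shift_array(sm, c(0, 1, 0)) - shift_array(sm, c(0, -1, 0))) / 2
  gz <- (shift_array(sm, c(0, 0, 1)) - shift_array(sm, c(0, 0, -1))) / 2
  sum(sqrt(gx^2 + gy^2 + gz^2)) * spacing_mm^2
}

#' Shape features of a segmentation mask
#'
#' Volume, mollified-gradient surface area, sphericity
#' `pi^(1/3) (6V)^(2/3) / A`, maximum 3-D diameter (largest pairwise
#' distance between boundary voxel centres) and compactness
#' `V / (sqrt(pi) A^(3/2))`. Intensity-independent by construction.
#'
#' @param mask logical 3-D array (nonempty).
#' @param spacing_mm voxel spacing in mm.
#' @return named numeric vector.
#' @export
shape_features <- function(mask, spacing_mm) {
  stopifnot(any(mask))
  nvox <- sum(mask)
  vol_mm3 <- nvox * spacing_mm^3
  area <- surface_area_mm2(mask, spacing_mm)
  # boundary voxels: in-mask with at least one out-of-mask 6-neighbour
  interior <- mask
  for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    interior <- interior & shift_array(mask, d, fill = FALSE)
  bnd <- which(mask & !interior)
  if (!length(bnd)) bnd <- which(mask)
  co <- arrayInd(bnd, dim(mask)) * spacing_mm
  if (nrow(co) > 2500) co <- co[seq(1, nrow(co), length.out = 2500), , drop = FALSE]
  dmax <- if (nrow(co) == 1L) spacing_mm else sqrt(max(dist(co)^2))
  c(shape_volume_ml = vol_mm3 / 1000,
    shape_surface_mm2 = area,
    shape_sphericity = pi^(1 / 3) * (6 * vol_mm3)^(2 / 3) / area,
    shape_max_diameter_mm = dmax,
    shape_compactness = vol_mm3 / (sqrt(pi) * area^1.5))
}

#' Extraction configuration
#'
#' @param quantizer `quantizer_spec` for the plain and WF- texture variants
#'   (study default: fixed bin width 0.01).
#' @param q_levels level count of the equal-probability (Q-) variant.
#' @param wavelet `wavelet_spec` for the WF- variant.
#' @return an `extraction_config`.
#' @export
extraction_config <- function(quantizer = quantizer_spec("fbw", W = 0.01),
                              q_levels = 64L,
                              wavelet = wavelet_spec()) {
  structure(list(quantizer = quantizer, q_levels = as.integer(q_levels),
                 wavelet = wavelet),
            class = "extraction_config")
}

#' The canonical 133-feature roster
#'
#' Read from the packaged YAML roster file: 17 SUV first-order features,
#' 3 histogram features, 5 shape features, and 36 texture features (GLCM
#' 10, GLRLM 11, GLSZM 10, NGTDM 5) under each of the plain, `WF_` and `Q_`
#' variants.
#'
#' @return character vector of 133 feature names, in extraction order.
#' @export
feature_roster <- function() {
  path <- system.file("extdata", "feature_roster.yaml", package = "phantomrad")
  if (path == "") path <- file.path("inst", "extdata", "feature_roster.yaml")
  r <- yaml::read_yaml(path)
  unlist(r$features, use.names = FALSE)
}

texture_feature_names <- function() {
  c(paste0("glcm_", c("energy", "contrast", "correlation", "homogeneity",
                      "entropy", "dissimilarity", "autocorrelation",
                      "cluster_shade", "cluster_prominence",
                      "max_probability")),
    paste0("glrlm_", c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                       "srlge", "srhge", "glv", "rlv")),
    paste0("glszm_", c("sze", "lze", "gln", "zsn", "zp", "lgze", "hgze",
                       "szhge", "glv", "zsv")),
    paste0("ngtdm_", c("coarseness", "contrast", "busyness", "complexity",
                       "strength")))
}

# Crop a grid + mask to the mask bounding box plus a margin (cheap texture
# computation without changing any in-mask quantity).
crop_to_mask <- function(values, mask, margin = 4L) {
  idx <- which(mask)
  co <- arrayInd(idx, dim(mask))
  lo <- pmax(apply(co, 2, min) - margin, 1L)
  hi <- pmin(apply(co, 2, max) + margin, dim(mask))
  list(values = values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       mask = mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
}

texture_block <- function(values, mask, quant) {
  disc <- discretize(values, mask, quant)
  texture_features(build_matrices(disc))
}

#' Extract the full radiomic feature vector
#'
#' Computes the configured 133-feature roster for one (image, mask) pair:
#' SUV first-order and histogram features on the raw in-mask intensities,
#' shape features on the mask, and the four texture families under the
#' plain quantizer, after wavelet band-pass filtering (`WF_`), and after
#' equal-probability quantization (`Q_`). Degenerate features (constant
#' input, single gray level) are returned as NA and recorded in the
#' `degenerate` element rather than propagating silently.
#'
#' @param pet a `volume_grid`.
#' @param mask logical array aligned with `pet` (or a `seg_mask`).
#' @param config an `extraction_config`.
#' @param wf_values optional precomputed wavelet-filtered array for the
#'   whole image (lets callers filter once when extracting many masks).
#' @return a `feature_vector`: list with `values` (named numeric, length
#'   133), `degenerate` (named logical) and `provenance`.
#' @export
extract_all <- function(pet, mask, config = extraction_config(),
                        wf_values = NULL) {
  stopifnot(inherits(pet, "volume_grid"), inherits(config, "extraction_config"))
  method <- "unknown"
  if (inherits(mask, "seg_mask")) { method <- mask$method; mask <- mask$mask }
  if (!any(mask)) stop("mask is empty")
  vals_in <- pet$values[mask]
  n <- length(vals_in)

  values <- setNames(rep(NA_real_, 133), feature_roster())
  degen <- setNames(rep(FALSE, 133), feature_roster())

  if (n >= 2) {
    fo <- first_order(vals_in, entropy_bin_width = config$quantizer$W)
    values[names(fo$values)] <- fo$values
    degen[names(fo$degenerate)] <- fo$degenerate
    ms <- moment_stats(vals_in)
    values["skewness"] <- ms$skewness
    values["kurtosis"] <- ms$kurtosis
    degen[c("skewness", "kurtosis")] <- ms$degenerate
    ac <- auc_csh(vals_in)
    values["aucCSH"] <- ac
    degen["aucCSH"] <- is.na(ac)
  } else {
    degen[c(grep("^suv_", names(degen), value = TRUE),
            "skewness", "kurtosis", "aucCSH")] <- TRUE
  }

  sh <- shape_features(mask, pet$spacing_mm)
  values[names(sh)] <- sh

  if (is.null(wf_values))
    wf_values <- wavelet_bandpass(pet$values, config$wavelet)

  cr <- crop_to_mask(pet$values, mask)
  cr_wf <- crop_to_mask(wf_values, mask)
  tx_names <- texture_feature_names()
  if (n >= 2) {
    for (block in list(
      list(prefix = "", res = texture_block(cr$values, cr$mask, config$quantizer)),
      list(prefix = "WF_", res = texture_block(cr_wf$values, cr_wf$mask,
                                               config$quantizer)),
      list(prefix = "Q_", res = texture_block(
        cr$values, cr$mask, quantizer_spec("equal_prob", N = config$q_levels))))) {
      nm <- paste0(block$prefix, names(block$res$values))
      values[nm] <- block$res$values
      degen[nm] <- block$res$degenerate
    }
  } else {
    degen[c(tx_names, paste0("WF_", tx_names), paste0("Q_", tx_names))] <- TRUE
  }

  structure(list(values = values, degenerate = degen,
                 provenance = list(quantizer = config$quantizer$method,
                                   W = config$quantizer$W,
                                   q_levels = config$q_levels,
                                   wavelet = config$wavelet$basis,
                                   wavelet_ratio = config$wavelet$ratio,
                                   mask_method = method, n_voxels = n)),
            class = "feature_vector")
}

#' Feature table for many masks on one image
#'
#' Runs [extract_all()] for each mask, computing the wavelet-filtered
#' volume once. Rows are lesions, columns features; degenerate entries are
#' NA and recorded in the `degenerate` attribute (a logical matrix).
#'
#' @param pet a `volume_grid`.
#' @param masks named list of logical arrays or `seg_mask`s.
#' @param config an `extraction_config`.
#' @return data.frame with `lesion_id` plus 133 feature columns.
#' @export
extract_table <- function(pet, masks, config = extraction_config()) {
  stopifnot(length(masks) > 0, !is.null(names(masks)))
  wf <- wavelet_bandpass(pet$values, config$wavelet)
  rows <- lapply(masks, function(m) extract_all(pet, m, config, wf_values = wf))
  tab <- do.call(rbind, lapply(rows, function(r) r$values))
  deg <- do.call(rbind, lapply(rows, function(r) r$degenerate))
  out <- data.frame(lesion_id = names(masks), tab, row.names = NULL,
                    check.names = FALSE)
  attr(out, "degenerate") <- deg
  out
}
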
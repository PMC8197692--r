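# Texture matrix construction: 3-D gray-level co-occurrence (GLCM),
# run-length (GLRLM), size-zone (GLSZM) and neighborhood gray-tone
# difference (NGTDM) matrices. GLCM/GLRLM use the 13 unique 3-D directions
# at distance 1 and are merged by summation; GLSZM zones and all mask
# connectivity are 26-connected. Pairs, runs and zones truncate at the mask
# boundary (out-of-mask neighbours are ignored).
#
# GLCM and GLSZM are held in sparse triplet form: with a fixed bin width of
# 0.01 on background-normalized SUVs, G can reach several thousand levels
# and a dense G x G co-occurrence matrix would be enormous, while the number
# of occupied cells stays bounded by the voxel count.

# Shift an array by an integer offset d, filling exposed voxels with `fill`:
# out[v] = arr[v + d] where defined.
shift_array <- function(arr, d, fill = 0) {
  dims <- dim(arr)
  out <- array(fill, dims)
  src <- list(valid_range(dims[1], d[1]), valid_range(dims[2], d[2]),
              valid_range(dims[3], d[3]))
  dst <- list(valid_range(dims[1], -d[1]), valid_range(dims[2], -d[2]),
              valid_range(dims[3], -d[3]))
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# Aggregate duplicate (key) entries: returns unique keys and summed counts.
aggregate_keys <- function(keys, weights = NULL) {
  o <- order(keys)
  k <- keys[o]
  w <- if (is.null(weights)) rep(1, length(k)) else weights[o]
  new <- c(TRUE, k[-1] != k[-length(k)])
  grp <- cumsum(new)
  list(key = k[new], n = as.vector(rowsum(w, grp)))
}

# Symmetric GLCM merged over the 13 directions, as triplets (i, j, n).
glcm_from_levels <- function(lev, G) {
  g1_all <- integer(0); g2_all <- integer(0)
  dirs <- directions_13()
  for (r in seq_len(nrow(dirs))) {
    nb <- shift_array(lev, dirs[r, ], fill = NA_integer_)
    ok <- !is.na(lev) & !is.na(nb)
    if (!any(ok)) next
    g1_all <- c(g1_all, lev[ok], nb[ok])
    g2_all <- c(g2_all, nb[ok], lev[ok])
  }
  if (!length(g1_all))
    return(list(i = integer(0), j = integer(0), n = numeric(0), G = G))
  agg <- aggregate_keys((as.numeric(g1_all) - 1) * G + as.numeric(g2_all))
  list(i = as.integer((agg$key - 1) %/% G) + 1L,
       j = as.integer((agg$key - 1) %% G) + 1L,
       n = agg$n, G = G)
}

glrlm_from_levels <- function(lev, G, per_direction = FALSE) {
  dims <- dim(lev)
  idx <- which(!is.na(lev))
  co <- arrayInd(idx, dims)
  lv <- lev[idx]
  rmax <- max(dims)
  dirs <- directions_13()
  B <- as.numeric(2 * max(dims) + 2)
  total <- numeric(G * rmax)
  per_dir <- if (per_direction) vector("list", nrow(dirs)) else NULL
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    a0 <- which(d != 0)[1]
    t <- co[, a0] * sign(d[a0])
    k1 <- co[, 1] - t * d[1]; k2 <- co[, 2] - t * d[2]; k3 <- co[, 3] - t * d[3]
    key <- (k1 + B) + (k2 + B) * (3 * B) + (k3 + B) * (9 * B^2)
    ord <- order(key, t)
    lvo <- lv[ord]; keyo <- key[ord]; to <- t[ord]
    n <- length(lvo)
    newrun <- c(TRUE, keyo[-1] != keyo[-n] | to[-1] != to[-n] + 1 |
                  lvo[-1] != lvo[-n])
    starts <- which(newrun)
    lens <- diff(c(starts, n + 1L))
    cnt <- tabulate((lens - 1L) * G + lvo[starts], nbins = G * rmax)
    total <- total + cnt
    if (per_direction) per_dir[[r]] <- matrix(cnt, G, rmax)
  }
  m <- matrix(total, G, rmax)
  keep <- max(1L, max(which(colSums(m) > 0)))
  structure(m[, seq_len(keep), drop = FALSE], per_direction = per_dir)
}

# GLSZM as zone triplets (g = level, z = size, n = count of such zones).
glszm_from_levels <- function(lev, G) {
  dims <- dim(lev)
  idx <- which(!is.na(lev))
  lv <- lev[idx]
  lab <- connected_labels(idx, dims, values = lv)
  sizes <- tabulate(lab)
  zone_lev <- lv[match(seq_along(sizes), lab)]
  agg <- aggregate_keys((as.numeric(zone_lev) - 1) * (max(sizes) + 1) +
                          as.numeric(sizes))
  zmx <- max(sizes) + 1
  list(g = as.integer((agg$key) %/% zmx) + 1L,
       z = as.integer(agg$key %% zmx),
       n = agg$n, G = G)
}

ngtdm_from_levels <- function(lev, G) {
  msk <- !is.na(lev)
  lv0 <- lev; lv0[!msk] <- 0L
  nbsum <- array(0, dim(lev)); nbcnt <- array(0, dim(lev))
  offs <- neighbor_offsets_26()
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    nbsum <- nbsum + shift_array(lv0, d, 0)
    nbcnt <- nbcnt + shift_array(msk * 1, d, 0)
  }
  valid <- msk & nbcnt > 0
  g <- lev[valid]
  avg <- nbsum[valid] / nbcnt[valid]
  dev <- abs(g - avg)
  s <- numeric(G)
  agg <- rowsum(dev, g)
  s[as.integer(rownames(agg))] <- agg[, 1]
  n_i <- tabulate(g, nbins = G)
  list(s = s, n = n_i, p = n_i / sum(n_i), n_valid = sum(n_i))
}

#' Build the four texture matrices
#'
#' @param disc a `discretized_volume` (levels NA outside the mask).
#' @param per_direction keep per-direction GLRLM matrices (attribute of the
#'   `glrlm` element), used for conservation checks.
#' @return a `texture_matrix_set`: `glcm` (symmetric co-occurrence counts
#'   merged over 13 directions, sparse triplets `i`, `j`, `n`), `glrlm`
#'   (G x Rmax run-count matrix), `glszm` (zone triplets `g` = level, `z` =
#'   size, `n` = count; 26-connected), `ngtdm` (per-level absolute
#'   gray-tone difference sums `s`, counts `n`, probabilities `p`), plus
#'   `G` and the in-mask voxel count `n_vox`. Use [glcm_dense()] /
#'   [glszm_dense()] for conventional matrix views.
#' @export
build_matrices <- function(disc, per_direction = FALSE) {
  stopifnot(inherits(disc, "discretized_volume"))
  lev <- disc$levels
  G <- disc$G
  n_vox <- sum(!is.na(lev))
  structure(list(glcm = glcm_from_levels(lev, G),
                 glrlm = glrlm_from_levels(lev, G, per_direction),
                 glszm = glszm_from_levels(lev, G),
                 ngtdm = ngtdm_from_levels(lev, G),
                 G = G, n_vox = n_vox),
            class = "texture_matrix_set")
}

#' Dense views of the sparse texture matrices
#'
#' Intended for inspection and verification at small G; the dense GLCM is
#' G x G and the dense GLSZM G x (largest zone size).
#'
#' @param mats a `texture_matrix_set`.
#' @return numeric matrix of counts.
#' @export
glcm_dense <- function(mats) {
  G <- mats$G
  m <- matrix(0, G, G)
  m[cbind(mats$glcm$i, mats$glcm$j)] <- mats$glcm$n
  m
}

#' @rdname glcm_dense
#' @export
glszm_dense <- function(mats) {
  G <- mats$G
  zmax <- if (length(mats$glszm$z)) max(mats$glszm$z) else 1L
  m <- matrix(0, G, zmax)
  m[cbind(mats$glszm$g, mats$glszm$z)] <- mats$glszm$n
  m
}

# Helper for degenerate-aware feature assembly.
feat <- function(value, degenerate = FALSE) {
  list(value = if (degenerate) NA_real_ else value, degenerate = degenerate)
}

#' Texture features from a matrix set
#'
#' Standard descriptor formulas per family, computed on normalized
#' matrices: GLCM energy, contrast, correlation, homogeneity (inverse
#' difference moment), entropy (log2), dissimilarity, autocorrelation,
#' cluster shade/prominence and maximum probability; GLRLM SRE, LRE, GLN,
#' RLN, RP, LGRE, HGRE, SRLGE, SRHGE, GLV, RLV; GLSZM SZE, LZE, GLN, ZSN,
#' ZP, LGZE, HGZE, SZHGE, GLV, ZSV; NGTDM coarseness, contrast, busyness,
#' complexity, strength. Features whose value is undefined for a
#' degenerate matrix (single gray level) are flagged rather than silently
#' NaN.
#'
#' @param mats a `texture_matrix_set`.
#' @return list with `values` (named numeric, NA where degenerate) and
#'   `degenerate` (named logical).
#' @export
texture_features <- function(mats) {
  stopifnot(inherits(mats, "texture_matrix_set"))
  out <- list()

  ## GLCM (sparse triplets i, j, p)
  tot <- sum(mats$glcm$n)
  if (mats$G > 1L && tot > 0) {
    i <- mats$glcm$i; j <- mats$glcm$j
    p <- mats$glcm$n / tot
    px <- rowsum(p, i)              # marginal over occupied row levels
    lev_x <- as.integer(rownames(px))
    px <- px[, 1]
    mu_x <- sum(lev_x * px)
    var_x <- sum((lev_x - mu_x)^2 * px)
    out$glcm_energy <- feat(sum(p^2))
    out$glcm_contrast <- feat(sum((i - j)^2 * p))
    out$glcm_correlation <- if (var_x > 0)
      feat(sum((i - mu_x) * (j - mu_x) * p) / var_x) else feat(NA, TRUE)
    out$glcm_homogeneity <- feat(sum(p / (1 + (i - j)^2)))
    out$glcm_entropy <- feat(-sum(p * log2(p)))
    out$glcm_dissimilarity <- feat(sum(abs(i - j) * p))
    out$glcm_autocorrelation <- feat(sum(i * j * p))
    out$glcm_cluster_shade <- feat(sum((i + j - 2 * mu_x)^3 * p))
    out$glcm_cluster_prominence <- feat(sum((i + j - 2 * mu_x)^4 * p))
    out$glcm_max_probability <- feat(max(p))
  } else {
    for (nm in c("energy", "contrast", "correlation", "homogeneity",
                 "entropy", "dissimilarity", "autocorrelation",
                 "cluster_shade", "cluster_prominence", "max_probability"))
      out[[paste0("glcm_", nm)]] <- feat(NA, TRUE)
  }

  ## GLRLM
  R <- mats$glrlm
  nr <- sum(R)
  if (nr > 0 && mats$G > 1L) {
    G <- mats$G; L <- ncol(R)
    occ <- which(R > 0, arr.ind = TRUE)
    gl <- occ[, 1]; rl <- occ[, 2]
    pr <- R[occ] / nr
    mu_g <- sum(gl * pr)
    mu_r <- sum(rl * pr)
    out$glrlm_sre <- feat(sum(pr / rl^2))
    out$glrlm_lre <- feat(sum(pr * rl^2))
    out$glrlm_gln <- feat(sum(rowSums(R)^2) / nr)
    out$glrlm_rln <- feat(sum(colSums(R)^2) / nr)
    out$glrlm_rp <- feat(nr / (13 * mats$n_vox))
    out$glrlm_lgre <- feat(sum(pr / gl^2))
    out$glrlm_hgre <- feat(sum(pr * gl^2))
    out$glrlm_srlge <- feat(sum(pr / (gl^2 * rl^2)))
    out$glrlm_srhge <- feat(sum(pr * gl^2 / rl^2))
    out$glrlm_glv <- feat(sum(pr * (gl - mu_g)^2))
    out$glrlm_rlv <- feat(sum(pr * (rl - mu_r)^2))
  } else {
    for (nm in c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                 "srlge", "srhge", "glv", "rlv"))
      out[[paste0("glrlm_", nm)]] <- feat(NA, TRUE)
  }

  ## GLSZM (zone triplets g, z, n)
  nz_tot <- sum(mats$glszm$n)
  if (nz_tot > 0 && mats$G > 1L) {
    gl <- mats$glszm$g; zl <- mats$glszm$z
    pz <- mats$glszm$n / nz_tot
    mu_g <- sum(gl * pz)
    mu_z <- sum(zl * pz)
    out$glszm_sze <- feat(sum(pz / zl^2))
    out$glszm_lze <- feat(sum(pz * zl^2))
    out$glszm_gln <- feat(sum(rowsum(pz, gl)^2) * nz_tot)
    out$glszm_zsn <- feat(sum(rowsum(pz, zl)^2) * nz_tot)
    out$glszm_zp <- feat(nz_tot / mats$n_vox)
    out$glszm_lgze <- feat(sum(pz / gl^2))
    out$glszm_hgze <- feat(sum(pz * gl^2))
    out$glszm_szhge <- feat(sum(pz * gl^2 / zl^2))
    out$glszm_glv <- feat(sum(pz * (gl - mu_g)^2))
    out$glszm_zsv <- feat(sum(pz * (zl - mu_z)^2))
  } else {
    for (nm in c("sze", "lze", "gln", "zsn", "zp", "lgze", "hgze",
                 "szhge", "glv", "zsv"))
      out[[paste0("glszm_", nm)]] <- feat(NA, TRUE)
  }

  ## NGTDM (Amadasun & King conventions)
  nt <- mats$ngtdm
  occ <- which(nt$p > 0)
  if (length(occ) > 1L) {
    p <- nt$p; s <- nt$s
    ps <- sum(p * s)
    ii <- occ[rep(seq_along(occ), each = length(occ))]
    jj <- occ[rep(seq_along(occ), times = length(occ))]
    ng <- length(occ)
    out$ngtdm_coarseness <- if (ps > 0) feat(1 / ps) else feat(1e6)
    out$ngtdm_contrast <- feat(
      sum(p[ii] * p[jj] * (ii - jj)^2) / (ng * (ng - 1)) * sum(s) / nt$n_valid)
    busy_den <- sum(abs(ii * p[ii] - jj * p[jj]))
    out$ngtdm_busyness <- if (busy_den > 0) feat(ps / busy_den) else feat(NA, TRUE)
    out$ngtdm_complexity <- feat(
      sum(abs(ii - jj) * (p[ii] * s[ii] + p[jj] * s[jj]) /
            (p[ii] + p[jj])) / nt$n_valid)
    ssum <- sum(s)
    out$ngtdm_strength <- if (ssum > 0)
      feat(sum((p[ii] + p[jj]) * (ii - jj)^2) / ssum) else feat(NA, TRUE)
  } else {
    for (nm in c("coarseness", "contrast", "busyness", "complexity",
                 "strength"))
      out[[paste0("ngtdm_", nm)]] <- feat(NA, TRUE)
  }

  list(values = vapply(out, function(f) f$value, numeric(1)),
       degenerate = vapply(out, function(f) f$degenerate, logical(1)))
}
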
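# Independent brute-force oracles. Everything here is written with explicit
# loops against the documented definitions, deliberately sharing no code
# with the package implementation.

oracle_offsets26 <- function() {
  out <- NULL
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1)
    if (di != 0 || dj != 0 || dk != 0) out <- rbind(out, c(di, dj, dk))
  out
}

oracle_dirs13 <- function() {
  off <- oracle_offsets26()
  off[off[, 1] * 9 + off[, 2] * 3 + off[, 3] > 0, , drop = FALSE]
}

in_bounds <- function(v, d) all(v >= 1) && all(v <= d)

# Dense symmetric GLCM: count every ordered in-mask voxel pair at each of
# the 26 unit offsets.
oracle_glcm <- function(lev, G) {
  d <- dim(lev)
  m <- matrix(0, G, G)
  off <- oracle_offsets26()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lev[i, j, k])) next
    for (r in seq_len(nrow(off))) {
      v <- c(i, j, k) + off[r, ]
      if (!in_bounds(v, d)) next
      g2 <- lev[v[1], v[2], v[3]]
      if (is.na(g2)) next
      m[lev[i, j, k], g2] <- m[lev[i, j, k], g2] + 1
    }
  }
  m
}

# GLRLM merged over the 13 directions: walk every maximal run.
oracle_glrlm <- function(lev, G) {
  d <- dim(lev)
  rmax <- max(d)
  m <- matrix(0, G, rmax)
  dirs <- oracle_dirs13()
  for (r in seq_len(nrow(dirs))) {
    dd <- dirs[r, ]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      g <- lev[i, j, k]
      if (is.na(g)) next
      prev <- c(i, j, k) - dd
      if (in_bounds(prev, d) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
          lev[prev[1], prev[2], prev[3]] == g) next  # not a run start
      len <- 0
      v <- c(i, j, k)
      while (in_bounds(v, d) && !is.na(lev[v[1], v[2], v[3]]) &&
             lev[v[1], v[2], v[3]] == g) {
        len <- len + 1
        v <- v + dd
      }
      m[g, len] <- m[g, len] + 1
    }
  }
  m[, seq_len(max(1, max(which(colSums(m) > 0)))), drop = FALSE]
}

# GLSZM by explicit flood fill (26-connectivity).
oracle_glszm <- function(lev, G) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  off <- oracle_offsets26()
  zones <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lev[i, j, k]) || seen[i, j, k]) next
    g <- lev[i, j, k]
    stack <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(off))) {
        w <- v + off[r, ]
        if (!in_bounds(w, d)) next
        if (seen[w[1], w[2], w[3]]) next
        gw <- lev[w[1], w[2], w[3]]
        if (is.na(gw) || gw != g) next
        seen[w[1], w[2], w[3]] <- TRUE
        stack[[length(stack) + 1]] <- w
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  zm <- do.call(rbind, zones)
  m <- matrix(0, G, max(zm[, 2]))
  for (q in seq_len(nrow(zm))) m[zm[q, 1], zm[q, 2]] <- m[zm[q, 1], zm[q, 2]] + 1
  m
}

# NGTDM per-voxel neighbourhood averages.
oracle_ngtdm <- function(lev, G) {
  d <- dim(lev)
  off <- oracle_offsets26()
  s <- numeric(G); n <- numeric(G); n_valid <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    g <- lev[i, j, k]
    if (is.na(g)) next
    acc <- 0; cnt <- 0
    for (r in seq_len(nrow(off))) {
      v <- c(i, j, k) + off[r, ]
      if (!in_bounds(v, d)) next
      gv <- lev[v[1], v[2], v[3]]
      if (is.na(gv)) next
      acc <- acc + gv; cnt <- cnt + 1
    }
    if (cnt == 0) next
    s[g] <- s[g] + abs(g - acc / cnt)
    n[g] <- n[g] + 1
    n_valid <- n_valid + 1
  }
  list(s = s, n = n, p = n / n_valid, n_valid = n_valid)
}

# Naive feature formulas from the dense matrices (loops, no vectorization).
oracle_texture_features <- function(glcm, glrlm, glszm, ngtdm, n_vox) {
  out <- c()
  G <- nrow(glcm)
  p <- glcm / sum(glcm)
  px <- rowSums(p)
  mu <- 0; for (i in 1:G) mu <- mu + i * px[i]
  va <- 0; for (i in 1:G) va <- va + (i - mu)^2 * px[i]
  e <- ct <- cr <- hm <- en <- ds <- ac <- cs <- cp <- 0
  for (i in 1:G) for (j in 1:G) {
    pij <- p[i, j]
    e <- e + pij^2
    ct <- ct + (i - j)^2 * pij
    hm <- hm + pij / (1 + (i - j)^2)
    if (pij > 0) en <- en - pij * log2(pij)
    ds <- ds + abs(i - j) * pij
    ac <- ac + i * j * pij
    cs <- cs + (i + j - 2 * mu)^3 * pij
    cp <- cp + (i + j - 2 * mu)^4 * pij
    cr <- cr + (i - mu) * (j - mu) * pij
  }
  out["glcm_energy"] <- e
  out["glcm_contrast"] <- ct
  out["glcm_correlation"] <- cr / va
  out["glcm_homogeneity"] <- hm
  out["glcm_entropy"] <- en
  out["glcm_dissimilarity"] <- ds
  out["glcm_autocorrelation"] <- ac
  out["glcm_cluster_shade"] <- cs
  out["glcm_cluster_prominence"] <- cp
  out["glcm_max_probability"] <- max(p)

  R <- glrlm; nr <- sum(R); L <- ncol(R)
  sre <- lre <- lgre <- hgre <- srlge <- srhge <- 0
  mug <- mur <- 0
  for (g in 1:G) for (l in 1:L) {
    q <- R[g, l] / nr
    sre <- sre + q / l^2; lre <- lre + q * l^2
    lgre <- lgre + q / g^2; hgre <- hgre + q * g^2
    srlge <- srlge + q / (g^2 * l^2); srhge <- srhge + q * g^2 / l^2
    mug <- mug + g * q; mur <- mur + l * q
  }
  glv <- rlv <- 0
  for (g in 1:G) for (l in 1:L) {
    q <- R[g, l] / nr
    glv <- glv + q * (g - mug)^2; rlv <- rlv + q * (l - mur)^2
  }
  out["glrlm_sre"] <- sre; out["glrlm_lre"] <- lre
  out["glrlm_gln"] <- sum(rowSums(R)^2) / nr
  out["glrlm_rln"] <- sum(colSums(R)^2) / nr
  out["glrlm_rp"] <- nr / (13 * n_vox)
  out["glrlm_lgre"] <- lgre; out["glrlm_hgre"] <- hgre
  out["glrlm_srlge"] <- srlge; out["glrlm_srhge"] <- srhge
  out["glrlm_glv"] <- glv; out["glrlm_rlv"] <- rlv

  Z <- glszm; nz <- sum(Z); Lz <- ncol(Z)
  sze <- lze <- lgze <- hgze <- szhge <- mug <- muz <- 0
  for (g in 1:G) for (z in 1:Lz) {
    q <- Z[g, z] / nz
    sze <- sze + q / z^2; lze <- lze + q * z^2
    lgze <- lgze + q / g^2; hgze <- hgze + q * g^2
    szhge <- szhge + q * g^2 / z^2
    mug <- mug + g * q; muz <- muz + z * q
  }
  gv <- zv <- 0
  for (g in 1:G) for (z in 1:Lz) {
    q <- Z[g, z] / nz
    gv <- gv + q * (g - mug)^2; zv <- zv + q * (z - muz)^2
  }
  out["glszm_sze"] <- sze; out["glszm_lze"] <- lze
  out["glszm_gln"] <- sum(rowSums(Z)^2) / nz
  out["glszm_zsn"] <- sum(colSums(Z)^2) / nz
  out["glszm_zp"] <- nz / n_vox
  out["glszm_lgze"] <- lgze; out["glszm_hgze"] <- hgze
  out["glszm_szhge"] <- szhge
  out["glszm_glv"] <- gv; out["glszm_zsv"] <- zv

  p <- ngtdm$p; s <- ngtdm$s
  occ <- which(p > 0); ng <- length(occ)
  ps <- 0; for (i in occ) ps <- ps + p[i] * s[i]
  out["ngtdm_coarseness"] <- 1 / ps
  ctr <- 0; for (i in occ) for (j in occ) ctr <- ctr + p[i] * p[j] * (i - j)^2
  out["ngtdm_contrast"] <- ctr / (ng * (ng - 1)) * sum(s) / ngtdm$n_valid
  bd <- 0; for (i in occ) for (j in occ) bd <- bd + abs(i * p[i] - j * p[j])
  out["ngtdm_busyness"] <- ps / bd
  cx <- 0
  for (i in occ) for (j in occ)
    cx <- cx + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
  out["ngtdm_complexity"] <- cx / ngtdm$n_valid
  st <- 0; for (i in occ) for (j in occ) st <- st + (p[i] + p[j]) * (i - j)^2
  out["ngtdm_strength"] <- st / sum(s)
  out
}

# Random discretized test volume: dims d, G levels, optional mask holes.
random_level_volume <- function(d = c(6, 6, 6), G = 8, p_mask = 1) {
  lev <- array(sample.int(G, prod(d), replace = TRUE), d)
  if (p_mask < 1) {
    drop <- runif(prod(d)) > p_mask
    lev[drop] <- NA_integer_
    if (all(is.na(lev))) lev[1] <- 1L
  }
  lev
}

# Wrap a level array as a discretized_volume without going through a
# quantizer.
as_disc <- function(lev, G) {
  structure(list(levels = lev, G = as.integer(G), method = "fixed",
                 mapping = NULL),
            class = "discretized_volume")
}

# Exact two-sided Wilcoxon signed-rank p by recursive enumeration of all
# sign assignments (midranks, zeros dropped).
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- 0
  for (mask in 0:(2^n - 1)) {
    w <- 0
    for (b in 1:n) if (bitwAnd(mask, bitwShiftL(1L, b - 1L)) > 0) w <- w + r[b]
    ws <- c(ws, w)
  }
  ws <- ws[-1]
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Spearman r by the explicit Pearson-on-midranks formula, and exact
# permutation p over all n! permutations.
oracle_spearman <- function(a, b) {
  r_of <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    num <- sum((rx - mean(rx)) * (ry - mean(ry)))
    num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  r_obs <- r_of(a, b)
  n <- length(a)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  rs <- vapply(perms(seq_len(n)), function(p) r_of(a, b[p]), numeric(1))
  list(r = r_obs, p = mean(abs(rs) >= abs(r_obs) - 1e-12))
}
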
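# Voxel connectivity utilities. All mask operations in the package use
# 26-connectivity (full 3x3x3 neighbourhood), fixed by design.

# 26-neighbourhood offsets as a 26 x 3 integer matrix.
neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# The 13 unique 3-D directions (half of the 26 offsets, one per +/- pair).
directions_13 <- function() {
  off <- neighbor_offsets_26()
  key <- off[, 1] * 9 + off[, 2] * 3 + off[, 3]
  off[key > 0, , drop = FALSE]
}

# Connected-component labelling of a set of voxels.
#
# idx:    linear indices of the voxels to label (1-based).
# dims:   dimensions of the parent array.
# values: optional vector aligned with idx; when given, edges only join
#         voxels with equal values (used for GLSZM zones).
# Returns an integer vector of component labels aligned with idx.
connected_labels <- function(idx, dims, values = NULL) {
  nv <- length(idx)
  if (nv == 0L) return(integer(0))
  lookup <- integer(prod(dims))
  lookup[idx] <- seq_len(nv)
  co <- arrayInd(idx, dims)
  offs <- directions_13()
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    ok <- co[, 1] + d[1] >= 1L & co[, 1] + d[1] <= dims[1] &
          co[, 2] + d[2] >= 1L & co[, 2] + d[2] <= dims[2] &
          co[, 3] + d[3] >= 1L & co[, 3] + d[3] <= dims[3]
    if (!any(ok)) next
    nb_lin <- idx[ok] + d[1] + d[2] * dims[1] + d[3] * dims[1] * dims[2]
    nb_id <- lookup[nb_lin]
    hit <- nb_id > 0L
    if (!any(hit)) next
    a <- which(ok)[hit]; b <- nb_id[hit]
    if (!is.null(values)) {
      same <- values[a] == values[b]
      a <- a[same]; b <- b[same]
    }
    from <- c(from, a); to <- c(to, b)
  }
  if (length(from) == 0L) return(seq_len(nv))
  g <- igraph::make_graph(rbind(from, to), n = nv, directed = FALSE)
  as.integer(igraph::components(g)$membership)
}

# Connected component (26-connectivity) of `mask` containing `seed_idx`
# (linear index). Returns a logical array.
component_containing <- function(mask, seed_idx) {
  idx <- which(mask)
  if (!mask[seed_idx]) stop("seed voxel is not inside the candidate mask")
  lab <- connected_labels(idx, dim(mask))
  seed_lab <- lab[match(seed_idx, idx)]
  out <- array(FALSE, dim(mask))
  out[idx[lab == seed_lab]] <- TRUE
  out
}

# Binary dilation of a mask by `iterations` voxels (26-neighbourhood).
dilate_mask <- function(mask, iterations = 1L) {
  dims <- dim(mask)
  offs <- neighbor_offsets_26()
  for (it in seq_len(iterations)) {
    out <- mask
    for (r in seq_len(nrow(offs))) {
      d <- offs[r, ]
      src <- list(valid_range(dims[1], d[1]), valid_range(dims[2], d[2]),
                  valid_range(dims[3], d[3]))
      dst <- list(valid_range(dims[1], -d[1]), valid_range(dims[2], -d[2]),
                  valid_range(dims[3], -d[3]))
      out[dst[[1]], dst[[2]], dst[[3]]] <-
        out[dst[[1]], dst[[2]], dst[[3]]] | mask[src[[1]], src[[2]], src[[3]]]
    }
    mask <- out
  }
  mask
}

# Index range of a shifted overlap: source voxels i such that i + d stays
# within 1..n (empty when |d| >= n).
valid_range <- function(n, d) {
  if (abs(d) >= n) return(integer(0))
  if (d >= 0) seq_len(n - d) else seq.int(1 - d, n)
}
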
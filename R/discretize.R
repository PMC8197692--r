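# Intensity discretization: fixed bin width (FBW), fixed bin number (FBN)
# and equal-probability (histogram-equalization) quantization. The three
# quantizers have different invariance classes — FBW moves under any
# rescaling, FBN is invariant to positive affine maps, equal-probability
# quantization to any strictly monotone map — and that asymmetry is the
# mechanism behind discretization-dependent feature reproducibility.

#' Quantizer specification
#'
#' @param method `"fbw"` (fixed bin width), `"fbn"` (fixed bin number) or
#'   `"equal_prob"` (histogram equalization).
#' @param W bin width in SUV units (FBW); the study default is 0.01.
#' @param N number of levels (FBN / equal-probability); default 64.
#' @return a `quantizer_spec`.
#' @export
quantizer_spec <- function(method = c("fbw", "fbn", "equal_prob"),
                           W = 0.01, N = 64L) {
  method <- match.arg(method)
  stopifnot(W > 0, N >= 2)
  structure(list(method = method, W = W, N = as.integer(N)),
            class = "quantizer_spec")
}

# Discretized volume container: integer level array (NA outside mask), the
# number of levels G and the mapping record.
discretized_volume <- function(levels_arr, G, method, mapping) {
  structure(list(levels = levels_arr, G = as.integer(G), method = method,
                 mapping = mapping),
            class = "discretized_volume")
}

#' Discretize in-mask intensities
#'
#' Dispatches on the quantizer method. All quantizers are monotone (larger
#' intensity never maps to a smaller level) and assign every in-mask voxel
#' a level in `1..G`.
#'
#' @param values numeric 3-D array (e.g. `pet$values`); finite in-mask.
#' @param mask logical array selecting the voxels to discretize.
#' @param spec a `quantizer_spec`.
#' @return a `discretized_volume` with `levels` (integer array, NA outside
#'   the mask) and `G`.
#' @export
discretize <- function(values, mask, spec) {
  stopifnot(inherits(spec, "quantizer_spec"), any(mask))
  x <- values[mask]
  if (!all(is.finite(x))) stop("in-mask intensities must be finite")
  res <- switch(spec$method,
                fbw = levels_fbw(x, spec$W),
                fbn = levels_fbn(x, spec$N),
                equal_prob = levels_equal_prob(x, spec$N))
  arr <- array(NA_integer_, dim(values))
  arr[mask] <- res$lev
  discretized_volume(arr, res$G, spec$method, res$mapping)
}

# level(x) = floor((x - min) / W) + 1, anchored at the in-mask minimum.
levels_fbw <- function(x, W) {
  mn <- min(x)
  lev <- as.integer(floor((x - mn) / W + 1e-12)) + 1L
  G <- max(lev)
  list(lev = lev, G = G, mapping = list(anchor = mn, W = W))
}

# level(x) = floor(N (x - min) / (max - min)) + 1, max mapped to N.
levels_fbn <- function(x, N) {
  mn <- min(x); mx <- max(x)
  if (mx == mn) return(list(lev = rep(1L, length(x)), G = 1L,
                            mapping = list(min = mn, max = mx, N = N)))
  lev <- pmin(as.integer(floor(N * (x - mn) / (mx - mn))) + 1L, N)
  list(lev = lev, G = N, mapping = list(min = mn, max = mx, N = N))
}

# Histogram equalization: level(x) = ceiling(N * Fhat(x)) with Fhat the
# empirical CDF (ties share their maximal rank), so level occupancies are
# as even as tie groups permit and the mapping depends on ranks only.
levels_equal_prob <- function(x, N) {
  n <- length(x)
  Fhat <- rank(x, ties.method = "max") / n
  lev <- as.integer(ceiling(N * Fhat - 1e-12))
  lev[lev < 1L] <- 1L
  G <- max(lev)
  list(lev = lev, G = G, mapping = list(N = N, n = n))
}
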
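# System degradation operators: Gaussian PSF, grid coarsening, image-domain
# noise, background normalization and metal-artifact bias injection.

#' PET system model
#'
#' Collects the degradation parameters of one acquisition/reconstruction
#' arm: point-spread FWHM, reconstructed voxel size, image noise level
#' (standard deviation relative to the background mean) and the RNG seed
#' that makes the arm reproducible.
#'
#' @param psf_fwhm_mm Gaussian PSF full width at half maximum, mm (clinical
#'   PET range 2-10 mm; 4.8 mm for the analog systems, 4.2 mm digital).
#' @param voxel_size_mm reconstructed isotropic voxel size, mm.
#' @param noise_sd Gaussian noise SD as a fraction of the background mean.
#' @param seed integer RNG seed.
#' @return a `system_model`.
#' @export
system_model <- function(psf_fwhm_mm = 4.8, voxel_size_mm = 2,
                         noise_sd = 0, seed = 1L) {
  stopifnot(psf_fwhm_mm >= 0, voxel_size_mm > 0, noise_sd >= 0)
  if (psf_fwhm_mm > 0 && (psf_fwhm_mm < 2 || psf_fwhm_mm > 10))
    warning("psf_fwhm_mm outside the plausible PET range (2-10 mm)")
  structure(list(psf_fwhm_mm = psf_fwhm_mm, voxel_size_mm = voxel_size_mm,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "system_model")
}

# Separable Gaussian convolution with zero padding (total activity is
# conserved away from the borders). sigma in voxels, per axis. Implemented
# as shifted accumulation, which vectorizes well and avoids large
# intermediate matrices.
gaussian_blur_array <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- dnorm(seq(-r, r), sd = sigma_vox)
  k <- k / sum(k)
  dims <- dim(arr)
  for (axis in 1:3) {
    out <- array(0, dims)
    for (o in seq(-r, r)) {
      d <- c(0L, 0L, 0L); d[axis] <- o
      src <- list(valid_range(dims[1], d[1]), valid_range(dims[2], d[2]),
                  valid_range(dims[3], d[3]))
      dst <- list(valid_range(dims[1], -d[1]), valid_range(dims[2], -d[2]),
                  valid_range(dims[3], -d[3]))
      out[dst[[1]], dst[[2]], dst[[3]]] <-
        out[dst[[1]], dst[[2]], dst[[3]]] +
        k[o + r + 1] * arr[src[[1]], src[[2]], src[[3]]]
    }
    arr <- out
  }
  arr
}

# Box-average downsampling by an integer factor per axis; trailing voxels
# that do not fill a complete block are dropped.
block_average <- function(arr, f) {
  f <- as.integer(f)
  if (f == 1L) return(arr)
  d <- dim(arr)
  nd <- d %/% f
  arr <- arr[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f),
             drop = FALSE]
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    da <- dim(a)
    dim(a) <- c(f, length(a) / f)
    a <- colMeans(a)
    arr <- aperm(array(a, c(da[1] / f, da[2], da[3])), order(perm))
  }
  arr
}

#' Apply a system model to an activity map
#'
#' Emulates acquisition and reconstruction as a stationary Gaussian PSF
#' (sigma = FWHM / 2.3548) followed by grid-aligned box-average resampling
#' to the reconstructed voxel size and additive Gaussian image noise with
#' standard deviation `noise_sd * background mean`, clipped at zero. The
#' output is bit-reproducible for a fixed seed.
#'
#' @param activity a `volume_grid` activity map (simulation grid).
#' @param sys a `system_model`; `sys$voxel_size_mm` must be an integer
#'   multiple of the activity spacing.
#' @param bg_level background mean used to scale the noise; defaults to the
#'   median of the positive activity voxels (robust to hot lesions).
#' @return a `volume_grid` PET image at `sys$voxel_size_mm` spacing.
#' @export
apply_system <- function(activity, sys, bg_level = NULL) {
  stopifnot(inherits(activity, "volume_grid"), inherits(sys, "system_model"))
  sp <- activity$spacing_mm
  if (sys$voxel_size_mm < sp - 1e-9)
    stop("activity grid spacing must not exceed the target voxel size")
  f <- sys$voxel_size_mm / sp
  if (abs(f - round(f)) > 1e-9)
    stop("target voxel size must be an integer multiple of the grid spacing")
  f <- as.integer(round(f))
  if (sys$psf_fwhm_mm > 0 && sys$psf_fwhm_mm < sys$voxel_size_mm)
    warning("PSF FWHM is below the reconstructed voxel size")
  vals <- gaussian_blur_array(activity$values, sys$psf_fwhm_mm / 2.3548 / sp)
  vals <- block_average(vals, f)
  if (sys$noise_sd > 0) {
    if (is.null(bg_level)) {
      pos <- vals[vals > 0]
      bg_level <- if (length(pos)) median(pos) else 0
    }
    vals <- with_seed(sys$seed, {
      vals + rnorm(length(vals), sd = sys$noise_sd * bg_level)
    })
    vals <- array(pmax(vals, 0), dim(vals))
  }
  volume_grid(vals, spacing_mm = sys$voxel_size_mm,
              origin_mm = activity$origin_mm)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Normalize a PET image to unit background mean
#'
#' Divides the image by its mean over a background mask so the mean
#' background SUV equals 1 exactly; the operation is idempotent and
#' invariant to global positive scaling of the input.
#'
#' @param pet a `volume_grid`.
#' @param bg_mask logical array aligned with `pet`.
#' @return normalized `volume_grid`.
#' @export
normalize_background <- function(pet, bg_mask) {
  stopifnot(inherits(pet, "volume_grid"))
  if (!any(bg_mask)) stop("background mask is empty")
  m <- mean(pet$values[bg_mask])
  if (!is.finite(m) || m <= 0)
    stop("background mean must be positive for normalization")
  volume_grid(pet$values / m, pet$spacing_mm, pet$origin_mm)
}

#' Inject metal streak artifacts
#'
#' Adds radially alternating positive/negative streaks (sinusoidal angular
#' modulation decaying as 1/r) through each metal centre to the pseudo-CT,
#' and a multiplicative attenuation-correction-like bias to the PET image
#' near the metal. Bias amplitude scales with insert density relative to
#' stainless steel (7.700 g/cm3), so aluminum < titanium < steel. With
#' amplitude 0 both volumes are returned untouched.
#'
#' @param pseudo_ct,pet `volume_grid`s on the same grid.
#' @param artifact_spec list with `metals` (each `list(center_mm, density)`),
#'   `amplitude` (relative PET bias at the metal surface), `ct_amplitude`
#'   (HU), `r0_mm` (bias decay length) and `n_spokes` (streak count).
#' @return list with modified `pseudo_ct` and `pet`.
#' @export
inject_streaks <- function(pseudo_ct, pet, artifact_spec) {
  if (is.null(artifact_spec) || artifact_spec$amplitude == 0)
    return(list(pseudo_ct = pseudo_ct, pet = pet))
  ct <- pseudo_ct$values
  bias <- array(1, dim(pet$values))
  co_ct <- coord_arrays(pseudo_ct)
  co_pet <- coord_arrays(pet)
  for (metal in artifact_spec$metals) {
    rel <- metal$density / 7.7
    # CT streaks on the fine grid
    dx <- co_ct$x - metal$center_mm[1]; dy <- co_ct$y - metal$center_mm[2]
    r <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    ct <- ct + artifact_spec$ct_amplitude * rel *
      cos(artifact_spec$n_spokes * theta) / (1 + r / 10)
    # PET multiplicative bias (suppresses apparent uptake near the metal)
    dx <- co_pet$x - metal$center_mm[1]; dy <- co_pet$y - metal$center_mm[2]
    r <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    bias <- bias * (1 - artifact_spec$amplitude * rel * exp(-r / artifact_spec$r0_mm) *
                      (0.7 + 0.3 * cos(artifact_spec$n_spokes * theta)))
  }
  pv <- pmax(pet$values * bias, 0)
  list(pseudo_ct = volume_grid(ct, pseudo_ct$spacing_mm, pseudo_ct$origin_mm),
       pet = volume_grid(array(pv, dim(pet$values)), pet$spacing_mm,
                         pet$origin_mm))
}
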
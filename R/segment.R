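# The three delineation methods compared by the pipeline: pseudo-CT region
# growing (ground truth), the fixed 40%-of-maximum PET threshold, and the
# contrast-oriented adaptive threshold (COA).

#' Per-lesion search region
#'
#' A box or sphere (in voxel coordinates) that contains one lesion and its
#' true maximum-uptake voxel; PET segmentation methods search only inside
#' it (dilated by a small margin so blur-spread edges are not clipped).
#'
#' @param lo,hi integer length-3 corners (inclusive) for a box ROI.
#' @param center_vox,radius_vox centre and radius for a sphere ROI.
#' @return a `seed_roi`.
#' @export
roi_box <- function(lo, hi) {
  stopifnot(length(lo) == 3, length(hi) == 3, all(hi >= lo))
  structure(list(type = "box", lo = as.integer(lo), hi = as.integer(hi)),
            class = "seed_roi")
}

#' @rdname roi_box
#' @export
roi_sphere <- function(center_vox, radius_vox) {
  stopifnot(length(center_vox) == 3, radius_vox > 0)
  structure(list(type = "sphere", center = as.numeric(center_vox),
                 radius = as.numeric(radius_vox)), class = "seed_roi")
}

#' ROI derived from a mask: its bounding box plus a margin
#' @param mask logical array.
#' @param margin_vox margin added on every side, in voxels.
#' @return a `seed_roi` box.
#' @export
roi_from_mask <- function(mask, margin_vox = 2L) {
  idx <- which(mask)
  if (!length(idx)) stop("cannot derive an ROI from an empty mask")
  co <- arrayInd(idx, dim(mask))
  roi_box(pmax(apply(co, 2, min) - margin_vox, 1L),
          pmin(apply(co, 2, max) + margin_vox, dim(mask)))
}

# Logical membership array of an ROI.
roi_mask <- function(roi, dims) {
  out <- array(FALSE, dims)
  if (roi$type == "box") {
    out[roi$lo[1]:roi$hi[1], roi$lo[2]:roi$hi[2], roi$lo[3]:roi$hi[3]] <- TRUE
  } else {
    co <- arrayInd(seq_len(prod(dims)), dims)
    d2 <- (co[, 1] - roi$center[1])^2 + (co[, 2] - roi$center[2])^2 +
      (co[, 3] - roi$center[3])^2
    out[d2 <= roi$radius^2] <- TRUE
  }
  out
}

# Segmentation result container.
seg_mask <- function(mask, grid, method) {
  structure(list(mask = mask, method = method,
                 volume_ml = sum(mask) * voxel_volume_ml(grid),
                 spacing_mm = grid$spacing_mm),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask:%s> %d voxels, %.3f ml @ %g mm\n",
              x$method, sum(x$mask), x$volume_ml, x$spacing_mm))
  invisible(x)
}

#' Ground-truth segmentation by region growing on a pseudo-CT
#'
#' Gaussian-smooths the pseudo-CT (kernel radius in voxels; sigma is half
#' the radius) and grows a 26-connected region from the seed voxel,
#' including every connected voxel whose smoothed value lies inside the
#' Hounsfield window.
#'
#' @param pseudo_ct a `volume_grid` in HU-like units.
#' @param window numeric `(lo, hi)` inclusion window; default 50-150 HU,
#'   bracketing the 100 HU lesion material.
#' @param smooth_radius_vox Gaussian kernel radius in voxels.
#' @param seed_vox integer length-3 voxel index inside the lesion.
#' @return a `seg_mask` with method tag `"gt"`.
#' @export
segment_region_growing <- function(pseudo_ct, window = c(50, 150),
                                   smooth_radius_vox = 2L, seed_vox) {
  stopifnot(inherits(pseudo_ct, "volume_grid"), length(window) == 2)
  vals <- pseudo_ct$values
  if (smooth_radius_vox > 0)
    vals <- gaussian_blur_array(vals, smooth_radius_vox / 2)
  seed_idx <- vox_linear(seed_vox, dim(vals))
  if (vals[seed_idx] < window[1] || vals[seed_idx] > window[2])
    stop("seed voxel value falls outside the initialization window")
  inwin <- vals >= window[1] & vals <= window[2]
  seg_mask(component_containing(inwin, seed_idx), pseudo_ct, "gt")
}

vox_linear <- function(v, dims) {
  stopifnot(length(v) == 3, all(v >= 1), all(v <= dims))
  v <- as.integer(v)
  v[1] + (v[2] - 1L) * dims[1] + (v[3] - 1L) * dims[1] * dims[2]
}

#' Fixed 40%-of-maximum PET threshold segmentation
#'
#' Thresholds at `frac` times the ROI maximum and keeps the 26-connected
#' supra-threshold component containing the maximum voxel, searched within
#' the ROI dilated by `dilate_vox` voxels. The threshold is relative, so
#' the mask is invariant to global positive intensity scaling.
#'
#' @param pet a `volume_grid`.
#' @param roi a `seed_roi`.
#' @param frac threshold fraction of the ROI maximum (0.40 in the study).
#' @param dilate_vox ROI dilation margin in voxels.
#' @return a `seg_mask` with method tag `"th40"`.
#' @export
segment_threshold40 <- function(pet, roi, frac = 0.40, dilate_vox = 2L) {
  stopifnot(inherits(pet, "volume_grid"))
  dims <- dim(pet$values)
  rm0 <- roi_mask(roi, dims)
  if (!any(rm0)) stop("ROI is empty")
  vals_roi <- pet$values[rm0]
  vmax <- max(vals_roi)
  if (vmax == min(vals_roi)) {
    warning("ROI is constant; returning the whole ROI")
    return(seg_mask(rm0, pet, "th40"))
  }
  search <- dilate_mask(rm0, dilate_vox)
  max_idx <- which(rm0 & pet$values == vmax)[1]
  cand <- search & pet$values >= frac * vmax
  seg_mask(component_containing(cand, max_idx), pet, "th40")
}

#' Robust whole-image background level
#'
#' Estimates the background as the mode (kernel density peak) of the
#' intensities outside all lesion ROIs and above an air cutoff expressed as
#' a fraction of the image maximum.
#'
#' @param pet a `volume_grid`.
#' @param exclusion optional list of logical arrays (lesion regions to
#'   exclude), or a single array.
#' @param air_frac voxels below `air_frac` times the median positive
#'   intensity (after exclusions) are treated as air and dropped.
#' @return scalar background level.
#' @export
estimate_background <- function(pet, exclusion = NULL, air_frac = 0.5) {
  stopifnot(inherits(pet, "volume_grid"))
  keep <- array(TRUE, dim(pet$values))
  if (!is.null(exclusion)) {
    if (is.array(exclusion)) exclusion <- list(exclusion)
    for (m in exclusion) keep <- keep & !m
  }
  vals <- pet$values[keep]
  vals <- vals[vals > 0]
  if (!length(vals)) stop("no candidate background voxels remain")
  vals <- vals[vals > air_frac * median(vals)]
  if (!length(vals)) stop("no candidate background voxels remain")
  if (length(unique(vals)) == 1L) return(vals[1])
  d <- density(vals, n = 512)
  d$x[which.max(d$y)]
}

#' COA parameters
#' @param a weight on the mean of the 70\% isocontour.
#' @param b weight on the background level.
#' @param iso_fraction isocontour fraction of the ROI maximum.
#' @return a `coa_params`.
#' @export
coa_params <- function(a = 0.5, b = 0.5, iso_fraction = 0.70) {
  stopifnot(a >= 0, b >= 0, iso_fraction > 0, iso_fraction < 1)
  if (a + b > 1) warning("a + b > 1; the adaptive threshold may exceed I70")
  structure(list(a = a, b = b, iso_fraction = iso_fraction),
            class = "coa_params")
}

#' Contrast-oriented adaptive threshold segmentation (COA)
#'
#' Computes the mean intensity of the voxels at or above `iso_fraction`
#' of the ROI maximum (I70), sets the threshold `T = a * I70 + b * bg` and
#' keeps the 26-connected supra-threshold component containing the maximum
#' voxel. When the background is estimated from the same image the mask is
#' invariant to joint positive scaling of image and background.
#'
#' @param pet a `volume_grid`.
#' @param roi a `seed_roi`.
#' @param params a `coa_params`.
#' @param bg background level (see [estimate_background()]).
#' @param dilate_vox ROI dilation margin in voxels.
#' @return a `seg_mask` with method tag `"coa"`. If the threshold reaches
#'   the ROI maximum an error of class `phantomrad_empty_mask` is signalled
#'   so callers can skip the lesion and continue.
#' @export
segment_coa <- function(pet, roi, params = coa_params(), bg,
                        dilate_vox = 2L) {
  stopifnot(inherits(pet, "volume_grid"), inherits(params, "coa_params"),
            bg >= 0)
  dims <- dim(pet$values)
  rm0 <- roi_mask(roi, dims)
  if (!any(rm0)) stop("ROI is empty")
  vals_roi <- pet$values[rm0]
  vmax <- max(vals_roi)
  i70 <- mean(vals_roi[vals_roi >= params$iso_fraction * vmax])
  thr <- params$a * i70 + params$b * bg
  if (thr >= vmax)
    stop(structure(class = c("phantomrad_empty_mask", "error", "condition"),
                   list(message = sprintf(
                     "COA threshold %.4g reaches the ROI maximum %.4g", thr, vmax),
                     call = sys.call())))
  search <- dilate_mask(rm0, dilate_vox)
  max_idx <- which(rm0 & pet$values == vmax)[1]
  cand <- search & pet$values >= thr
  seg_mask(component_containing(cand, max_idx), pet, "coa")
}

#' Volume recovery coefficient
#'
#' Ratio of a mask volume to a reference mask volume (e.g. with-metal vs
#' without-metal segmentations of the same tube, or segmented vs truth).
#'
#' @param mask,ref `seg_mask` objects (or lists with a `volume_ml` field).
#' @return scalar RC.
#' @export
recovery_coefficient <- function(mask, ref) {
  if (ref$volume_ml <= 0) stop("reference volume must be positive")
  mask$volume_ml / ref$volume_ml
}
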
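#' 3-D scalar volume on an isotropic grid
#'
#' The universal carrier for activity maps, PET images and pseudo-CT volumes.
#' World coordinates follow the voxel-centre convention:
#' `world = origin_mm + (index - 0.5) * spacing_mm` for 1-based indices.
#'
#' @param values numeric 3-D array; all values must be finite.
#' @param spacing_mm positive isotropic voxel spacing in millimetres.
#' @param origin_mm numeric length-3 world position of the corner of the
#'   first voxel, in millimetres.
#' @return An object of class `volume_grid`.
#' @examples
#' v <- volume_grid(array(1, c(8, 8, 8)), spacing_mm = 2)
#' voxel_volume_ml(v)
#' @export
volume_grid <- function(values, spacing_mm = 1, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (!all(is.finite(values)))
    stop("`values` must be finite everywhere")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("`spacing_mm` must be a positive scalar")
  if (length(origin_mm) != 3L)
    stop("`origin_mm` must have length 3")
  structure(
    list(values = values, spacing_mm = as.numeric(spacing_mm),
         origin_mm = as.numeric(origin_mm)),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d @ %g mm  range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing_mm,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel volume in millilitres
#' @param grid a `volume_grid` (or a numeric spacing in mm).
#' @return scalar volume of one voxel in ml.
#' @export
voxel_volume_ml <- function(grid) {
  sp <- if (inherits(grid, "volume_grid")) grid$spacing_mm else grid
  sp^3 / 1000
}

#' World coordinates of voxel centres along one axis
#' @param grid a `volume_grid`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of centre positions in mm.
#' @export
axis_coords <- function(grid, axis) {
  n <- dim(grid$values)[axis]
  grid$origin_mm[axis] + (seq_len(n) - 0.5) * grid$spacing_mm
}

# Coordinate arrays (mm) for every voxel centre, as three arrays.
coord_arrays <- function(grid) {
  d <- dim(grid$values)
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  list(x = array(rep(xs, times = d[2] * d[3]), d),
       y = array(rep(rep(ys, each = d[1]), times = d[3]), d),
       z = array(rep(zs, each = d[1] * d[2]), d))
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over the RNifti package so phantom outputs and external
#' PET/mask volumes can move in and out of the pipeline. Masks are written
#' as uint8.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param grid a `volume_grid`.
#' @param mask logical 3-D array aligned with `grid`.
#' @return `read_volume` returns a `volume_grid`; writers return `path`
#'   invisibly.
#' @export
read_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI input")
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  if (max(sp) - min(sp) > 1e-6)
    stop("only isotropic volumes are supported")
  volume_grid(array(as.numeric(img), dim(img)), spacing_mm = sp[1])
}

#' @rdname read_volume
#' @export
write_volume <- function(grid, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI output")
  img <- RNifti::asNifti(grid$values, pixdim = rep(grid$spacing_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
write_mask <- function(mask, spacing_mm, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI output")
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)),
                         pixdim = rep(spacing_mm, 3), datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}
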
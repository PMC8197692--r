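# Declarative phantom scenes: geometric solids, layered lesions and the
# three study setups (single-lesion beds, a NEMA-IQ-like body, and a
# cheese-phantom calibration cylinder with metal/tissue inserts).

#' Geometric solids
#'
#' Solids are evaluated by the centre-point rule: a voxel belongs to a solid
#' when its centre does. Cylinders are axis-aligned with the z axis.
#'
#' @param center_mm length-3 centre in world mm.
#' @param radius_mm radius in mm.
#' @param height_mm full cylinder height in mm.
#' @return a `solid` specification list.
#' @export
solid_sphere <- function(center_mm, radius_mm) {
  stopifnot(length(center_mm) == 3, radius_mm > 0)
  structure(list(type = "sphere", center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm), class = "solid")
}

#' @rdname solid_sphere
#' @export
solid_cylinder <- function(center_mm, radius_mm, height_mm) {
  stopifnot(length(center_mm) == 3, radius_mm > 0, height_mm > 0)
  structure(list(type = "cylinder", center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm, height_mm = height_mm),
            class = "solid")
}

# Analytic volume of a solid in ml.
solid_volume_ml <- function(s) {
  switch(s$type,
         sphere = 4 / 3 * pi * s$radius_mm^3 / 1000,
         cylinder = pi * s$radius_mm^2 * s$height_mm / 1000,
         stop("unknown solid type"))
}

# Logical membership array of a solid on a grid (centre-point rule).
solid_mask <- function(s, grid) {
  co <- coord_arrays(grid)
  dx <- co$x - s$center_mm[1]
  dy <- co$y - s$center_mm[2]
  dz <- co$z - s$center_mm[3]
  if (s$type == "sphere") {
    dx^2 + dy^2 + dz^2 <= s$radius_mm^2
  } else {
    (dx^2 + dy^2 <= s$radius_mm^2) & (abs(dz) <= s$height_mm / 2)
  }
}

# Scale a solid about its own centre (linear factor).
scale_solid <- function(s, f, center_mm = s$center_mm) {
  s$center_mm <- center_mm
  s$radius_mm <- s$radius_mm * f
  if (s$type == "cylinder") s$height_mm <- s$height_mm * f
  s
}

#' Layered lesion specification
#'
#' A lesion is a nest of concentric, linearly scaled copies of one outer
#' solid. Layer i occupies the shell between scale fractions
#' `layer_fracs[i]` (outer) and `layer_fracs[i + 1]` (inner; the last layer
#' reaches the centre). `concentrations` are ordered outer to inner and are
#' expressed in the same arbitrary activity units as the scene background.
#'
#' @param outer a `solid` giving the full lesion extent.
#' @param concentrations positive numeric, one per layer, outer to inner.
#' @param layer_fracs decreasing fractions starting at 1, one per layer.
#' @param id lesion identifier string.
#' @return a `lesion_spec`.
#' @export
lesion_spec <- function(outer, concentrations, layer_fracs = NULL, id = "lesion") {
  nl <- length(concentrations)
  if (is.null(layer_fracs))
    layer_fracs <- seq(1, by = -1 / nl, length.out = nl)
  stopifnot(nl >= 1, all(concentrations > 0),
            length(layer_fracs) == nl, layer_fracs[1] == 1,
            all(diff(layer_fracs) < 0))
  structure(list(outer = outer, concentrations = as.numeric(concentrations),
                 layer_fracs = as.numeric(layer_fracs), id = id),
            class = "lesion_spec")
}

# Layer label map of a lesion on a grid: 0 outside, 1..nl outer to inner.
lesion_layer_map <- function(les, grid) {
  lab <- array(0L, dim(grid$values))
  for (i in seq_along(les$layer_fracs)) {
    m <- solid_mask(scale_solid(les$outer, les$layer_fracs[i]), grid)
    lab[m] <- i
  }
  lab
}

#' Heterogeneous multilayer lesion layouts
#'
#' Six three-layer cylindrical layouts (L1..L6) realise every permutation of
#' the high/medium/low concentrations over the outer/middle/inner shells.
#' L4..L6 carry their high concentration in the interior, the configuration
#' under which fixed-percentage PET thresholds reject the cold rim. Contrast
#' ratios are expressed as `(C_H/C_L, C_M/C_L)`; the low layer sits at
#' `c_l = 10 * c_bg` so the lesion-to-background contrast is 10.
#'
#' @param pattern integer 1..6.
#' @param ratio length-2 numeric `(C_H/C_L, C_M/C_L)`; one of (10,5), (8,4),
#'   (4,2) in the default study.
#' @param c_l low-layer concentration (activity units).
#' @param diameter_mm,height_mm outer cylinder size; the default exceeds
#'   three times the widest system FWHM so partial-volume effects stay small.
#' @param center_mm lesion centre.
#' @return a `lesion_spec`.
#' @export
lesion_layout <- function(pattern, ratio = c(10, 5), c_l = 10,
                          diameter_mm = 30, height_mm = 30,
                          center_mm = c(0, 0, 0)) {
  stopifnot(pattern %in% 1:6, length(ratio) == 2, ratio[1] > ratio[2])
  # permutations of (H, M, L) over (outer, middle, inner) shells
  perms <- list(c("H", "M", "L"), c("H", "L", "M"), c("M", "H", "L"),
                c("M", "L", "H"), c("L", "H", "M"), c("L", "M", "H"))
  conc <- c(H = c_l * ratio[1], M = c_l * ratio[2], L = c_l)
  outer <- solid_cylinder(center_mm, diameter_mm / 2, height_mm)
  lesion_spec(outer, unname(conc[perms[[pattern]]]),
              layer_fracs = c(1, 0.72, 0.42),
              id = sprintf("L%d_r%g_%g", pattern, ratio[1], ratio[2]))
}

#' Two-layer cylindrical lesion series V1..V8
#'
#' Lesion volumes grow geometrically from 1 ml (V1) to 15.6 ml (V8); each
#' lesion has a cold outer cylinder at `c_l` and a hot inner cylinder at
#' `6 * c_l`. The smallest members are strongly affected by partial-volume
#' blurring, the property the series is designed to expose.
#'
#' @param index integer 1..8.
#' @param c_l outer-layer concentration; inner layer is `contrast * c_l`.
#' @param contrast inner-to-outer concentration ratio.
#' @param center_mm lesion centre.
#' @return a `lesion_spec`.
#' @export
lesion_vseries <- function(index, c_l = 10, contrast = 6,
                           center_mm = c(0, 0, 0)) {
  stopifnot(index %in% 1:8)
  vol_ml <- 1 * (15.6 / 1)^((index - 1) / 7)
  # cylinder with height = diameter: V = 2 pi r^3
  r <- (vol_ml * 1000 / (2 * pi))^(1 / 3)
  outer <- solid_cylinder(center_mm, r, 2 * r)
  lesion_spec(outer, c(c_l, contrast * c_l),
              layer_fracs = c(1, 0.45^(1 / 3)),
              id = sprintf("V%d", index))
}

#' Phantom scene constructors
#'
#' A scene is a declarative layout: a background concentration, a bounding
#' box, a list of placed lesions, optional material inserts and an optional
#' metal-artifact specification. `scene_lesion_bed` hosts one lesion in a
#' warm background box (the in-silico analogue of a lesion placed in the
#' phantom); `scene_nema` mimics the NEMA image-quality phantom with six
#' fillable spheres and ten background spheres used as uniform regions of
#' interest; `scene_cheese` mimics a solid-water calibration cylinder with
#' metal/tissue inserts and fillable tubes.
#'
#' @param lesion a `lesion_spec`.
#' @param c_bg background concentration (activity units).
#' @param margin_mm background margin around the lesion bounding box.
#' @return a `phantom_scene`.
#' @export
scene_lesion_bed <- function(lesion, c_bg = 1, margin_mm = 16) {
  ext <- lesion_extent_mm(lesion)
  box <- ext + 2 * margin_mm
  center <- box / 2
  lesion$outer$center_mm <- center
  structure(list(kind = "lesion_bed", box_mm = box, c_bg = c_bg,
                 lesions = list(lesion), inserts = list(), body = NULL,
                 artifact = NULL),
            class = "phantom_scene")
}

lesion_extent_mm <- function(les) {
  s <- les$outer
  if (s$type == "sphere") rep(2 * s$radius_mm, 3)
  else c(2 * s$radius_mm, 2 * s$radius_mm, s$height_mm)
}

#' @rdname scene_lesion_bed
#' @param sphere_contrast fillable-sphere to background concentration ratio.
#' @export
scene_nema <- function(c_bg = 1, sphere_contrast = 10) {
  box <- c(220, 220, 160)
  center <- box / 2
  # six fillable spheres, NEMA IQ diameters (mm), on a 57 mm pitch circle
  d6 <- c(10, 13, 17, 22, 28, 37)
  ang <- seq(0, by = pi / 3, length.out = 6)
  lesions <- vector("list", 6)
  for (i in 1:6) {
    ctr <- center + c(57 * cos(ang[i]), 57 * sin(ang[i]), 0)
    lesions[[i]] <- lesion_spec(solid_sphere(ctr, d6[i] / 2),
                                concentrations = sphere_contrast * c_bg,
                                layer_fracs = 1,
                                id = sprintf("S%d_d%dmm", i, d6[i]))
  }
  # ten background spheres (5.7-8.4 ml), scripted placement on two rings
  dbg <- seq(22.2, 25.2, length.out = 10)
  rois <- vector("list", 10)
  for (i in 1:10) {
    a <- 2 * pi * (i - 1) / 10 + pi / 10
    z <- if (i %% 2 == 0) 45 else -45
    ctr <- center + c(62 * cos(a), 62 * sin(a), z)
    rois[[i]] <- lesion_spec(solid_sphere(ctr, dbg[i] / 2),
                             concentrations = c_bg, layer_fracs = 1,
                             id = sprintf("BG%02d", i))
  }
  body <- solid_cylinder(center, 100, 150)
  structure(list(kind = "nema", box_mm = box, c_bg = c_bg,
                 lesions = c(lesions, rois), inserts = list(), body = body,
                 artifact = NULL),
            class = "phantom_scene")
}

#' @rdname scene_lesion_bed
#' @param configuration `"pc"` (prostate) or `"hn"` (head-and-neck) insert
#'   layout.
#' @param metal `"water"`, `"aluminum"`, `"titanium"` or `"steel"`; the
#'   material occupying the metal-insert holes.
#' @param tube_contrast fillable-tube to background concentration ratio.
#' @export
scene_cheese <- function(configuration = c("pc", "hn"),
                         metal = c("water", "aluminum", "titanium", "steel"),
                         c_bg = 1, tube_contrast = 10) {
  configuration <- match.arg(configuration)
  metal <- match.arg(metal)
  densities <- c(water = 1.000, aluminum = 2.800, titanium = 4.500,
                 steel = 7.700)
  box <- c(320, 320, 190)
  center <- box / 2
  # three large (33 ml) and three small (11 ml) fillable tubes, 28 mm bore
  tube_r <- 14
  h_large <- 33000 / (pi * tube_r^2)
  h_small <- 11000 / (pi * tube_r^2)
  if (configuration == "pc") {
    tube_pos <- list(TL1 = c(-40, 20), TL2 = c(55, 45), TL3 = c(-90, -60),
                     TS1 = c(25, -35), TS2 = c(90, 25), TS3 = c(-45, 95))
    metal_pos <- list(c(0, -5), c(-15, 60))
  } else {
    tube_pos <- list(TL1 = c(70, -30), TL2 = c(-30, 40), TL3 = c(-80, -40),
                     TS1 = c(95, 40), TS2 = c(10, 75), TS3 = c(-40, -90))
    metal_pos <- list(c(0, 10))
  }
  lesions <- vector("list", 6)
  for (i in seq_along(tube_pos)) {
    nm <- names(tube_pos)[i]
    h <- if (startsWith(nm, "TL")) h_large else h_small
    ctr <- center + c(tube_pos[[i]], 0)
    lesions[[i]] <- lesion_spec(solid_cylinder(ctr, tube_r, h),
                                concentrations = tube_contrast * c_bg,
                                layer_fracs = 1, id = nm)
  }
  inserts <- lapply(metal_pos, function(p)
    list(material = metal, density = unname(densities[metal]),
         solid = solid_cylinder(center + c(p, 0), tube_r, 70)))
  artifact <- if (metal == "water") NULL else
    list(metals = lapply(inserts, function(ins)
           list(center_mm = ins$solid$center_mm, density = ins$density)),
         amplitude = 0.15, ct_amplitude = 800, r0_mm = 40, n_spokes = 12)
  body <- solid_cylinder(center, 150, 180)
  structure(list(kind = "cheese", box_mm = box, c_bg = c_bg,
                 lesions = lesions, inserts = inserts, body = body,
                 artifact = artifact),
            class = "phantom_scene")
}

#' Rasterise a phantom scene
#'
#' Produces the noiseless activity map, exact per-lesion ground truth and a
#' pseudo-CT substrate on a grid of the requested spacing. Voxel membership
#' uses the centre-point rule, so voxelised volumes converge to the analytic
#' solid volumes as the spacing shrinks. Lesion material maps to 100 HU
#' (inside the 50-150 HU region-growing window), water/background to 0 HU,
#' air to -1000 HU and inserts to `1000 * (density - 1)` HU.
#'
#' @param scene a `phantom_scene`.
#' @param spacing_mm simulation grid spacing; the default 1 mm keeps
#'   voxelisation error well below the degradation effects under study.
#' @return list with elements `activity` and `pseudo_ct` (`volume_grid`s)
#'   and `truth`, a list with one entry per lesion carrying `mask`,
#'   `layer_map`, `volume_ml` (voxelised) and `analytic_volume_ml`.
#' @export
build_scene <- function(scene, spacing_mm = 1) {
  stopifnot(inherits(scene, "phantom_scene"))
  dims <- pmax(ceiling(scene$box_mm / spacing_mm), 8L)
  grid <- volume_grid(array(0, dims), spacing_mm = spacing_mm)
  act <- array(scene$c_bg, dims)
  ct <- array(0, dims)
  if (!is.null(scene$body)) {
    inside <- solid_mask(scene$body, grid)
    act[!inside] <- 0
    ct[!inside] <- -1000
  }
  occupied <- array(FALSE, dims)
  truth <- vector("list", length(scene$lesions))
  names(truth) <- vapply(scene$lesions, function(l) l$id, character(1))
  for (i in seq_along(scene$lesions)) {
    les <- scene$lesions[[i]]
    lab <- lesion_layer_map(les, grid)
    mask <- lab > 0L
    nvox <- sum(mask)
    if (nvox < 1L)
      stop(sprintf("lesion '%s' is smaller than one voxel at %g mm spacing",
                   les$id, spacing_mm))
    if (any(occupied & mask))
      stop(sprintf("lesion '%s' overlaps a previously placed object", les$id))
    occupied <- occupied | mask
    act[mask] <- les$concentrations[lab[mask]]
    ct[mask] <- 100
    truth[[i]] <- list(id = les$id, mask = mask, layer_map = lab,
                       volume_ml = nvox * voxel_volume_ml(grid),
                       analytic_volume_ml = solid_volume_ml(les$outer),
                       concentrations = les$concentrations)
  }
  for (ins in scene$inserts) {
    m <- solid_mask(ins$solid, grid)
    if (any(occupied & m))
      stop("insert overlaps a previously placed object")
    occupied <- occupied | m
    act[m] <- 0
    ct[m] <- 1000 * (ins$density - 1)
  }
  list(activity = volume_grid(act, spacing_mm),
       pseudo_ct = volume_grid(ct, spacing_mm),
       truth = truth)
}

#' Voxelise lesion ground-truth masks on an arbitrary grid
#'
#' Re-rasterises the scene's lesions on a (typically coarser) output grid
#' so segmentation accuracy can be judged on the grid the PET image lives
#' on.
#'
#' @param scene a `phantom_scene`.
#' @param grid a `volume_grid` defining the target geometry.
#' @return list of per-lesion truth entries (see [build_scene()]).
#' @export
voxelize_truth <- function(scene, grid) {
  out <- vector("list", length(scene$lesions))
  names(out) <- vapply(scene$lesions, function(l) l$id, character(1))
  for (i in seq_along(scene$lesions)) {
    les <- scene$lesions[[i]]
    lab <- lesion_layer_map(les, grid)
    mask <- lab > 0L
    out[[i]] <- list(id = les$id, mask = mask, layer_map = lab,
                     volume_ml = sum(mask) * voxel_volume_ml(grid),
                     analytic_volume_ml = solid_volume_ml(les$outer),
                     concentrations = les$concentrations)
  }
  out
}
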
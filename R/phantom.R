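#' Phantom specification
#'
#' Describes an idealized trabecular geometry with known analytic
#' morphometry: parallel plates (the SMI = 0 limit), a square lattice of
#' cylindrical rods (the SMI = 3 limit), a solid ball (SMI = 4), or a mixed
#' plate/rod volume.  Phantoms are the ground-truth substrate for validating
#' every morphometric estimator without real scans.
#'
#' All lengths are in micrometres.  Features must span at least 2 voxels to
#' be representable; [make_phantom()] errors otherwise.
#'
#' @param kind One of `"parallel_plates"`, `"square_lattice_rods"`,
#'   `"solid_ball"`, `"mixed"`.
#' @param plate_thickness_um,plate_spacing_um Plate thickness and gap
#'   (plates are perpendicular to the third axis).
#' @param rod_radius_um,rod_pitch_um Rod radius and centre-to-centre pitch
#'   (rods run along the third axis).
#' @param ball_radius_um Radius of the solid ball.
#' @param voxel_um Isotropic voxel size.
#' @param shape_voxels Integer triple: volume dimensions in voxels.
#' @param tilt_deg Optional rotation (degrees, about the second axis) of the
#'   plate normal / rod axis, to probe orientation-invariance of the
#'   estimators.  Analytic ground truth is unchanged by a rigid rotation.
#' @return A list of class `phantom_spec`.
#' @seealso [make_phantom()]
#' @export
phantom_spec <- function(kind = c("parallel_plates", "square_lattice_rods",
                                  "solid_ball", "mixed"),
                         plate_thickness_um = 100, plate_spacing_um = 400,
                         rod_radius_um = 50, rod_pitch_um = 500,
                         ball_radius_um = 200,
                         voxel_um = 10,
                         shape_voxels = c(100L, 100L, 100L),
                         tilt_deg = 0) {
  kind <- match.arg(kind)
  if (voxel_um <= 0) abort("`voxel_um` must be positive.")
  shape_voxels <- as.integer(shape_voxels)
  if (length(shape_voxels) != 3L || any(shape_voxels < 8L)) {
    abort("`shape_voxels` must be three integers, each >= 8.")
  }
  lens <- c(plate_thickness_um, plate_spacing_um, rod_radius_um,
            rod_pitch_um, ball_radius_um)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    abort("all phantom lengths must be positive and finite.")
  }
  if (kind %in% c("parallel_plates", "mixed") &&
      plate_thickness_um + plate_spacing_um > shape_voxels[3] * voxel_um) {
    abort("plate period exceeds the volume extent along the third axis.")
  }
  structure(list(kind = kind,
                 plate_thickness_um = plate_thickness_um,
                 plate_spacing_um = plate_spacing_um,
                 rod_radius_um = rod_radius_um,
                 rod_pitch_um = rod_pitch_um,
                 ball_radius_um = ball_radius_um,
                 voxel_um = voxel_um,
                 shape_voxels = shape_voxels,
                 tilt_deg = tilt_deg),
            class = "phantom_spec")
}

# voxel-centre coordinate grids in um, as three vectors
phantom_coords <- function(spec) {
  lapply(spec$shape_voxels, function(n) (seq_len(n) - 0.5) * spec$voxel_um)
}

phantom_plates_mask <- function(spec) {
  t <- spec$plate_thickness_um
  s <- spec$plate_spacing_um
  vx <- spec$voxel_um
  if (t < 2 * vx || s < 2 * vx) {
    abort("plate thickness and spacing must each span at least 2 voxels.")
  }
  co <- phantom_coords(spec)
  period <- t + s
  theta <- spec$tilt_deg * pi / 180
  # phase-shift by half a gap so plates do not touch the volume boundary
  if (theta == 0) {
    inplate <- ((co[[3]] - s / 2) %% period) < t
    array(rep(inplate, each = spec$shape_voxels[1] * spec$shape_voxels[2]),
          spec$shape_voxels)
  } else {
    # plate normal rotated in the x-z plane
    u <- outer(co[[1]] * sin(theta), co[[3]] * cos(theta), `+`) # nx x nz
    inplate <- ((u - s / 2) %% period) < t
    aperm(array(rep(inplate, times = spec$shape_voxels[2]),
                c(spec$shape_voxels[1], spec$shape_voxels[3],
                  spec$shape_voxels[2])),
          c(1, 3, 2))
  }
}

phantom_rods_mask <- function(spec) {
  r <- spec$rod_radius_um
  p <- spec$rod_pitch_um
  vx <- spec$voxel_um
  if (r < vx) abort("rod diameter must span at least 2 voxels.")
  if (p < 2 * r) abort("rod pitch must be at least the rod diameter.")
  co <- phantom_coords(spec)
  # rods along z on a square x-y lattice; axes snapped to voxel centres so
  # the discrete maximal inscribed sphere matches the analytic one
  o <- (floor((p / 2) / vx) + 0.5) * vx
  dx <- ((co[[1]] - o + p / 2) %% p) - p / 2
  dy <- ((co[[2]] - o + p / 2) %% p) - p / 2
  d2 <- outer(dx^2, dy^2, `+`)
  sect <- d2 <= r^2
  array(rep(sect, times = spec$shape_voxels[3]), spec$shape_voxels)
}

phantom_ball_mask <- function(spec) {
  r <- spec$ball_radius_um
  vx <- spec$voxel_um
  if (r < vx) abort("ball diameter must span at least 2 voxels.")
  co <- phantom_coords(spec)
  ext <- spec$shape_voxels * vx
  if (2 * r >= min(ext)) abort("ball does not fit inside the volume.")
  # centre on a voxel centre (see rods)
  ctr <- (floor(spec$shape_voxels / 2) - 0.5) * vx
  d2 <- outer(outer((co[[1]] - ctr[1])^2, (co[[2]] - ctr[2])^2, `+`),
              (co[[3]] - ctr[3])^2, `+`)
  array(d2 <= r^2, spec$shape_voxels)
}

#' Generate a phantom volume with analytic ground truth
#'
#' Renders a [phantom_spec()] to a binary [voxel_volume()].  The analytic
#' morphometry of the geometry (bone volume fraction, thickness, separation,
#' trabecular number, SMI, connectivity density, where defined in closed
#' form) is attached as `ground_truth` metadata; `NA` marks quantities with
#' no closed form for that geometry.  Deterministic given the spec.
#'
#' @param spec A [phantom_spec()].
#' @return A [voxel_volume()] with a `ground_truth` attribute.
#' @examples
#' ph <- make_phantom(phantom_spec("parallel_plates",
#'   plate_thickness_um = 100, plate_spacing_um = 400,
#'   voxel_um = 10, shape_voxels = c(40, 40, 100)))
#' attr(ph, "ground_truth")$BVTV # 0.2
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  t <- spec$plate_thickness_um; s <- spec$plate_spacing_um
  r <- spec$rod_radius_um; p <- spec$rod_pitch_um
  rb <- spec$ball_radius_um
  gt <- switch(spec$kind,
    parallel_plates = list(
      BVTV = t / (t + s), TbN = 1000 / (t + s), ConnD = 0,
      TbSp = s / 1000, SMI = 0, TbTh = t / 1000),
    square_lattice_rods = list(
      BVTV = pi * r^2 / p^2, TbN = NA_real_, ConnD = 0,
      TbSp = NA_real_, SMI = 3, TbTh = 2 * r / 1000),
    solid_ball = {
      ext <- spec$shape_voxels * spec$voxel_um
      list(BVTV = (4 / 3) * pi * rb^3 / prod(ext), TbN = NA_real_,
           ConnD = 0, TbSp = NA_real_, SMI = 4, TbTh = 2 * rb / 1000)
    },
    mixed = list(
      BVTV = (t / (t + s) + pi * r^2 / p^2) / 2, TbN = NA_real_,
      ConnD = 0, TbSp = NA_real_, SMI = NA_real_, TbTh = NA_real_))
  mask <- switch(spec$kind,
    parallel_plates = phantom_plates_mask(spec),
    square_lattice_rods = phantom_rods_mask(spec),
    solid_ball = phantom_ball_mask(spec),
    mixed = {
      # plates in the lower half (third axis), rods in the upper half
      m1 <- phantom_plates_mask(spec)
      m2 <- phantom_rods_mask(spec)
      nz <- spec$shape_voxels[3]
      half <- nz %/% 2
      m1[, , (half + 1):nz] <- m2[, , (half + 1):nz]
      m1
    })
  voxel_volume(mask, voxel_um = spec$voxel_um, ground_truth = gt)
}

#' Voxelized solid torus
#'
#' Test geometry for connectivity estimators: a solid torus has Euler
#' characteristic 0 and exactly one independent loop (first Betti number 1).
#'
#' @param major_um,minor_um Major (tube centre-line) and minor (tube) radii,
#'   micrometres.  The torus axis is the third axis.
#' @param voxel_um Voxel size, micrometres.
#' @param shape_voxels Volume dimensions in voxels.
#' @return A [voxel_volume()].
#' @export
torus_volume <- function(major_um, minor_um, voxel_um,
                         shape_voxels = NULL) {
  if (minor_um < voxel_um) abort("torus tube must span at least 2 voxels.")
  if (is.null(shape_voxels)) {
    need <- ceiling(2 * (major_um + minor_um) / voxel_um) + 4
    shape_voxels <- c(need, need, ceiling(2 * minor_um / voxel_um) + 4)
  }
  shape_voxels <- pmax(as.integer(shape_voxels), 8L)
  co <- lapply(shape_voxels, function(n) (seq_len(n) - 0.5) * voxel_um)
  ext <- shape_voxels * voxel_um
  ctr <- ext / 2
  rho <- sqrt(outer((co[[1]] - ctr[1])^2, (co[[2]] - ctr[2])^2, `+`))
  mask <- array(FALSE, shape_voxels)
  for (k in seq_len(shape_voxels[3])) {
    mask[, , k] <- (rho - major_um)^2 + (co[[3]][k] - ctr[3])^2 <= minor_um^2
  }
  voxel_volume(mask, voxel_um = voxel_um,
               ground_truth = list(euler = 0L, beta1 = 1L))
}
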
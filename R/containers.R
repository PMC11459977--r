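## Core containers. Conventions used throughout the package:
##  - image arrays have dim c(nz, ny, nx): z (axial) fastest, x slowest;
##  - all lengths in mm, angles in degrees, attenuation in mm^-1;
##  - the volume centre sits on the axis of rotation (plus `origin` offset);
##  - projection stacks have dim c(n_views, n_axial, n_transaxial).

#' Create an image volume
#'
#' A 3D voxel grid with isotropic in-plane spacing and explicit axial spacing.
#' Axes follow the tomographic convention: `voxels[iz, iy, ix]` with x and y
#' transaxial and z axial; the grid centre lies at `origin` relative to the
#' axis of rotation.
#'
#' @param voxels numeric 3D array with dim `c(nz, ny, nx)`.
#' @param voxel_size in-plane voxel size (mm), isotropic in x and y.
#' @param z_spacing axial voxel size (mm); defaults to `voxel_size`.
#' @param origin length-3 offset (mm) of the volume centre, `c(x, y, z)`.
#' @return object of class `image_volume`.
#' @export
image_volume <- function(voxels, voxel_size, z_spacing = voxel_size,
                         origin = c(0, 0, 0)) {
  stopifnot(is.numeric(voxels), length(dim(voxels)) == 3,
            voxel_size > 0, z_spacing > 0, length(origin) == 3)
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 z_spacing = z_spacing, origin = as.numeric(origin)),
            class = "image_volume")
}

#' Create an empty image volume on a given grid
#'
#' @param n length-3 `c(nz, ny, nx)` or a single integer for a cubic grid.
#' @inheritParams image_volume
#' @param value fill value.
#' @export
empty_volume <- function(n, voxel_size, z_spacing = voxel_size,
                         origin = c(0, 0, 0), value = 0) {
  if (length(n) == 1) n <- rep(n, 3)
  image_volume(array(value, dim = n), voxel_size, z_spacing, origin)
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d (z,y,x), %.3g mm in-plane, %.3g mm axial\n",
              d[1], d[2], d[3], x$voxel_size, x$z_spacing))
  invisible(x)
}

## grid geometry as plain scalars for the C++ core
grid_geom <- function(vol) {
  d <- dim(vol$voxels)
  list(nz = d[1], ny = d[2], nx = d[3],
       dx = vol$voxel_size, dz = vol$z_spacing,
       ox = vol$origin[1], oy = vol$origin[2], oz = vol$origin[3])
}

## voxel-centre coordinates along each axis
voxel_coords <- function(vol) {
  g <- grid_geom(vol)
  list(x = g$ox + (seq_len(g$nx) - 1 - (g$nx - 1) / 2) * g$dx,
       y = g$oy + (seq_len(g$ny) - 1 - (g$ny - 1) / 2) * g$dx,
       z = g$oz + (seq_len(g$nz) - 1 - (g$nz - 1) / 2) * g$dz)
}

#' Create a circular-orbit specification
#'
#' @param n_angles number of projection angles (>= 1).
#' @param initial_angle starting angle (deg).
#' @param angular_increment per-view increment (deg); positive =
#'   counterclockwise, negative = clockwise.
#' @param n_orbits number of identical repeated orbits (summed).
#' @param axial_position axial offset (mm) of the detector centre relative to
#'   the reconstructed volume.
#' @return object of class `orbit_spec`.
#' @export
orbit_spec <- function(n_angles, initial_angle = 180, angular_increment = 3,
                       n_orbits = 1, axial_position = 0) {
  stopifnot(n_angles >= 1, abs(angular_increment) > 0, n_orbits >= 1)
  structure(list(n_angles = as.integer(n_angles),
                 initial_angle = initial_angle,
                 angular_increment = angular_increment,
                 n_orbits = as.integer(n_orbits),
                 axial_position = axial_position),
            class = "orbit_spec")
}

#' Create projection data
#'
#' @param views numeric array `c(n_views, n_axial, n_transaxial)` of counts.
#' @param bin_size square detector bin size (mm).
#' @param detector_radius radius at the face of the scintillation crystal (mm).
#' @param orbit an [orbit_spec()].
#' @return object of class `projection_data`.
#' @export
projection_data <- function(views, bin_size, detector_radius, orbit) {
  stopifnot(is.numeric(views), length(dim(views)) == 3, bin_size > 0,
            inherits(orbit, "orbit_spec"))
  if (dim(views)[1] != orbit$n_angles)
    stop("number of views (", dim(views)[1], ") does not match orbit n_angles (",
         orbit$n_angles, ")")
  if (any(!is.finite(views)) || any(views < 0))
    stop("projection values must be finite and non-negative")
  structure(list(views = views, bin_size = bin_size,
                 detector_radius = detector_radius, orbit = orbit),
            class = "projection_data")
}

#' @export
print.projection_data <- function(x, ...) {
  d <- dim(x$views)
  cat(sprintf("<projection_data> %d views of %d x %d bins, %.3g mm, detector radius %.3g mm\n",
              d[1], d[2], d[3], x$bin_size, x$detector_radius))
  invisible(x)
}

#' Create a pinhole aperture specification
#'
#' @param position length-3 `c(x', y', z')` (mm) in the rotating collimator
#'   frame; y' points toward the detector.
#' @param shape `"round"` or `"rectangular"`.
#' @param size diameter (mm) for round holes, or `c(width, height)` (mm).
#' @param tilt tilt of the hole axis about z' (deg).
#' @param acceptance_angle half-angle of the acceptance cone (deg), in (0, 90).
#' @param detector_element identifier of the detector segment the hole exposes.
#' @export
hole_spec <- function(position, shape = c("round", "rectangular"), size,
                      tilt = 0, acceptance_angle = 45, detector_element = 1L) {
  shape <- match.arg(shape)
  stopifnot(length(position) == 3, all(size > 0),
            acceptance_angle > 0, acceptance_angle < 90)
  if (shape == "round" && length(size) != 1)
    stop("round holes take a single diameter")
  if (shape == "rectangular" && length(size) != 2)
    stop("rectangular holes take c(width, height)")
  structure(list(position = as.numeric(position), shape = shape,
                 size = as.numeric(size), tilt = tilt,
                 acceptance_angle = acceptance_angle,
                 detector_element = as.integer(detector_element)),
            class = "hole_spec")
}

#' Create collimator parameters
#'
#' @param radius_of_rotation distance from the axis of rotation to the aperture
#'   plane (mm).
#' @param geometry `"cylindrical"` or `"polygonal"`.
#' @param holes list of [hole_spec()] objects (at least one).
#' @export
collimator_params <- function(radius_of_rotation,
                              geometry = c("cylindrical", "polygonal"),
                              holes) {
  geometry <- match.arg(geometry)
  if (inherits(holes, "hole_spec")) holes <- list(holes)
  stopifnot(radius_of_rotation > 0, length(holes) >= 1,
            all(vapply(holes, inherits, TRUE, "hole_spec")))
  structure(list(radius_of_rotation = radius_of_rotation, geometry = geometry,
                 holes = holes),
            class = "collimator_params")
}

## holes as the plain matrix the C++ core consumes
holes_matrix <- function(collimator) {
  m <- t(vapply(collimator$holes, function(h) {
    c(h$position,
      if (h$shape == "round") 0 else 1,
      h$size[1], if (length(h$size) > 1) h$size[2] else h$size[1],
      h$tilt, h$acceptance_angle)
  }, numeric(8)))
  colnames(m) <- c("x", "y", "z", "shape", "w", "h", "tilt", "acc")
  m
}

#' Create detector parameters
#'
#' Bundles the camera description: intrinsic resolution for PSF correction,
#' scintillation-crystal attributes for DOI correction, the detector bin grid,
#' and the acquisition orbit.
#'
#' @param intrinsic_resolution intrinsic detector FWHM (mm), >= 0.
#' @param crystal_thickness scintillation crystal thickness (mm), > 0.
#' @param crystal_attenuation linear attenuation of the crystal at the imaging
#'   photon energy (mm^-1), >= 0.
#' @param detector_radius radius at the crystal face (mm).
#' @param orbit an [orbit_spec()].
#' @param n_transaxial,n_axial detector bin counts.
#' @param bin_size square bin size (mm).
#' @export
detector_params <- function(intrinsic_resolution, crystal_thickness,
                            crystal_attenuation, detector_radius, orbit,
                            n_transaxial, n_axial = n_transaxial, bin_size) {
  stopifnot(intrinsic_resolution >= 0, crystal_thickness > 0,
            crystal_attenuation >= 0, detector_radius > 0,
            inherits(orbit, "orbit_spec"), n_transaxial >= 1, n_axial >= 1,
            bin_size > 0)
  structure(list(intrinsic_resolution = intrinsic_resolution,
                 crystal_thickness = crystal_thickness,
                 crystal_attenuation = crystal_attenuation,
                 detector_radius = detector_radius, orbit = orbit,
                 n_transaxial = as.integer(n_transaxial),
                 n_axial = as.integer(n_axial), bin_size = bin_size),
            class = "detector_params")
}

#' Create a system-matrix configuration
#'
#' @param psf enable detector-space PSF convolution.
#' @param doi enable depth-of-interaction crystal subdivision.
#' @param attenuation `"off"`, `"simple"` (one factor per footprint) or
#'   `"full"` (one factor per detector bin).
#' @param psf_n_sigma Gaussian truncation (standard deviations kept).
#' @param psf_subsampling integer >= 1; PSF/footprint computed on a grid of
#'   `bin_size / psf_subsampling` before downsampling to the bin size.
#' @param sampling_interval spatial sampling interval (mm) for PSF and DOI
#'   distributions.
#' @param mask `"none"`, `"cylinder"`, `"attenuation_map"` or `"file"`.
#' @param object_radius cylinder mask radius (mm); required for
#'   `mask = "cylinder"` and checked against map/file masks when given.
#' @param mask_file path of an Interfile mask image (for `mask = "file"`).
#' @param keep_in_memory keep all per-view matrices cached, versus computing
#'   each view's matrix per projection angle and releasing it.
#' @param min_weight truncation threshold; weights `<= min_weight` are dropped.
#' @export
matrix_config <- function(psf = FALSE, doi = FALSE,
                          attenuation = c("off", "simple", "full"),
                          psf_n_sigma = 2, psf_subsampling = 1L,
                          sampling_interval = 0.1,
                          mask = c("cylinder", "none", "attenuation_map", "file"),
                          object_radius = NULL, mask_file = NULL,
                          keep_in_memory = TRUE, min_weight = 0) {
  attenuation <- match.arg(attenuation)
  mask <- match.arg(mask)
  stopifnot(psf_n_sigma > 0, psf_subsampling >= 1, sampling_interval > 0,
            min_weight >= 0)
  if (mask == "cylinder" && is.null(object_radius))
    stop("mask = 'cylinder' requires object_radius")
  if (!is.null(object_radius)) stopifnot(object_radius > 0)
  structure(list(psf = isTRUE(psf), doi = isTRUE(doi), attenuation = attenuation,
                 psf_n_sigma = psf_n_sigma,
                 psf_subsampling = as.integer(psf_subsampling),
                 sampling_interval = sampling_interval, mask = mask,
                 object_radius = object_radius, mask_file = mask_file,
                 keep_in_memory = isTRUE(keep_in_memory),
                 min_weight = min_weight),
            class = "matrix_config")
}

## short stable fingerprint of an R object (config staleness guard)
config_fingerprint <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  b <- utf8ToInt(s)
  h <- 5381
  for (v in b) h <- (h * 33 + v) %% 4294967296
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}
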
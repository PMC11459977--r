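## Coordinate frames and ray geometry.
##
## Fixed frame (x, y, z): x, y transaxial, z axial, origin on the axis of
## rotation. Rotating frame (x', y', z'): coincides with the fixed frame when
## the detector is at 0 deg; y' points from the collimator toward the detector,
## so at angle 0 the detector sits on the +y axis and angles increase
## counterclockwise viewed from +z.

#' Rotation matrix mapping fixed-frame to rotating-frame coordinates
#'
#' @param angle_deg view angle (deg).
#' @return 3x3 orthonormal matrix `R` with `p_rot = R %*% p_fixed`.
#' @export
view_rotation <- function(angle_deg) {
  th <- angle_deg * pi / 180
  matrix(c(cos(th), -sin(th), 0,
           sin(th),  cos(th), 0,
           0,        0,       1), 3, 3)
}

#' Generate the per-view geometry of a circular orbit
#'
#' Angles are `initial_angle + k * angular_increment` for
#' `k = 0, ..., n_angles - 1`; a positive increment rotates counterclockwise.
#'
#' @param orbit an [orbit_spec()].
#' @return list of `view_geometry` objects with fields `view_index`, `angle`,
#'   `rotation` (fixed -> rotating), `detector_direction` (unit vector toward
#'   the detector centre in the fixed frame).
#' @export
generate_orbit <- function(orbit) {
  stopifnot(inherits(orbit, "orbit_spec"))
  lapply(seq_len(orbit$n_angles), function(k) {
    a <- orbit$initial_angle + (k - 1) * orbit$angular_increment
    th <- a * pi / 180
    structure(list(view_index = k, angle = a,
                   rotation = view_rotation(a),
                   detector_direction = c(-sin(th), cos(th), 0)),
              class = "view_geometry")
  })
}

#' Trace a ray through a voxel grid (exact Siddon-style lengths)
#'
#' Returns every voxel the segment `p0 -> p1` crosses, ordered from `p0` to
#' `p1`, with the exact chord length inside each voxel. A ray missing the grid
#' gives a zero-row result.
#'
#' @param p0,p1 length-3 points (mm) in the fixed frame.
#' @param grid an [image_volume()] (its voxel values are ignored).
#' @return data.frame with columns `iz, iy, ix` (1-based) and `length` (mm).
#' @export
trace_ray <- function(p0, p1, grid) {
  stopifnot(length(p0) == 3, length(p1) == 3, inherits(grid, "image_volume"))
  if (all(p0 == p1)) stop("p0 and p1 must differ")
  g <- grid_geom(grid)
  m <- cpp_trace_ray(as.numeric(p0), as.numeric(p1),
                     g$nx, g$ny, g$nz, g$dx, g$dz, g$ox, g$oy, g$oz)
  as.data.frame(m)
}

#' Sample interaction depths through the scintillation crystal along a LOR
#'
#' Fixed-step subdivision of the crystal along an oblique line of response:
#' depth is measured normal to the crystal face, and the lateral position
#' drifts with obliquity (parallax). Samples are interval midpoints.
#'
#' @param entry length-3 point (mm) where the LOR meets the crystal face.
#' @param direction length-3 unit vector of the LOR; must have a positive
#'   component along `normal`.
#' @param crystal_thickness crystal thickness (mm).
#' @param step spatial sampling interval (mm) along the face normal.
#' @param normal inward unit normal of the crystal face (default +y).
#' @return data.frame with columns `depth` (mm, normal to the face),
#'   `path_length` (mm along the LOR to the sample) and `x, y, z` positions.
#' @export
crystal_depth_samples <- function(entry, direction, crystal_thickness, step,
                                  normal = c(0, 1, 0)) {
  stopifnot(length(entry) == 3, length(direction) == 3,
            crystal_thickness > 0, step > 0)
  direction <- direction / sqrt(sum(direction^2))
  cosi <- sum(direction * normal)
  if (cosi <= 1e-9) stop("grazing ray: no component into the crystal")
  if (step > crystal_thickness) {
    warning("sampling step exceeds crystal thickness; single mid-crystal sample")
    depths <- crystal_thickness / 2
  } else {
    ns <- ceiling(crystal_thickness / step)
    edges <- crystal_thickness * (0:ns) / ns
    depths <- (edges[-1] + edges[-(ns + 1)]) / 2
  }
  path <- depths / cosi
  pos <- t(vapply(path, function(s) entry + s * direction, numeric(3)))
  data.frame(depth = depths, path_length = path,
             x = pos[, 1], y = pos[, 2], z = pos[, 3])
}
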
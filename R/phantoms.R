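## Digital activity/attenuation phantoms and Poisson acquisition simulation.
##
## All phantoms are built from axial cylinders voxelized with partial-volume
## handling: interior/exterior voxels are classified analytically and boundary
## voxels get a 3x3 in-plane subvoxel fraction, with exact axial overlap.
## Generation is deterministic. Default attenuation coefficients are linear
## coefficients at 140 keV (99mTc): water 0.0153 mm^-1, acrylic (PMMA)
## 0.0173 mm^-1, air 0.

#' Default linear attenuation coefficients at 140 keV (mm^-1)
#' @export
mu_defaults <- function() c(water = 0.0153, acrylic = 0.0173, air = 0)

#' Build an empty phantom grid
#'
#' Convenience grid constructor centred on the axis of rotation.
#'
#' @param n `c(nz, ny, nx)` or a single integer for a cubic grid.
#' @param voxel_size in-plane voxel size (mm).
#' @param z_spacing axial spacing (mm).
#' @export
phantom_grid <- function(n, voxel_size, z_spacing = voxel_size) {
  empty_volume(n, voxel_size, z_spacing)
}

## in-plane inclusion fraction of a disc (centre cx,cy, radius r) per (y,x)
.disc_frac <- function(co, cx, cy, r, h) {
  dy <- co$y - cy
  dx <- co$x - cx
  d <- sqrt(outer(dy^2, dx^2, `+`))              # [ny, nx]
  marg <- h * sqrt(2) / 2
  f <- matrix(0, length(dy), length(dx))
  f[d <= r - marg] <- 1
  bidx <- which(d > r - marg & d < r + marg, arr.ind = TRUE)
  if (nrow(bidx)) {
    off <- (c(1, 2, 3) - 2) / 3 * h
    sub <- expand.grid(ox = off, oy = off)
    for (k in seq_len(nrow(bidx))) {
      yy <- dy[bidx[k, 1]] + sub$oy
      xx <- dx[bidx[k, 2]] + sub$ox
      f[bidx[k, 1], bidx[k, 2]] <- mean(outer(yy^2, xx^2, `+`) <= r^2)
    }
  }
  f
}

## cylinder inclusion fraction array [nz, ny, nx]
.cyl_frac <- function(grid, centre_xy, diameter, z0, z1) {
  co <- voxel_coords(grid)
  g <- grid_geom(grid)
  fxy <- .disc_frac(co, centre_xy[1], centre_xy[2], diameter / 2, g$dx)
  fz <- pmax(0, pmin(co$z + g$dz / 2, z1) - pmax(co$z - g$dz / 2, z0)) / g$dz
  arr <- outer(fz, fxy)                          # [nz, ny, nx]
  dim(arr) <- c(g$nz, g$ny, g$nx)
  arr
}

## paint values into `base` where frac > 0 (replacing, fraction-blended)
.paint <- function(base, frac, value) base * (1 - frac) + value * frac

#' NEMA-style micro image-quality phantom
#'
#' Acrylic body (outer diameter 33.5 mm, length 63.0 mm) with three sections:
#' five hot rods (diameters 1-5 mm, length 20.0 mm, centres on a 7 mm radius
#' at 72 degree spacing), a uniform active section (inner diameter 30.0 mm,
#' length 15.0 mm), and a spillover section with one water-filled and one
#' air-filled chamber (8 mm inner diameter, 15 mm long, centres at x = +/-7.5
#' mm, following the NEMA NU-4 convention since the chamber geometry is not
#' part of the stated phantom dimensions).
#'
#' Label volume: 0 background/cold body, 1 uniform section, 2 water chamber,
#' 3 air chamber, 4 central inter-rod reference region (diameter 5.4 mm,
#' length 15.0 mm), 10 + d for the rod of diameter d mm. Labels are assigned
#' by voxel-centre majority (fraction > 0.5).
#'
#' @param grid an [image_volume()] template; a voxel size <= 0.5 mm is
#'   recommended to resolve the 1 mm rod (a warning is raised otherwise).
#' @param activity activity concentration in active regions (arbitrary units).
#' @param mu named attenuation coefficients (mm^-1), see [mu_defaults()].
#' @return list with `activity`, `attenuation` and `labels` (all
#'   [image_volume()]; labels integer-valued).
#' @export
make_iq_phantom <- function(grid, activity = 1, mu = mu_defaults()) {
  g <- grid_geom(grid)
  if (g$dx > 0.5)
    warning("voxel size ", g$dx, " mm cannot resolve the 1 mm rod; <= 0.5 mm recommended")
  act <- array(0, dim = dim(grid$voxels))
  att <- array(0, dim = dim(grid$voxels))
  lab <- array(0, dim = dim(grid$voxels))

  body <- .cyl_frac(grid, c(0, 0), 33.5, -31.5, 31.5)
  att <- .paint(att, body, mu[["acrylic"]])

  ## uniform section
  uni <- .cyl_frac(grid, c(0, 0), 30.0, -7.5, 7.5)
  att <- .paint(att, uni, mu[["water"]])
  act <- act + activity * uni
  lab[uni > 0.5] <- 1

  ## hot rods, length 20 mm, centres on a 7 mm circle
  for (dmm in 1:5) {
    ang <- (dmm - 1) * 72 * pi / 180
    ctr <- 7 * c(cos(ang), sin(ang))
    rod <- .cyl_frac(grid, ctr, dmm, -29.5, -9.5)
    att <- .paint(att, rod, mu[["water"]])
    act <- act + activity * rod
    lab[rod > 0.5] <- 10 + dmm
  }

  ## reference region central to the rods (cold)
  ref <- .cyl_frac(grid, c(0, 0), 5.4, -27.0, -12.0)
  lab[ref > 0.5 & lab < 10] <- 4

  ## spillover chambers
  wat <- .cyl_frac(grid, c(7.5, 0), 8.0, 10.5, 25.5)
  air <- .cyl_frac(grid, c(-7.5, 0), 8.0, 10.5, 25.5)
  att <- .paint(att, wat, mu[["water"]])
  att <- .paint(att, air, mu[["air"]])
  lab[wat > 0.5] <- 2
  lab[air > 0.5] <- 3

  mk <- function(a) image_volume(a, grid$voxel_size, grid$z_spacing, grid$origin)
  list(activity = mk(act), attenuation = mk(att), labels = mk(lab))
}

#' Mouse-sized triple line source phantom
#'
#' Acrylic body (outer diameter 25.4 mm, length 60.0 mm) housing three
#' capillary line sources of 0.4 mm inner diameter: one on the axis and two at
#' a 10.0 mm radial offset separated by 90 degrees, i.e. centres at (0, 0),
#' (10, 0) and (0, 10) mm in the transaxial plane.
#'
#' @inheritParams make_iq_phantom
#' @param line_length active capillary length (mm).
#' @return list with `activity` and `attenuation` ([image_volume()]).
#' @export
make_triple_line_phantom <- function(grid, activity = 1, mu = mu_defaults(),
                                     line_length = 60) {
  act <- array(0, dim = dim(grid$voxels))
  att <- array(0, dim = dim(grid$voxels))
  body <- .cyl_frac(grid, c(0, 0), 25.4, -30, 30)
  att <- .paint(att, body, mu[["acrylic"]])
  hl <- line_length / 2
  for (ctr in list(c(0, 0), c(10, 0), c(0, 10))) {
    ln <- .cyl_frac(grid, ctr, 0.4, -hl, hl)
    att <- .paint(att, ln, mu[["water"]])
    act <- act + activity * ln
  }
  mk <- function(a) image_volume(a, grid$voxel_size, grid$z_spacing, grid$origin)
  list(activity = mk(act), attenuation = mk(att))
}

#' Uniform volumetric cylinder phantom
#'
#' Acrylic body (outer diameter 28.0 mm, length 55.0 mm) with a uniform active
#' section of 26.0 mm inner diameter and 21.0 mm length, centred.
#'
#' @inheritParams make_iq_phantom
#' @return list with `activity` and `attenuation` ([image_volume()]).
#' @export
make_uniform_cylinder <- function(grid, activity = 1, mu = mu_defaults()) {
  act <- array(0, dim = dim(grid$voxels))
  att <- array(0, dim = dim(grid$voxels))
  body <- .cyl_frac(grid, c(0, 0), 28.0, -27.5, 27.5)
  att <- .paint(att, body, mu[["acrylic"]])
  core <- .cyl_frac(grid, c(0, 0), 26.0, -10.5, 10.5)
  att <- .paint(att, core, mu[["water"]])
  act <- act + activity * core
  mk <- function(a) image_volume(a, grid$voxel_size, grid$z_spacing, grid$origin)
  list(activity = mk(act), attenuation = mk(att))
}

#' Simulate a Poisson-noisy acquisition
#'
#' Forward-projects the activity, scales the noiseless projections to the
#' requested total count, then draws independent Poisson counts per bin.
#' Deterministic for a fixed seed.
#'
#' @param activity an [image_volume()] on the projector's grid.
#' @param projector a [pinhole_projector()].
#' @param total_counts expected total number of detected counts (> 0).
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @param noiseless skip the Poisson draw (returns the scaled expectation).
#' @return a [projection_data()] of counts.
#' @export
simulate_acquisition <- function(activity, projector, total_counts,
                                 seed = NULL, noiseless = FALSE) {
  stopifnot(total_counts > 0)
  p <- forward_project(projector, activity)
  s <- sum(p$views)
  if (s <= 0) stop("activity projects to zero counts; check geometry/mask")
  p$views <- p$views * (total_counts / s)
  if (!noiseless) {
    if (!is.null(seed)) set.seed(seed)
    p$views <- array(rpois(length(p$views), p$views), dim = dim(p$views))
  }
  p
}
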
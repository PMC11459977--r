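## Shared fixture builders. Geometry mirrors a single-pinhole preclinical
## camera: aperture 1 mm at 30 mm radius of rotation, crystal face at 55 mm.

tiny_orbit <- function(n_angles = 4, initial = 0, increment = 90, ...) {
  orbit_spec(n_angles, initial, increment, ...)
}

tiny_detector <- function(orbit = tiny_orbit(), n_bins = 48, bin_size = 1,
                          fwhm = 1, thickness = 4, mu_c = 0.3, radius = 55) {
  detector_params(intrinsic_resolution = fwhm, crystal_thickness = thickness,
                  crystal_attenuation = mu_c, detector_radius = radius,
                  orbit = orbit, n_transaxial = n_bins, n_axial = n_bins,
                  bin_size = bin_size)
}

tiny_collimator <- function(diameter = 1, ror = 30, tilt = 0, acc = 45) {
  collimator_params(ror, holes = hole_spec(c(0, ror, 0), size = diameter,
                                           tilt = tilt,
                                           acceptance_angle = acc))
}

## footprint helpers: weighted centroid and Sheppard-ish moments in bin units
fp_centroid <- function(fp, det) {
  x <- (fp$it - 1 - (det$n_transaxial - 1) / 2) * det$bin_size
  z <- (fp$ia - 1 - (det$n_axial - 1) / 2) * det$bin_size +
    det$orbit$axial_position
  w <- fp$weight
  c(x = sum(x * w) / sum(w), z = sum(z * w) / sum(w))
}

fp_moment2 <- function(fp, det) {
  ctr <- fp_centroid(fp, det)
  x <- (fp$it - 1 - (det$n_transaxial - 1) / 2) * det$bin_size
  z <- (fp$ia - 1 - (det$n_axial - 1) / 2) * det$bin_size +
    det$orbit$axial_position
  w <- fp$weight
  c(x = sum(w * (x - ctr["x"])^2) / sum(w),
    z = sum(w * (z - ctr["z"])^2) / sum(w))
}

## uniform-disc footprint rasterized the brute-force way (pixel-overlap by
## n x n subsampling) on the detector bin grid; independent of the C++ path
oracle_disc_footprint <- function(centre, diameter, det, nsub = 32) {
  R <- diameter / 2
  cx <- centre[1]; cz <- centre[2]
  xs <- (seq_len(det$n_transaxial) - 1 - (det$n_transaxial - 1) / 2) *
    det$bin_size
  zs <- (seq_len(det$n_axial) - 1 - (det$n_axial - 1) / 2) * det$bin_size
  keepx <- which(abs(xs - cx) < R + det$bin_size)
  keepz <- which(abs(zs - cz) < R + det$bin_size)
  sub <- (seq_len(nsub) - 0.5) / nsub - 0.5
  out <- NULL
  for (it in keepx) for (ia in keepz) {
    cov <- mean(outer((xs[it] + sub * det$bin_size - cx)^2,
                      (zs[ia] + sub * det$bin_size - cz)^2, `+`) <= R^2)
    if (cov > 0)
      out <- rbind(out, data.frame(it = it, ia = ia, weight = cov))
  }
  out
}
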
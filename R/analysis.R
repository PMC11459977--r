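## NEMA-style figures of merit: contrast-to-noise ratio, coefficient of
## variation, uniformity, and FWHM in-plane resolution. All metrics are
## invariant under positive global intensity scaling.

#' Cylindrical ROI specification scaled by NEMA fractions
#'
#' The analysis cylinder covers a fraction of the active diameter and of the
#' active length (default 60% and 75%).
#'
#' @param active_diameter,active_length active-region dimensions (mm).
#' @param fractions `c(diameter_fraction, length_fraction)`.
#' @param centre length-3 cylinder centre (mm).
#' @return object of class `roi_spec` with fields `diameter`, `length`,
#'   `centre`.
#' @export
nema_roi <- function(active_diameter, active_length, fractions = c(0.6, 0.75),
                     centre = c(0, 0, 0)) {
  stopifnot(active_diameter > 0, active_length > 0, length(fractions) == 2)
  structure(list(diameter = fractions[1] * active_diameter,
                 length = fractions[2] * active_length,
                 centre = as.numeric(centre)),
            class = "roi_spec")
}

#' Voxel mask of a cylindrical ROI (voxel-centre inclusion)
#'
#' @param grid an [image_volume()] template.
#' @param roi an `roi_spec` from [nema_roi()], or a list with `centre`,
#'   `diameter`, `length`.
#' @return logical array on the grid.
#' @export
roi_mask <- function(grid, roi) {
  co <- voxel_coords(grid)
  d <- dim(grid$voxels)
  inxy <- outer((co$y - roi$centre[2])^2, (co$x - roi$centre[1])^2, `+`) <=
    (roi$diameter / 2)^2
  inz <- abs(co$z - roi$centre[3]) <= roi$length / 2
  arr <- outer(inz, inxy) > 0          # outer() promotes logicals to numeric
  dim(arr) <- d
  arr
}

.roi_values <- function(image, roi_or_mask) {
  m <- if (is.array(roi_or_mask) && is.logical(roi_or_mask)) roi_or_mask
       else roi_mask(image, roi_or_mask)
  v <- image$voxels[m]
  if (length(v) == 0) stop("empty ROI")
  v
}

#' Coefficient of variation in an ROI
#'
#' `CV = sigma / mu` with the population standard deviation over ROI voxels.
#' A zero mean returns `NA` (flagged missing).
#'
#' @param image an [image_volume()].
#' @param roi an `roi_spec` or logical mask array.
#' @export
cv <- function(image, roi) {
  v <- .roi_values(image, roi)
  mu <- mean(v)
  if (mu == 0) return(NA_real_)
  sqrt(mean((v - mu)^2)) / mu
}

#' Integral uniformity in an ROI
#'
#' `U = (I_max - I_min) / (I_max + I_min)`; `I_max + I_min = 0` returns `NA`.
#'
#' @inheritParams cv
#' @export
uniformity <- function(image, roi) {
  v <- .roi_values(image, roi)
  mx <- max(v); mn <- min(v)
  if (mx + mn == 0) return(NA_real_)
  (mx - mn) / (mx + mn)
}

#' Hot-rod contrast-to-noise ratio
#'
#' `CNR_i = (|I_i - I_r| / (I_i + I_r)) / (sigma / mu)` where `I_i` is the
#' mean intensity in rod i, `I_r` the mean in the reference ROI central to the
#' rods, and `sigma`, `mu` are taken in the uniform-region ROI. Undefined
#' ratios (`I_i + I_r = 0` or `mu = 0`) are returned as `NA`.
#'
#' @param image an [image_volume()].
#' @param rod_rois named list of rod ROIs (masks or `roi_spec`s).
#' @param reference_roi reference ROI (mask or `roi_spec`).
#' @param uniform_roi uniform-region ROI (mask or `roi_spec`).
#' @return named numeric vector of per-rod CNR.
#' @export
cnr <- function(image, rod_rois, reference_roi, uniform_roi) {
  Ir <- mean(.roi_values(image, reference_roi))
  noise <- cv(image, uniform_roi)
  vapply(rod_rois, function(roi) {
    Ii <- mean(.roi_values(image, roi))
    if (Ii + Ir == 0 || is.na(noise) || noise == 0) return(NA_real_)
    (abs(Ii - Ir) / (Ii + Ir)) / noise
  }, numeric(1))
}

## FWHM of a 1D profile: 3-point parabolic peak fit, then linear interpolation
## of the half-maximum crossings. NA when the peak touches the profile edge.
.profile_fwhm <- function(vals, coords) {
  n <- length(vals)
  pk <- which.max(vals)
  if (pk <= 1 || pk >= n) return(NA_real_)
  ## parabolic refinement of peak value
  y1 <- vals[pk - 1]; y2 <- vals[pk]; y3 <- vals[pk + 1]
  den <- y1 - 2 * y2 + y3
  peak <- if (den < 0) y2 - (y1 - y3)^2 / (8 * den) else y2
  half <- peak / 2
  ## left crossing
  li <- max(which(vals[1:pk] <= half), 0)
  if (li == 0) return(NA_real_)
  xl <- coords[li] + (half - vals[li]) / (vals[li + 1] - vals[li]) *
    (coords[li + 1] - coords[li])
  ## right crossing
  riRel <- which(vals[pk:n] <= half)
  if (length(riRel) == 0) return(NA_real_)
  ri <- pk + riRel[1] - 1
  xr <- coords[ri - 1] + (half - vals[ri - 1]) / (vals[ri] - vals[ri - 1]) *
    (coords[ri] - coords[ri - 1])
  xr - xl
}

#' In-plane FWHM resolution of axial line sources
#'
#' For each transverse slab the volume is integrated axially; for each
#' expected line position the peak is located within a search window and the
#' x and y profiles through the peak are measured by 3-point parabolic peak
#' refinement and linear interpolation of the half-maximum crossings. The
#' result averages all valid x and y FWHMs; profiles whose peak touches the
#' volume/window boundary are flagged missing.
#'
#' @param image an [image_volume()].
#' @param line_centres matrix (or list) of transaxial line positions
#'   `(x, y)` in mm.
#' @param slab_centres axial slab centres (mm).
#' @param slab_thickness slab thickness (mm).
#' @param search_radius half-width (mm) of the peak search window around each
#'   expected line position.
#' @return list with `average` (mm) and `table` (data.frame slab/line/axis/
#'   fwhm).
#' @export
fwhm_resolution <- function(image, line_centres,
                            slab_centres = c(-14.5, 0, 14.5),
                            slab_thickness = 3.5, search_radius = 3) {
  if (is.list(line_centres)) line_centres <- do.call(rbind, line_centres)
  co <- voxel_coords(image)
  rows <- list()
  for (zc in slab_centres) {
    inz <- abs(co$z - zc) <= slab_thickness / 2
    if (!any(inz)) next
    slab <- apply(image$voxels[inz, , , drop = FALSE], c(2, 3), sum)  # [ny, nx]
    for (li in seq_len(nrow(line_centres))) {
      cx <- line_centres[li, 1]; cy <- line_centres[li, 2]
      wx <- which(abs(co$x - cx) <= search_radius)
      wy <- which(abs(co$y - cy) <= search_radius)
      if (!length(wx) || !length(wy)) next
      win <- slab[wy, wx, drop = FALSE]
      pk <- which(win == max(win), arr.ind = TRUE)[1, ]
      iy <- wy[pk[1]]; ix <- wx[pk[2]]
      fx <- .profile_fwhm(slab[iy, ], co$x)
      fy <- .profile_fwhm(slab[, ix], co$y)
      rows[[length(rows) + 1]] <- data.frame(
        slab = zc, line = li,
        axis = c("x", "y"), fwhm = c(fx, fy))
    }
  }
  tab <- do.call(rbind, rows)
  list(average = mean(tab$fwhm, na.rm = TRUE), table = tab)
}

#' Figures of merit over a snapshot series
#'
#' Evaluates CV, uniformity and (optionally) per-rod CNR on every snapshot of
#' a [reconstruct()] result.
#'
#' @param result a `recon_result` with snapshots.
#' @param uniform_roi ROI for CV/uniformity.
#' @param rod_rois,reference_roi optional CNR inputs.
#' @return data.frame with one row per snapshot and metric.
#' @export
fom_series <- function(result, uniform_roi, rod_rois = NULL,
                       reference_roi = NULL) {
  stopifnot(inherits(result, "recon_result"), length(result$snapshots) > 0)
  rows <- lapply(names(result$snapshots), function(nm) {
    img <- result$snapshots[[nm]]
    si <- as.integer(sub("subiter_", "", nm))
    out <- data.frame(subiteration = si,
                      metric = c("cv", "uniformity"),
                      value = c(cv(img, uniform_roi),
                                uniformity(img, uniform_roi)))
    if (!is.null(rod_rois)) {
      cn <- cnr(img, rod_rois, reference_roi, uniform_roi)
      out <- rbind(out, data.frame(subiteration = si,
                                   metric = paste0("cnr_", names(cn)),
                                   value = unname(cn)))
    }
    out
  })
  do.call(rbind, rows)
}
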
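## System-matrix computation: per-view sparse voxel -> bin weight matrices for
## pinhole collimation with optional PSF, DOI and attenuation corrections and
## image masking, plus matched forward/back projection.

#' Build a voxel mask
#'
#' The default cylinder includes voxels whose transaxial centre satisfies
#' `x^2 + y^2 <= object_radius^2`. Map and file masks include strictly positive
#' voxels. When an `object_radius` is supplied alongside a map/file mask, the
#' masked object must fit inside the cylinder, otherwise an error is raised
#' (the matrix weights are computed according to the object radius).
#'
#' @param grid an [image_volume()] defining the voxel grid.
#' @param mode `"cylinder"`, `"attenuation_map"`, `"file"` or `"none"`.
#' @param object_radius cylinder radius (mm).
#' @param atten_map an [image_volume()] attenuation map (for
#'   `mode = "attenuation_map"`).
#' @param mask_file path of an Interfile mask image (for `mode = "file"`).
#' @return logical array with the grid's dimensions.
#' @export
build_mask <- function(grid,
                       mode = c("cylinder", "attenuation_map", "file", "none"),
                       object_radius = NULL, atten_map = NULL,
                       mask_file = NULL) {
  mode <- match.arg(mode)
  d <- dim(grid$voxels)
  co <- voxel_coords(grid)
  r2 <- outer(co$y^2, co$x^2, `+`)               # [ny, nx]
  if (mode == "none")
    return(array(TRUE, dim = d))
  if (mode == "cylinder") {
    if (is.null(object_radius)) stop("cylinder mask requires object_radius")
    incl <- r2 <= object_radius^2
    return(aperm(array(incl, dim = c(d[2], d[3], d[1])), c(3, 1, 2)))
  }
  src <- if (mode == "attenuation_map") {
    if (is.null(atten_map)) stop("mode 'attenuation_map' requires atten_map")
    atten_map
  } else {
    if (is.null(mask_file)) stop("mode 'file' requires mask_file")
    read_image_interfile(mask_file)
  }
  if (!identical(dim(src$voxels), d))
    stop("mask source grid does not match the image grid")
  m <- src$voxels > 0
  if (!is.null(object_radius)) {
    cyl <- build_mask(grid, "cylinder", object_radius = object_radius)
    if (any(m & !cyl))
      stop("masked object extends beyond object_radius = ", object_radius,
           " mm; increase the object radius")
  }
  m
}

#' Detector-space PSF kernel
#'
#' Isotropic Gaussian of the camera's intrinsic resolution,
#' `sigma = FWHM / (2 sqrt(2 log 2))`, built on the subsampled grid
#' (`bin_size / subsampling`), truncated at `n_sigma * sigma`, integrated down
#' to bin resolution and renormalized to sum 1.
#'
#' @param intrinsic_resolution FWHM (mm); 0 gives the discrete delta.
#' @param bin_size detector bin size (mm).
#' @param subsampling integer >= 1.
#' @param n_sigma truncation radius in standard deviations.
#' @return square matrix summing to 1.
#' @export
psf_kernel <- function(intrinsic_resolution, bin_size, subsampling = 1L,
                       n_sigma = 2) {
  stopifnot(intrinsic_resolution >= 0, bin_size > 0, subsampling >= 1,
            n_sigma > 0)
  if (intrinsic_resolution <= 0) return(matrix(1, 1, 1))
  fp <- bin_size / subsampling
  sigma <- intrinsic_resolution / (2 * sqrt(2 * log(2)))
  K <- ceiling(n_sigma * sigma / fp)
  j <- -K:K
  fine <- 0.5 * (erf_((j + 0.5) * fp / (sigma * sqrt(2))) -
                 erf_((j - 0.5) * fp / (sigma * sqrt(2))))
  ## aggregate fine pixels to bins centred on fine pixel 0
  half <- floor(subsampling / 2)
  bin_idx <- floor((j + half) / subsampling)
  k1 <- vapply(sort(unique(bin_idx)), function(b) sum(fine[bin_idx == b]),
               numeric(1))
  k2 <- outer(k1, k1)
  k2 / sum(k2)
}

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

## shared argument preparation for point footprints
.point_fp <- function(point, detector, collimator, view_angle, psf, doi,
                      psf_n_sigma, psf_subsampling, sampling_interval,
                      frame = c("fixed", "rotating")) {
  frame <- match.arg(frame)
  stopifnot(inherits(detector, "detector_params"),
            inherits(collimator, "collimator_params"))
  p <- as.numeric(point)
  if (frame == "fixed") p <- as.numeric(view_rotation(view_angle) %*% p)
  res <- cpp_point_footprint(p[1], p[2], p[3], holes_matrix(collimator),
                             detector$n_transaxial, detector$n_axial,
                             detector$bin_size,
                             detector$orbit$axial_position,
                             detector$detector_radius,
                             detector$crystal_thickness,
                             detector$crystal_attenuation,
                             detector$intrinsic_resolution,
                             psf, doi, psf_n_sigma,
                             as.integer(psf_subsampling), sampling_interval)
  data.frame(bin = res$bin, it = res$it, ia = res$ia, weight = res$weight)
}

#' Geometric footprint of a point through the pinhole(s)
#'
#' Projects the aperture(s) onto the detector by similar triangles through the
#' hole position and distributes the solid-angle weight
#' `A cos(theta) / (4 pi r^2)` over the bins by fractional overlap with the
#' projected aperture. Points outside a hole's acceptance cone contribute
#' nothing through that hole. Without DOI the detection plane sits at the face
#' radius plus half the crystal thickness.
#'
#' @param point length-3 position (mm).
#' @param detector a [detector_params()].
#' @param collimator a [collimator_params()].
#' @param view_angle view angle (deg) when `frame = "fixed"`.
#' @param frame `"fixed"` (rotate into the view) or `"rotating"`.
#' @return data.frame with columns `bin`, `it`, `ia` (1-based) and `weight`.
#' @export
geometric_footprint <- function(point, detector, collimator, view_angle = 0,
                                frame = c("fixed", "rotating")) {
  .point_fp(point, detector, collimator, view_angle, psf = FALSE, doi = FALSE,
            psf_n_sigma = 2, psf_subsampling = 1L, sampling_interval = 0.1,
            frame = frame)
}

#' Depth-of-interaction footprint of a point
#'
#' Subdivides the scintillation crystal into fixed-depth intervals along the
#' oblique LOR; each interval's footprint is the aperture re-projected to that
#' depth (parallax drift included) weighted by the interaction probability
#' `exp(-mu_c l_k) - exp(-mu_c l_{k+1})`. The total placed weight is the
#' absolute detection probability `1 - exp(-mu_c l_total)` times the geometric
#' weight. Degenerate cases: zero thickness falls back to the crystal face
#' and zero crystal attenuation to mid-depth, both with unit weight (the
#' latter with a warning).
#'
#' @inheritParams geometric_footprint
#' @param sampling_interval depth sampling interval (mm).
#' @param psf also convolve with the intrinsic PSF.
#' @param psf_n_sigma,psf_subsampling PSF parameters (see [matrix_config()]).
#' @return data.frame with columns `bin`, `it`, `ia`, `weight`.
#' @export
apply_doi <- function(point, detector, collimator, view_angle = 0,
                      sampling_interval = 0.1, psf = FALSE, psf_n_sigma = 2,
                      psf_subsampling = 1L, frame = c("fixed", "rotating")) {
  if (detector$crystal_attenuation <= 0 && detector$crystal_thickness > 0)
    warning("crystal attenuation is 0 with DOI enabled; falling back to mid-depth")
  .point_fp(point, detector, collimator, view_angle, psf = psf, doi = TRUE,
            psf_n_sigma = psf_n_sigma, psf_subsampling = psf_subsampling,
            sampling_interval = sampling_interval, frame = frame)
}

#' Attenuation factors for a point's footprint
#'
#' `mode = "simple"` returns one factor `exp(-integral of mu dl)` along the
#' point-to-hole ray applied to the whole footprint; `mode = "full"` returns a
#' per-bin factor along each point-to-bin LOR.
#'
#' @param point length-3 position (mm) in the fixed frame.
#' @param atten_map [image_volume()] of linear attenuation (mm^-1), registered
#'   to the image grid.
#' @param mode `"simple"` or `"full"`.
#' @param detector,collimator system description.
#' @param view_angle view angle (deg).
#' @param footprint for `mode = "full"`, a footprint data.frame (from
#'   [geometric_footprint()]) whose bins get individual factors.
#' @param hole which hole the simple ray targets (index).
#' @return a scalar (`simple`) or a numeric vector matching the footprint rows
#'   (`full`), all in (0, 1].
#' @export
attenuation_factors <- function(point, atten_map, mode = c("simple", "full"),
                                detector, collimator, view_angle = 0,
                                footprint = NULL, hole = 1L) {
  mode <- match.arg(mode)
  if (any(atten_map$voxels < 0)) stop("negative attenuation values in map")
  g <- grid_geom(atten_map)
  mu <- as.numeric(atten_map$voxels)
  Rinv <- t(view_rotation(view_angle))           # rotating -> fixed
  p <- as.numeric(point)
  if (mode == "simple") {
    h <- as.numeric(Rinv %*% collimator$holes[[hole]]$position)
    li <- cpp_line_integral(mu, p, h, g$nx, g$ny, g$nz, g$dx, g$dz,
                            g$ox, g$oy, g$oz)
    return(exp(-li))
  }
  if (is.null(footprint)) stop("mode 'full' requires a footprint")
  P <- detector$detector_radius + detector$crystal_thickness / 2
  vapply(seq_len(nrow(footprint)), function(i) {
    bx <- (footprint$it[i] - 1 - (detector$n_transaxial - 1) / 2) * detector$bin_size
    bz <- (footprint$ia[i] - 1 - (detector$n_axial - 1) / 2) * detector$bin_size +
      detector$orbit$axial_position
    b <- as.numeric(Rinv %*% c(bx, P, bz))
    exp(-cpp_line_integral(mu, p, b, g$nx, g$ny, g$nz, g$dx, g$dz,
                           g$ox, g$oy, g$oz))
  }, numeric(1))
}

#' Create a pinhole projector
#'
#' Bundles the voxel grid, detector, collimator, matrix configuration and
#' optional attenuation map into a projector with matched forward/back
#' projection. With `keep_in_memory = TRUE` per-view sparse matrices are
#' cached after first use; otherwise each view's matrix is computed per
#' projection angle and released (identical results, lower memory).
#'
#' @param grid an [image_volume()] template (values ignored).
#' @param detector a [detector_params()].
#' @param collimator a [collimator_params()].
#' @param config a [matrix_config()].
#' @param atten_map [image_volume()], required iff `config$attenuation != "off"`.
#' @return object of class `pinhole_projector`.
#' @export
pinhole_projector <- function(grid, detector, collimator, config,
                              atten_map = NULL) {
  stopifnot(inherits(grid, "image_volume"), inherits(detector, "detector_params"),
            inherits(collimator, "collimator_params"),
            inherits(config, "matrix_config"))
  if (config$attenuation != "off" && is.null(atten_map))
    stop("attenuation = '", config$attenuation, "' requires an attenuation map")
  if (config$attenuation == "off" && !is.null(atten_map))
    stop("attenuation map supplied but attenuation = 'off'")
  if (!is.null(atten_map)) {
    if (!identical(dim(atten_map$voxels), dim(grid$voxels)))
      stop("attenuation map must be registered to the image grid")
    if (any(atten_map$voxels < 0)) stop("negative attenuation values in map")
  }
  if (config$doi && detector$crystal_attenuation <= 0)
    warning("DOI enabled with zero crystal attenuation; using mid-depth fallback")
  mask <- build_mask(grid, mode = config$mask,
                     object_radius = config$object_radius,
                     atten_map = atten_map, mask_file = config$mask_file)
  angles <- vapply(generate_orbit(detector$orbit), `[[`, numeric(1), "angle")
  prj <- new.env(parent = emptyenv())
  prj$grid <- grid
  prj$detector <- detector
  prj$collimator <- collimator
  prj$config <- config
  prj$atten_map <- atten_map
  prj$mask <- mask
  prj$angles <- angles
  prj$n_bins <- detector$n_axial * detector$n_transaxial
  prj$n_vox <- length(grid$voxels)
  prj$cache <- vector("list", length(angles))
  prj$fingerprint <- config_fingerprint(list(config, detector, collimator,
                                             grid_geom(grid)))
  class(prj) <- "pinhole_projector"
  prj
}

#' @export
print.pinhole_projector <- function(x, ...) {
  cat(sprintf(paste0("<pinhole_projector> %d views, %d bins, %d voxels ",
                     "(psf=%s doi=%s att=%s mask=%s, %s)\n"),
              length(x$angles), x$n_bins, x$n_vox,
              x$config$psf, x$config$doi, x$config$attenuation, x$config$mask,
              if (x$config$keep_in_memory) "in-memory" else "per-angle"))
  invisible(x)
}

#' Compute the sparse system matrix of one view
#'
#' For each unmasked voxel and each hole: geometric footprint, optional PSF
#' convolution, optional DOI accumulation, optional attenuation scaling, then
#' truncation of weights below `min_weight`. Deterministic for fixed inputs.
#'
#' @param projector a [pinhole_projector()].
#' @param view view index (1-based).
#' @return object of class `system_matrix_view`: list with `view_index`,
#'   `angle`, `matrix` (a `dgCMatrix`, bins x voxels) and `fingerprint`.
#' @export
compute_view_matrix <- function(projector, view) {
  stopifnot(inherits(projector, "pinhole_projector"),
            view >= 1, view <= length(projector$angles))
  A <- .view_mat(projector, view, cache = FALSE)
  structure(list(view_index = view, angle = projector$angles[view],
                 matrix = A, fingerprint = projector$fingerprint),
            class = "system_matrix_view")
}

## dgCMatrix (n_bins x n_vox) of one view, honouring the cache mode
.view_mat <- function(prj, v, cache = prj$config$keep_in_memory) {
  if (!is.null(prj$cache[[v]])) return(prj$cache[[v]])
  g <- grid_geom(prj$grid)
  d <- prj$detector
  cfg <- prj$config
  att_mode <- match(cfg$attenuation, c("off", "simple", "full")) - 1L
  tr <- cpp_view_matrix(prj$angles[v],
                        g$nx, g$ny, g$nz, g$dx, g$dz, g$ox, g$oy, g$oz,
                        d$n_transaxial, d$n_axial, d$bin_size,
                        d$orbit$axial_position, d$detector_radius,
                        d$crystal_thickness, d$crystal_attenuation,
                        d$intrinsic_resolution,
                        holes_matrix(prj$collimator),
                        cfg$psf, cfg$doi, att_mode, cfg$psf_n_sigma,
                        cfg$psf_subsampling, cfg$sampling_interval,
                        cfg$min_weight,
                        as.logical(prj$mask),
                        if (att_mode > 0) as.numeric(prj$atten_map$voxels)
                        else numeric(0))
  ## triplets arrive in CSC order (voxel-major, bins sorted within voxel):
  ## build the dgCMatrix directly instead of via sparseMatrix()'s sort
  A <- methods::new(methods::getClassDef("dgCMatrix", package = "Matrix"),
                    i = tr$i - 1L,
                    p = c(0L, as.integer(cumsum(tabulate(tr$j, prj$n_vox)))),
                    x = tr$x, Dim = c(prj$n_bins, prj$n_vox))
  if (cache) prj$cache[[v]] <- A
  A
}

#' Forward projection
#'
#' Linear map `p = A x` per view; repeated orbits (`n_orbits > 1`) are summed.
#'
#' @param projector a [pinhole_projector()].
#' @param image an [image_volume()] on the projector's grid.
#' @param views optional subset of view indices (default all).
#' @return a [projection_data()] (zero-filled outside `views`).
#' @export
forward_project <- function(projector, image, views = NULL) {
  stopifnot(inherits(image, "image_volume"))
  if (!identical(dim(image$voxels), dim(projector$grid$voxels)))
    stop("image grid does not match the projector grid")
  if (is.null(views)) views <- seq_along(projector$angles)
  d <- projector$detector
  x <- as.numeric(image$voxels)
  out <- array(0, dim = c(length(projector$angles), d$n_axial, d$n_transaxial))
  sc <- d$orbit$n_orbits
  for (v in views) {
    p <- as.numeric(.view_mat(projector, v) %*% x) * sc
    out[v, , ] <- p
  }
  projection_data(out, bin_size = d$bin_size,
                  detector_radius = d$detector_radius, orbit = d$orbit)
}

#' Back projection (exact adjoint of [forward_project()])
#'
#' @param projector a [pinhole_projector()].
#' @param projections a [projection_data()] or an array of matching dim.
#' @param views optional subset of view indices (default all).
#' @return an [image_volume()].
#' @export
back_project <- function(projector, projections, views = NULL) {
  y <- if (inherits(projections, "projection_data")) projections$views
       else projections
  d <- projector$detector
  if (!all(dim(y) == c(length(projector$angles), d$n_axial, d$n_transaxial)))
    stop("projection dimensions do not match the projector")
  if (is.null(views)) views <- seq_along(projector$angles)
  x <- numeric(projector$n_vox)
  sc <- d$orbit$n_orbits
  for (v in views) {
    x <- x + as.numeric(Matrix::crossprod(.view_mat(projector, v),
                                          as.numeric(y[v, , ]))) * sc
  }
  out <- projector$grid
  out$voxels <- array(x, dim = dim(projector$grid$voxels))
  out
}

## back-project ones over given views: subset sensitivity image (vector)
.sensitivity <- function(prj, views) {
  ones <- array(1, dim = c(length(prj$angles), prj$detector$n_axial,
                           prj$detector$n_transaxial))
  as.numeric(back_project(prj, ones, views = views)$voxels)
}
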
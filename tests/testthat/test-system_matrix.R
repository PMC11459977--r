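make_tiny_projector <- function(n = 12, vox = 1.5, n_views = 4, n_bins = 32,
                                cfg = matrix_config(mask = "none"),
                                atten = NULL, ...) {
  det <- tiny_detector(orbit = tiny_orbit(n_views, 0, 360 / n_views),
                       n_bins = n_bins, ...)
  pinhole_projector(empty_volume(n, vox), det, tiny_collimator(),
                    cfg, atten_map = atten)
}

test_that("single on-axis voxel reproduces its geometric footprint", {
  ## one-voxel grid: the view matrix IS the footprint (composition identity)
  det <- tiny_detector(orbit = tiny_orbit(1, 0, 1), n_bins = 63)
  col <- tiny_collimator()
  prj <- pinhole_projector(empty_volume(1, 1), det, col,
                           matrix_config(mask = "none"))
  A <- compute_view_matrix(prj, 1)$matrix
  fp <- geometric_footprint(c(0, 0, 0), det, col, frame = "rotating")
  expect_equal(A@x, fp$weight)
  expect_equal(A@i + 1L, fp$bin)
  expect_s3_class(compute_view_matrix(prj, 1), "system_matrix_view")
})

test_that("PSF convolution conserves per-voxel weight (unit-sum kernel)", {
  ## detector wide enough that no footprint clips its edge
  prj0 <- make_tiny_projector(n_bins = 64)
  prjP <- make_tiny_projector(n_bins = 64,
                              cfg = matrix_config(psf = TRUE, mask = "none"))
  A0 <- compute_view_matrix(prj0, 2)$matrix
  AP <- compute_view_matrix(prjP, 2)$matrix
  w0 <- Matrix::colSums(A0)
  wP <- Matrix::colSums(AP)
  ## compare voxels whose footprints stay fully on the detector
  core <- which(w0 > 0 & wP > 0)
  ## PSF broadens support
  expect_gt(sum(AP != 0), sum(A0 != 0))
  expect_equal(wP[core], w0[core], tolerance = 1e-6)
})

test_that("every correction combination yields finite non-negative weights", {
  amap <- empty_volume(12, 1.5)
  amap$voxels <- 0.015 * build_mask(amap, "cylinder", object_radius = 7)
  for (psf in c(FALSE, TRUE)) for (doi in c(FALSE, TRUE))
    for (att in c("off", "simple", "full")) {
      cfg <- matrix_config(psf = psf, doi = doi, attenuation = att,
                           sampling_interval = 0.5, mask = "cylinder",
                           object_radius = 7)
      prj <- make_tiny_projector(cfg = cfg,
                                 atten = if (att != "off") amap)
      A <- compute_view_matrix(prj, 1)$matrix
      expect_true(all(is.finite(A@x)) && all(A@x > 0))
      ## masked voxels have empty columns
      expect_equal(sum(Matrix::colSums(A != 0)[!as.logical(prj$mask)]), 0)
    }
})

test_that("forward projection is linear and back projection is its adjoint", {
  prj <- make_tiny_projector()
  d <- dim(prj$grid$voxels)
  mk <- function(a) image_volume(array(a, d), 1.5)
  set.seed(1)
  x1 <- mk(runif(prod(d))); x2 <- mk(runif(prod(d)))
  z <- forward_project(prj, mk(0))
  expect_equal(sum(z$views), 0)                 # zero image -> zero projections
  p1 <- forward_project(prj, x1)$views
  p2 <- forward_project(prj, x2)$views
  p12 <- forward_project(prj, mk(x1$voxels + x2$voxels))$views
  expect_equal(p12, p1 + p2, tolerance = 1e-12)

  y <- array(runif(length(p1)), dim = dim(p1))
  bp <- back_project(prj, y)$voxels
  expect_equal(sum(p1 * y), sum(x1$voxels * bp), tolerance = 1e-12)

  ## one-hot bin reproduces that bin's matrix column (adjoint definition)
  A1 <- compute_view_matrix(prj, 1)$matrix
  onehot <- array(0, dim = dim(p1)); onehot[1, 5, 7] <- 1
  bin <- (7 - 1) * prj$detector$n_axial + 5
  expect_equal(as.numeric(back_project(prj, onehot)$voxels),
               as.numeric(A1[bin, ]))
  expect_equal(sum(back_project(prj, array(0, dim(p1)))$voxels), 0)
})

test_that("in-memory and per-angle modes produce bit-identical results", {
  cfg_mem <- matrix_config(mask = "cylinder", object_radius = 7,
                           keep_in_memory = TRUE)
  cfg_ang <- matrix_config(mask = "cylinder", object_radius = 7,
                           keep_in_memory = FALSE)
  pm <- make_tiny_projector(cfg = cfg_mem)
  pa <- make_tiny_projector(cfg = cfg_ang)
  img <- pm$grid
  img$voxels <- array(seq_len(prod(dim(img$voxels))), dim = dim(img$voxels))
  fm <- forward_project(pm, img)
  fa <- forward_project(pa, img)
  expect_identical(fm$views, fa$views)
  ## per-angle mode releases matrices, in-memory caches them
  expect_true(all(vapply(pm$cache, Negate(is.null), TRUE)))
  expect_true(all(vapply(pa$cache, is.null, TRUE)))
  bm <- back_project(pm, fm)$voxels
  ba <- back_project(pa, fa)$voxels
  expect_identical(bm, ba)
})

test_that("repeated orbits are summed", {
  p1 <- make_tiny_projector()
  p2 <- make_tiny_projector()
  p2$detector$orbit$n_orbits <- 2L
  img <- p1$grid
  img$voxels <- array(1, dim = dim(img$voxels))
  expect_equal(forward_project(p2, img)$views,
               2 * forward_project(p1, img)$views)
})
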
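test_that("on-axis footprint obeys pinhole magnification and inverse square", {
  det <- tiny_detector(n_bins = 63)            # odd: axis hits a bin centre
  col <- tiny_collimator(diameter = 1)
  ## point on the hole axis at d = 20 below the hole; detection plane at
  ## face + T/2 = 57, so f = 27 and the disc diameter is a (d+f)/d = 2.35
  fp <- geometric_footprint(c(0, 10, 0), det, col, frame = "rotating")
  expect_equal(sum(fp$weight), (pi / 4) * cos(0) / (4 * pi * 20^2),
               tolerance = 1e-12)
  ctr <- fp_centroid(fp, det)
  expect_equal(unname(ctr), c(0, 0), tolerance = 1e-9)
  ## support: 3 bins across (disc of 2.35 mm on 1 mm bins, centred)
  expect_equal(sort(unique(fp$it)), 31:33)

  ## doubling the distance quarters the total weight
  fp2 <- geometric_footprint(c(0, -10, 0), det, col, frame = "rotating")
  expect_equal(sum(fp2$weight) / sum(fp$weight), 1 / 4, tolerance = 1e-9)

  ## outside the acceptance cone: empty footprint
  coln <- tiny_collimator(diameter = 1, acc = 10)
  out <- geometric_footprint(c(15, 10, 0), det, coln, frame = "rotating")
  expect_equal(nrow(out), 0)

  ## voxel coincident with the hole centre is an undefined ray
  expect_error(geometric_footprint(c(0, 30, 0), det, col, frame = "rotating"),
               "coincides")
})

test_that("footprint matches the brute-force pixel-overlap oracle off axis", {
  det <- tiny_detector(n_bins = 63)
  col <- tiny_collimator(diameter = 1)
  h <- c(0, 30, 0)
  for (v in list(c(0, 10, 0), c(4, 10, -2), c(-3, 6, 5), c(2, 14, 3))) {
    fp <- geometric_footprint(v, det, col, frame = "rotating")
    d <- h[2] - v[2]; f <- 57 - h[2]
    ctr_exp <- (h + (h - v) * f / d)[c(1, 3)]   # similar triangles
    dia_exp <- 1 * (d + f) / d
    orc <- oracle_disc_footprint(ctr_exp, dia_exp, det)
    ## same grid, same estimator: centroids and second moments agree
    names(orc)[3] <- "weight"
    orc$bin <- orc$it                           # fp_* only use it/ia/weight
    expect_equal(unname(fp_centroid(fp, det)), unname(fp_centroid(orc, det)),
                 tolerance = 0.05)
    m_fp <- fp_moment2(fp, det); m_or <- fp_moment2(orc, det)
    expect_equal(4 * sqrt(unname(m_fp)), 4 * sqrt(unname(m_or)),
                 tolerance = 0.1)
  }
})

test_that("psf_kernel is a unit-sum integrated Gaussian with a delta limit", {
  expect_identical(psf_kernel(0, 0.5), matrix(1, 1, 1))
  for (par in list(c(1, 0.5, 1, 2), c(2.3, 1, 4, 3), c(0.8, 0.25, 2, 2))) {
    k <- psf_kernel(par[1], par[2], par[3], par[4])
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_equal(k, t(k), tolerance = 1e-12)   # isotropic
  }
  ## centre-bin value against numerical integration of the Gaussian over the
  ## bin (quadrature oracle), with a large truncation radius
  bin <- 1; fwhm <- 2.354820045 * bin           # sigma = 1 bin
  k <- psf_kernel(fwhm, bin, subsampling = 1, n_sigma = 8)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  g1 <- integrate(function(x) dnorm(x, sd = sigma), -bin / 2, bin / 2)$value
  mid <- (nrow(k) + 1) / 2
  expect_equal(k[mid, mid], g1^2, tolerance = 1e-6)
})

test_that("DOI accumulation has the analytic total and exact limit behaviour", {
  det <- tiny_detector(n_bins = 63, thickness = 4, mu_c = 0.3)
  col <- tiny_collimator(diameter = 1)
  v <- c(0, 10, 0)
  geo <- geometric_footprint(v, det, col, frame = "rotating")
  doi <- apply_doi(v, det, col, frame = "rotating", sampling_interval = 0.05)
  ## normal incidence: no lateral shift, total = (1 - exp(-mu T)) x geometric
  expect_equal(sum(doi$weight) / sum(geo$weight), 1 - exp(-0.3 * 4),
               tolerance = 1e-9)
  expect_equal(unname(fp_centroid(doi, det)), c(0, 0), tolerance = 1e-9)

  ## oblique: the attenuation-weighted mean interaction depth is shallower
  ## than mid-crystal, so the DOI centroid sits closer to the axis than the
  ## mid-plane geometric one (parallax handled per depth)
  vo <- c(8, 10, 0)
  doi_o <- apply_doi(vo, det, col, frame = "rotating", sampling_interval = 0.05)
  geo_o <- geometric_footprint(vo, det, col, frame = "rotating")
  expect_lt(abs(fp_centroid(doi_o, det)["x"]), abs(fp_centroid(geo_o, det)["x"]))

  ## crystal thickness -> 0: identical to DOI-disabled at the crystal face
  det0 <- det; det0$crystal_thickness <- 0
  detF <- det; detF$crystal_thickness <- 1e-300  # face plane, T/2 negligible
  expect_equal(apply_doi(v, det0, col, frame = "rotating"),
               geometric_footprint(v, detF, col, frame = "rotating"))

  ## zero crystal attenuation: warning + mid-depth fallback (= DOI off)
  detz <- det; detz$crystal_attenuation <- 0
  expect_warning(dz <- apply_doi(v, detz, col, frame = "rotating"),
                 "mid-depth")
  expect_equal(dz, geometric_footprint(v, detz, col, frame = "rotating"))
})

test_that("attenuation factors follow exp(-mu L) and modes coincide for points", {
  det <- tiny_detector()
  col <- tiny_collimator()
  grid <- empty_volume(c(8, 8, 8), 2)
  mu0 <- grid; mu0$voxels <- array(0, dim = dim(grid$voxels))
  ## zero map: factors exactly 1
  expect_equal(attenuation_factors(c(0, -6, 0), mu0, "simple", det, col), 1)

  ## uniform slab: exp(-mu L) with L the in-grid chord of the voxel->hole ray
  mus <- grid; mus$voxels <- array(0.012, dim = dim(grid$voxels))
  f <- attenuation_factors(c(0, -6, 0), mus, "simple", det, col)
  expect_equal(f, exp(-0.012 * 14), tolerance = 1e-9)   # y: -6 .. 8

  ## negative attenuation is rejected
  mub <- grid; mub$voxels[1] <- -1
  expect_error(attenuation_factors(c(0, -6, 0), mub, "simple", det, col),
               "negative")

  ## full mode equals simple mode for a point-like footprint
  deto <- tiny_detector(n_bins = 63)
  colp <- tiny_collimator(diameter = 0.05)     # projects well inside one bin
  fp <- geometric_footprint(c(0, 0, 0), deto, colp, frame = "rotating")
  expect_equal(nrow(fp), 1)
  fs <- attenuation_factors(c(0, 0, 0), mus, "simple", deto, colp)
  ff <- attenuation_factors(c(0, 0, 0), mus, "full", deto, colp,
                            footprint = fp)
  expect_equal(ff, fs, tolerance = 1e-3)
})

test_that("voxel masks: cylinder default, map/file equivalence, bounds error", {
  grid <- empty_volume(c(8, 16, 16), 1)
  m <- build_mask(grid, "cylinder", object_radius = 5)
  expect_identical(as.logical(m), as.logical(aperm(array(
    outer(((1:16) - 8.5)^2, ((1:16) - 8.5)^2, `+`) <= 25,
    dim = c(16, 16, 8)), c(3, 1, 2))))

  ## radius beyond the grid: all-true mask
  expect_true(all(build_mask(grid, "cylinder", object_radius = 50)))

  ## attenuation-map mask with a centred cylinder == cylinder mask (strict
  ## voxel-centre map so the two constructions coincide)
  cyl <- build_mask(grid, "cylinder", object_radius = 6)
  amap <- grid
  amap$voxels <- array(0.015 * cyl, dim = dim(grid$voxels))
  expect_identical(build_mask(grid, "attenuation_map", atten_map = amap), cyl)

  ## object bigger than the declared radius is an error
  expect_error(build_mask(grid, "attenuation_map", atten_map = amap,
                          object_radius = 4), "object_radius")
  ## and fits within a generous radius
  expect_identical(build_mask(grid, "attenuation_map", atten_map = amap,
                              object_radius = 7), cyl)

  ## file-based mask round-trips through Interfile
  dir <- withr::local_tempdir()
  write_image_interfile(amap, file.path(dir, "mask.hv"))
  expect_identical(build_mask(grid, "file",
                              mask_file = file.path(dir, "mask.hv")), cyl)
})
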
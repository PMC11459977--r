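## small fixture shared across reconstruction tests
recon_fixture <- function(counts = 2e5, seed = 9, noiseless = FALSE,
                          n_views = 8) {
  det <- tiny_detector(orbit = tiny_orbit(n_views, 180, 270 / n_views),
                       n_bins = 40)
  grid <- empty_volume(c(16, 20, 20), 1.4)
  ph <- make_uniform_cylinder(grid)
  prj <- pinhole_projector(grid, det, tiny_collimator(),
                           matrix_config(mask = "cylinder", object_radius = 14.5))
  proj <- simulate_acquisition(ph$activity, prj, counts, seed = seed,
                               noiseless = noiseless)
  list(prj = prj, proj = proj, ph = ph, grid = grid)
}

test_that("make_subsets interleaves and balances view indices", {
  s <- make_subsets(91, 7)
  expect_length(s, 7)
  expect_true(all(lengths(s) == 13))
  expect_equal(sort(unlist(s)), 1:91)
  expect_equal(s[[1]][1:3], c(1, 8, 15))        # angularly interleaved

  expect_equal(make_subsets(10, 1), list(1:10))
  s2 <- make_subsets(120, 8)
  expect_true(all(lengths(s2) == 15))
  s3 <- make_subsets(10, 4)                     # non-divisible: sizes differ <= 1
  expect_true(max(lengths(s3)) - min(lengths(s3)) <= 1)
  expect_error(make_subsets(5, 6))
})

test_that("EM updates: fixed point, non-negativity, MLEM == OSEM(1 subset)", {
  fx <- recon_fixture(noiseless = TRUE)
  mask <- as.logical(fx$prj$mask)
  xt <- ifelse(mask, 2.5, 0)                    # uniform truth inside mask
  img <- fx$grid; img$voxels <- array(xt, dim = dim(fx$grid$voxels))
  m <- forward_project(fx$prj, img)$views
  sens <- pinholetomo:::.sensitivity(fx$prj, 1:8)
  xn <- osem_update(xt, fx$prj, m, 1:8, sens)
  expect_equal(xn, xt, tolerance = 1e-9)        # EM fixed point
  expect_true(all(xn >= 0))

  rcM <- recon_config("MLEM", n_subiterations = 4)
  rcO <- recon_config("OSEM", n_subsets = 1, n_subiterations = 4)
  resM <- reconstruct(fx$proj, fx$prj, rcM)
  resO <- reconstruct(fx$proj, fx$prj, rcO)
  expect_identical(resM$image$voxels, resO$image$voxels)
})

test_that("MLEM log-likelihood is non-decreasing and conserves counts", {
  fx <- recon_fixture(counts = 1e5)
  res <- reconstruct(fx$proj, fx$prj,
                     recon_config("MLEM", n_subiterations = 8,
                                  track_objective = TRUE))
  ll <- res$trace$objective
  expect_true(all(diff(ll) >= -1e-7 * abs(ll[-1])))

  fxn <- recon_fixture(counts = 1e5, noiseless = TRUE)
  resn <- reconstruct(fxn$proj, fxn$prj,
                      recon_config("MLEM", n_subiterations = 10))
  yh <- forward_project(fxn$prj, resn$image)
  expect_equal(sum(yh$views), sum(fxn$proj$views), tolerance = 0.01)
})

test_that("OSL-MRP reduces to OSEM at PF = 0 and is penalty-free on flats", {
  fx <- recon_fixture()
  m <- fx$proj$views
  sens <- pinholetomo:::.sensitivity(fx$prj, c(1, 3, 5, 7))
  x <- ifelse(as.logical(fx$prj$mask), 1.7, 0)
  x_osem <- osem_update(x, fx$prj, m, c(1, 3, 5, 7), sens)
  x_mrp0 <- os_osl_mrp_update(x, fx$prj, m, c(1, 3, 5, 7), sens, pf = 0)
  attr(x_mrp0, "n_clamped") <- NULL
  expect_equal(x_mrp0, x_osem, tolerance = 1e-12)

  ## flat image: neighbourhood median == value, so PF changes nothing in the
  ## volume interior (the mask boundary median differs by construction)
  x_mrp1 <- os_osl_mrp_update(x, fx$prj, m, c(1, 3, 5, 7), sens, pf = 1)
  core <- as.logical(fx$prj$mask) &
    pinholetomo:::cpp_median3(x, 16, 20, 20) == x
  expect_equal(x_mrp1[core], x_osem[core], tolerance = 1e-10)
})

test_that("OSL-MRP stabilises noise: lower CV than OSEM at matched subiteration", {
  fx <- recon_fixture(counts = 5e4, seed = 21)
  rc0 <- recon_config("OSEM", n_subsets = 4, n_subiterations = 16)
  rc1 <- recon_config("OS_OSL_MRP", n_subsets = 4, n_subiterations = 16,
                      penalisation_factor = 1)
  res0 <- reconstruct(fx$proj, fx$prj, rc0)
  res1 <- reconstruct(fx$proj, fx$prj, rc1)
  roi <- nema_roi(26, 21)
  expect_lt(cv(res1$image, roi), cv(res0$image, roi))
})

test_that("OS-SPS-QP: relaxation schedule, prior identities, monotone objective", {
  ## lambda_n = alpha / (1 + gamma n): lambda_0 = 1, lambda_10 = 0.5
  expect_equal(1 / (1 + 0.1 * 0), 1)
  expect_equal(1 / (1 + 0.1 * 10), 0.5)

  ## quadratic prior gradient vanishes on any uniform image
  qp <- pinholetomo:::cpp_quad_prior(rep(3.2, 4 * 5 * 6), 4L, 5L, 6L)
  expect_equal(qp$grad, rep(0, 120))
  expect_true(all(qp$curv > 0))

  ## PF = 0, small relaxation, noiseless data: objective non-decreasing
  fx <- recon_fixture(counts = 1e5, noiseless = TRUE)
  init <- reconstruct(fx$proj, fx$prj,
                      recon_config("OSEM", n_subsets = 4, n_subiterations = 4))
  rc <- recon_config("OS_SPS_QP", n_subsets = 1, n_subiterations = 6,
                     penalisation_factor = 0, alpha = 0.3, gamma = 0.1,
                     initial_image = init$image, track_objective = TRUE)
  res <- reconstruct(fx$proj, fx$prj, rc)
  obj <- res$trace$objective
  expect_true(all(diff(obj) >= -1e-7 * abs(obj[-1])))
  expect_true(all(res$image$voxels >= 0))
})

test_that("reconstruct bookkeeping: passes, snapshots, determinism", {
  fx <- recon_fixture(counts = 3e4)
  res <- reconstruct(fx$proj, fx$prj,
                     recon_config("OSEM", n_subsets = 4, n_subiterations = 12,
                                  save_every = 4))
  expect_named(res$snapshots,
               c("subiter_004", "subiter_008", "subiter_012"))
  ## last snapshot equals the final image
  expect_identical(res$snapshots$subiter_012$voxels, res$image$voxels)
  res2 <- reconstruct(fx$proj, fx$prj,
                      recon_config("OSEM", n_subsets = 4,
                                   n_subiterations = 12, save_every = 4))
  expect_identical(res$image$voxels, res2$image$voxels)

  ## MLEM with 9 iterations runs 9 full passes (trace length when tracked)
  resM <- reconstruct(fx$proj, fx$prj,
                      recon_config("MLEM", n_subiterations = 9,
                                   track_objective = TRUE))
  expect_equal(nrow(resM$trace), 9)
})
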
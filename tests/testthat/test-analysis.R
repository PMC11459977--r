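## tiny synthetic image for metric arithmetic
metric_fixture <- function() {
  grid <- empty_volume(c(20, 24, 24), 1)
  list(grid = grid,
       mk = function(vals) {
         v <- grid
         v$voxels <- array(vals, dim = dim(grid$voxels))
         v
       })
}

test_that("CV, uniformity: hand-checked values, flags, scale invariance", {
  fx <- metric_fixture()
  roi <- nema_roi(10, 10)
  img <- fx$mk(5)
  expect_equal(cv(img, roi), 0)                 # constant ROI
  expect_equal(uniformity(img, roi), 0)

  ## two-voxel ROI {1, 3}: population sd 1, mean 2 -> CV = 0.5
  m <- array(FALSE, dim = dim(fx$grid$voxels))
  m[1, 1, 1] <- m[1, 1, 2] <- TRUE
  v <- fx$mk(0); v$voxels[1, 1, 1] <- 1; v$voxels[1, 1, 2] <- 3
  expect_equal(cv(v, m), 0.5)
  ## I_max = 2, I_min = 1 -> U = 1/3 ; I_min = 0 -> U = 1 (the 100% regime)
  v$voxels[1, 1, 1] <- 1; v$voxels[1, 1, 2] <- 2
  expect_equal(uniformity(v, m), 1 / 3)
  v$voxels[1, 1, 1] <- 0
  expect_equal(uniformity(v, m), 1)

  ## positive scaling leaves both invariant
  set.seed(4)
  r <- fx$mk(runif(prod(dim(fx$grid$voxels)), 1, 2))
  r5 <- fx$mk(5 * r$voxels)
  expect_equal(cv(r5, roi), cv(r, roi))
  expect_equal(uniformity(r5, roi), uniformity(r, roi))

  ## zero-mean ROI flagged missing
  expect_true(is.na(cv(fx$mk(0), roi)))
  expect_true(is.na(uniformity(fx$mk(0), roi)))
})

test_that("CNR: hand arithmetic, zero-contrast, consistency with CV", {
  fx <- metric_fixture()
  rod <- array(FALSE, dim = dim(fx$grid$voxels)); rod[5, 5, 5] <- TRUE
  ref <- array(FALSE, dim = dim(fx$grid$voxels)); ref[5, 10, 10] <- TRUE
  uni <- array(FALSE, dim = dim(fx$grid$voxels))
  uni[15, 1:4, 1] <- TRUE
  img <- fx$mk(0)
  img$voxels[5, 5, 5] <- 3                       # I_i
  img$voxels[5, 10, 10] <- 1                     # I_r
  img$voxels[15, 1:4, 1] <- c(2, 6, 2, 6)        # mu = 4, sd = 2, CV = 0.5
  ## (|3-1|/(3+1)) / 0.5 = 1
  expect_equal(unname(cnr(img, list(r1 = rod), ref, uni)), 1)
  ## rescale the noise ROI: CV = 0.25 -> CNR doubles
  img$voxels[15, 1:4, 1] <- c(3, 5, 3, 5)
  expect_equal(unname(cnr(img, list(r1 = rod), ref, uni)), 2)
  ## I_i == I_r gives CNR 0; global scaling leaves CNR unchanged
  img$voxels[5, 5, 5] <- 1
  expect_equal(unname(cnr(img, list(r1 = rod), ref, uni)), 0)
  img$voxels[5, 5, 5] <- 3
  im2 <- fx$mk(img$voxels * 7)
  expect_equal(cnr(im2, list(r1 = rod), ref, uni),
               cnr(img, list(r1 = rod), ref, uni))
  ## CNR_i * CV == contrast term, exactly
  got <- cnr(img, list(r1 = rod), ref, uni) * cv(img, uni)
  expect_equal(unname(got), abs(3 - 1) / (3 + 1))
})

test_that("NEMA ROI fractions reproduce the documented ROI dimensions", {
  r1 <- nema_roi(30, 15)
  expect_equal(r1$diameter, 18)                  # 60% of 30 mm
  expect_equal(r1$length, 11.25)                 # 75% of 15 mm
  r2 <- nema_roi(26, 21)
  expect_equal(r2$diameter, 15.6)
  expect_equal(r2$length, 15.75)
  r3 <- nema_roi(26, 21, fractions = c(1, 1))
  expect_equal(r3$diameter, 26)
  expect_equal(r3$length, 21)
})

test_that("FWHM: Gaussian oracle, impulse floor, isotropy", {
  ## ideal Gaussian line source, sigma = 1 mm, 0.1 mm grid
  grid <- empty_volume(c(12, 161, 161), 0.1)
  co <- pinholetomo:::voxel_coords(grid)
  prof <- exp(-outer(co$y^2, co$x^2, `+`) / 2)
  vol <- grid
  vol$voxels <- aperm(array(prof, c(161, 161, 12)), c(3, 1, 2))
  f <- fwhm_resolution(vol, rbind(c(0, 0)), slab_centres = 0,
                       slab_thickness = 1, search_radius = 1)
  expect_equal(f$average, 2 * sqrt(2 * log(2)), tolerance = 0.005)
  ## x and y agree for an isotropic blur
  expect_equal(f$table$fwhm[f$table$axis == "x"],
               f$table$fwhm[f$table$axis == "y"], tolerance = 0.01)

  ## single-voxel impulse: interpolation floor of one voxel width
  grid2 <- empty_volume(c(8, 21, 21), 0.5)
  imp <- grid2; imp$voxels[4, 11, 11] <- 1
  fi <- fwhm_resolution(imp, rbind(c(0, 0)), slab_centres = 0,
                        slab_thickness = 2, search_radius = 2)
  expect_equal(fi$average, 0.5, tolerance = 1e-6)

  ## peak on the volume boundary is flagged missing
  edge <- grid2; edge$voxels[4, 11, 21] <- 1
  fe <- fwhm_resolution(edge, rbind(c(5, 0)), slab_centres = 0,
                        slab_thickness = 2, search_radius = 1)
  expect_true(any(is.na(fe$table$fwhm)))
})

test_that("fom_series tabulates metrics over snapshots", {
  fx <- metric_fixture()
  snaps <- list(subiter_002 = fx$mk(1), subiter_004 = fx$mk(2))
  res <- structure(list(snapshots = snaps,
                        config = recon_config("OSEM", n_subiterations = 4)),
                   class = "recon_result")
  tab <- fom_series(res, nema_roi(10, 10))
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$metric, c("cv", "uniformity"))
  expect_equal(tab$subiteration, c(2, 2, 4, 4))
})
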
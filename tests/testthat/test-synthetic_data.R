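# The phantom generator and the image-domain reconstruction surrogate.

spec128 <- phantom_spec()

test_that("activity map honours activities, ratio and linearity", {
  vol <- build_activity_map(spec128, 128)
  msk <- suppressWarnings(make_voi_masks(spec128, 128))
  # lung insert voxels are cold
  expect_true(all(vol$data[msk$data == 9] == 0))
  # interior sphere-to-background ratio is 4:1 up to rasterization
  interior <- sphere_interior_mask(spec128, vol, 1)
  bg <- mean(vol$data[msk$data %in% c(7, 8)])
  expect_equal(mean(vol$data[interior]) / bg, 4, tolerance = 0.02)
  # doubling all activities doubles the map voxel-wise
  spec2 <- phantom_spec(sphere_activity = 40, background_activity = 10)
  vol2 <- build_activity_map(spec2, 128)
  expect_equal(vol2$data, 2 * vol$data, tolerance = 1e-12)
})

test_that("geometry violations are caught", {
  bad <- phantom_spec(field_of_view = 100)  # ring no longer fits
  expect_error(build_activity_map(bad, 128),
               class = "radiorobust_geometry_error")
  expect_error(make_voi_masks(phantom_spec(sphere_diameters = numeric(0)), 128),
               class = "radiorobust_geometry_error")
  expect_error(build_activity_map(spec128, 100),
               class = "radiorobust_validation_error")
})

test_that("label map has nine disjoint regions and flags tiny VOIs", {
  expect_warning(msk <- make_voi_masks(spec128, 128), "only")
  labs <- sort(unique(as.vector(msk$data[msk$data > 0])))
  expect_equal(labs, 1:9)
  # smallest sphere on the coarse grid: very few voxels, flagged
  expect_lte(sum(msk$data == 6), 12)
  expect_true("sphere6" %in% attr(msk, "low_count"))
  msk256 <- make_voi_masks(spec128, 256)
  expect_equal(sort(unique(as.vector(msk256$data[msk256$data > 0]))), 1:9)
})

test_that("reconstruction surrogate is deterministic and has the zero-noise limit", {
  act <- build_activity_map(spec128, 128)
  s <- transform(build_grid("gaussian_fwhm")[1, ], matrix_size = 128)
  m <- effect_model()
  r1 <- simulate_reconstruction(act, s, m, seed = 11)
  r2 <- simulate_reconstruction(act, s, m, seed = 11)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_reconstruction(act, s, m, seed = 12)
  expect_false(identical(r1$data, r3$data))
  # no blur, no axial filter, no noise -> exactly the activity map
  m0 <- effect_model(noise_sigma0 = 0, base_fwhm = 0)
  r0 <- simulate_reconstruction(act, s, m0, seed = 1)
  expect_equal(r0$data, act$data, tolerance = 1e-10)
})

test_that("noise SD scales as acquisition time^(-1/2)", {
  act <- build_activity_map(spec128, 128)
  s <- transform(build_grid("acquisition_time"), matrix_size = 128)
  m <- effect_model(base_fwhm = 0)
  # flat background box away from all inserts: smoothing leaves it at 5,
  # so its spread is pure noise; > 10^4 voxels for Monte-Carlo stability
  flat <- array(FALSE, dim(act$data))
  flat[1:20, 1:20, ] <- TRUE
  expect_gt(sum(flat), 1e4)
  sd1 <- sd(simulate_reconstruction(act, s[s$x_value == 1, ], m, 5)$data[flat])
  sd4 <- sd(simulate_reconstruction(act, s[s$x_value == 4, ], m, 6)$data[flat])
  expect_equal(sd1 / sd4, 2, tolerance = 0.05)
  # closed form against the model constants (TOF factor 0.85, 2x28 updates)
  expect_equal(sd1, 0.5 * sqrt(3 / 1) * 0.85, tolerance = 0.05)
})

test_that("smoothing strength is monotone in FWHM, z-weight and beta", {
  act <- build_activity_map(spec128, 128)
  m <- effect_model(noise_sigma0 = 0)
  spatial_var <- function(s) {
    stats::var(as.vector(simulate_reconstruction(act, s, m, 1)$data))
  }
  gf <- build_grid("gaussian_fwhm")
  v_g <- vapply(c(0, 5, 10), function(w) {
    spatial_var(transform(gf[1, ], gaussian_fwhm = w))
  }, numeric(1))
  expect_true(all(diff(v_g) < 0))
  zf <- build_grid("z_filter")
  v_z <- vapply(1:4, function(i) spatial_var(zf[i, ]), numeric(1))
  expect_true(all(diff(v_z) < 1e-12))
  bb <- build_grid("bpl_beta")
  v_b <- vapply(c(50, 350, 1000), function(b) {
    spatial_var(transform(bb[1, ], beta = b))
  }, numeric(1))
  expect_true(all(diff(v_b) < 0))
  # more updates never lowers the noise SD
  upd <- build_grid("osem_updates")
  m2 <- effect_model(base_fwhm = 0)
  sd_lo <- sd(simulate_reconstruction(act, upd[upd$x_value == 16, ][1, ], m2, 2)$data)
  sd_hi <- sd(simulate_reconstruction(act, upd[upd$x_value == 320, ][1, ], m2, 3)$data)
  expect_gt(sd_hi, sd_lo)
})

test_that("partial-volume behaviour: smoothing preserves the large sphere mean, not the small one", {
  act <- build_activity_map(spec128, 256)
  msk <- make_voi_masks(spec128, 256)
  m <- effect_model(noise_sigma0 = 0)
  s <- build_grid("gaussian_fwhm")[1, ]
  # core of the 37 mm sphere (half radius): several blur sigmas from the
  # boundary, so its mean survives smoothing; the full 10 mm sphere VOI is
  # comparable to the kernel and loses activity monotonically
  core <- {
    d2 <- sphere_interior_mask(spec128, act, 1)
    spec_half <- spec128
    spec_half$sphere_diameters[1] <- spec128$sphere_diameters[1] / 2
    sphere_interior_mask(spec_half, act, 1)
  }
  mean_in <- function(fwhm, vox) {
    r <- simulate_reconstruction(act, transform(s, gaussian_fwhm = fwhm), m, 1)
    mean(r$data[vox])
  }
  m37 <- vapply(c(0, 5, 7), mean_in, numeric(1), vox = core)
  m10 <- vapply(c(0, 5, 10), mean_in, numeric(1), vox = msk$data == 6)
  expect_equal(m37 / mean(act$data[core]), rep(1, 3), tolerance = 0.02)
  expect_true(all(diff(m10) < 0))
})

test_that("synthetic feature tables follow the generative model exactly", {
  tab <- simulate_feature_values("a/x+b", "bpl_beta", x = 10, n_regions = 3,
                                 alpha_range = c(2, 2), beta_range = c(1, 1),
                                 sigma = 0, seed = 1)
  expect_equal(tab$value, rep(2 / 10 + 1, 3))
  t1 <- simulate_feature_values("a*log(x)+b", "gaussian_fwhm", x = 0:10,
                                sigma = 0.1, seed = 42)
  t2 <- simulate_feature_values("a*log(x)+b", "gaussian_fwhm", x = 0:10,
                                sigma = 0.1, seed = 42)
  expect_identical(t1, t2)
  truth <- attr(t1, "truth")
  expect_equal(truth$family, "a*log(x)+b")
  expect_length(truth$alpha, 9)
  # sigma = 0 values reproduce from the recorded truth (x rescaled: +2)
  t0 <- simulate_feature_values("a*x+b", "gaussian_fwhm", x = c(0, 3, 8),
                                n_regions = 2, sigma = 0, seed = 7)
  tr <- attr(t0, "truth")
  expect_equal(t0$value[t0$region == "region1"],
               tr$alpha[1] * (c(0, 3, 8) + 2) + tr$beta[1])
})

test_that("volumes round-trip through NIfTI with spacing intact", {
  vol <- build_activity_map(spec128, 128)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$data, vol$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-5)
  unlink(path)
})
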
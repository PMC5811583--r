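test_that("noiseless phantom generation conserves total activity", {
  spec <- phantom_spec(spheres = list(sphere_spec(c(0, 0, 0), 1, 10)),
                       psf_fwhm = 0, grid_shape = c(32, 32, 32))
  ph <- generate_phantom(spec)
  total_mbq <- sum(ph$image$values) / 1e6
  expect_lt(abs(total_mbq - 10) / 10, 0.005)  # rasterization tolerance

  sharp <- generate_phantom(phantom_spec(psf_fwhm = 0))
  expect_lt(abs(sum(sharp$image$values) / 1e6 - sum(sharp$truth$activity_mbq)) /
              sum(sharp$truth$activity_mbq), 0.005)

  blurred <- generate_phantom(phantom_spec(psf_fwhm = 12))
  expect_equal(sum(blurred$image$values), sum(sharp$image$values),
               tolerance = 1e-6)
})

test_that("default NEMA ground truth spans 0.5 to 26.5 ml", {
  ph <- generate_phantom(phantom_spec(psf_fwhm = 0))
  expect_equal(min(ph$truth$volume_ml), 0.5)
  expect_equal(max(ph$truth$volume_ml), 26.5)
  expect_equal(nrow(ph$truth), 6)
  expect_equal(ph$truth$activity_mbq,
               ph$truth$volume_ml * ph$truth$concentration_mbq_ml)
})

test_that("sphere_spec radius is consistent with its volume", {
  for (v in c(0.5, 1.2, 2.6, 5.6, 11.5, 26.5)) {
    s <- sphere_spec(c(0, 0, 0), v, 1)
    expect_equal(4 / 3 * pi * s$radius_mm^3 / 1000, v, tolerance = 1e-9)
  }
  expect_error(sphere_spec(c(0, 0, 0), -1, 1), "> 0")
})

test_that("invalid phantom geometry errors", {
  border <- phantom_spec(
    spheres = list(sphere_spec(c(70, 0, 0), 26.5, 1)),
    grid_shape = c(32, 32, 32)  # half-extent 76.8 mm < 70 + r + 2 FWHM
  )
  expect_error(generate_phantom(border), "border")
  overlapping <- phantom_spec(spheres = list(
    sphere_spec(c(0, 0, 0), 26.5, 1),
    sphere_spec(c(10, 0, 0), 26.5, 1)
  ))
  expect_error(generate_phantom(overlapping), "overlap")
})

test_that("fixed seeds reproduce noisy outputs bit-for-bit", {
  spec <- phantom_spec(spheres = list(sphere_spec(c(0, 0, 0), 2.6, 5)),
                       grid_shape = c(32, 32, 32), noise_enabled = TRUE,
                       seed = 7L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$values, b$image$values)
  other <- generate_phantom(phantom_spec(
    spheres = list(sphere_spec(c(0, 0, 0), 2.6, 5)),
    grid_shape = c(32, 32, 32), noise_enabled = TRUE, seed = 8L
  ))
  expect_false(identical(a$image$values, other$image$values))
})

test_that("Poisson noise conserves activity in expectation and leaves the RNG alone", {
  sc <- default_scene()
  totals <- vapply(1:20, function(s) {
    sum(apply_poisson_noise(sc$image, 1, s)$values)
  }, 0)
  truth <- sum(sc$image$values)
  se <- stats::sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - truth), 3 * se)

  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(apply_poisson_noise(sc$image, 1, 5))
  expect_identical(runif(1), before)
})

test_that("increasing PSF width never increases the maximum voxel value", {
  base <- phantom_spec(spheres = list(sphere_spec(c(0, 0, 0), 2.6, 5)),
                       grid_shape = c(32, 32, 32))
  maxima <- vapply(c(0, 6, 12, 18), function(f) {
    max(generate_phantom(modifyList(base, list(psf_fwhm = f)))$image$values)
  }, 0)
  expect_true(all(diff(maxima) <= 1e-9))
})

test_that("patient scene margin mask recovers the deposition activity", {
  sc <- default_scene()
  s <- mask_sum(sc$image, sc$margin_mask) / 1e6
  expect_lt(abs(s - 3.7) / 3.7, 0.01)
  expect_false(any(sc$margin_mask$selected & sc$liver_mask$selected))

  zero <- generate_patient_scene(patient_scene_spec(
    deposition_activity_mbq = 0, liver_activity_mbq = 0,
    lung_activity_mbq = 0
  ))
  expect_equal(mask_sum(zero$image, zero$margin_mask), 0)

  spec <- patient_scene_spec(noise_enabled = TRUE, seed = 3L)
  expect_identical(generate_patient_scene(spec)$image$values,
                   generate_patient_scene(spec)$image$values)
})

test_that("deposition overlapping the liver is rejected", {
  spec <- patient_scene_spec(deposition_center = c(-80, 0, -60))
  expect_error(generate_patient_scene(spec), "disjoint")
})

test_that("planar projection conserves counts and is symmetric without attenuation", {
  vals <- array(0, c(8, 8, 8))
  vals[4, 5, 3] <- 1
  img <- voxel_image(vals, spacing = c(4.8, 4.8, 4.8))
  lab <- roi_mask(array(TRUE, c(8, 8, 8)))
  pr <- project_planar(img, lab, lab, mu = 0)
  expect_identical(pr$anterior$values, pr$posterior$values)
  expect_equal(sum(pr$anterior$values), 1)
  expect_equal(sum(pr$posterior$values), 1)
})

test_that("geometric mean cancels depth attenuation for a point source", {
  # Closed form: a unit source at depth d sees exp(-mu*d) anterior and
  # exp(-mu*(T-d)) posterior; the geometric mean is exp(-mu*T/2) at any d,
  # so correcting by the known half-thickness recovers the true counts.
  mu <- 0.011  # ~81 keV in water, per mm
  n <- 8
  sy <- 4.8
  total_thickness <- n * sy
  for (depth_vox in c(2, 5, 7)) {
    vals <- array(0, c(8, n, 8))
    vals[4, depth_vox, 4] <- 1
    img <- voxel_image(vals, spacing = c(4.8, sy, 4.8))
    lab <- roi_mask(array(TRUE, dim(vals)))
    pr <- project_planar(img, lab, lab, mu = mu)
    expect_false(isTRUE(all.equal(pr$anterior$values, pr$posterior$values)))
    gm <- sqrt(sum(pr$anterior$values) * sum(pr$posterior$values))
    recovered <- gm * exp(mu * total_thickness / 2)
    expect_equal(recovered, 1, tolerance = 0.05)
  }
})

test_that("phantom and scene specs round-trip through JSON", {
  ps <- phantom_spec(psf_fwhm = 9, seed = 5L)
  path <- tempfile(fileext = ".json")
  write_spec_json(ps, path)
  back <- read_phantom_spec(path)
  expect_equal(back$psf_fwhm, 9)
  expect_equal(length(back$spheres), 6)
  expect_equal(vapply(back$spheres, function(s) s$volume_ml, 0),
               vapply(ps$spheres, function(s) s$volume_ml, 0))
  unlink(path)

  ss <- patient_scene_spec(deposition_activity_mbq = 2.2, seed = 9L)
  write_spec_json(ss, path)
  back2 <- read_patient_scene_spec(path)
  expect_equal(back2$deposition_activity_mbq, 2.2)
  expect_equal(back2$lung_centers, ss$lung_centers)
  unlink(path)
})
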
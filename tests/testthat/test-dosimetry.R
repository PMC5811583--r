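test_that("estimate_activity recovers a known noiseless deposition and is linear", {
  sc <- default_scene()
  a <- estimate_activity(sc$image, sc$margin_mask)
  expect_lt(abs(a - 3.7) / 3.7, 0.01)

  zero <- voxel_image(array(0, dim(sc$image$values)), sc$image$spacing)
  expect_equal(estimate_activity(zero, sc$margin_mask), 0)

  doubled <- voxel_image(sc$image$values * 2, sc$image$spacing,
                         sc$image$origin)
  expect_equal(estimate_activity(doubled, sc$margin_mask), 2 * a)

  empty <- roi_mask(array(FALSE, dim(sc$image$values)))
  expect_error(estimate_activity(sc$image, empty), "empty")
})

test_that("estimate_volume applies the percentage-of-maximum rule", {
  vals <- array(0, c(10, 10, 10))
  vals[2:5, 2:6, 2:6] <- 100  # 4*5*5 = 100 voxels, uniform
  img <- voxel_image(vals, spacing = c(4.8, 4.8, 4.8))
  full <- roi_mask(array(TRUE, c(10, 10, 10)))
  for (t in c(0.1, 0.3, 1.0)) {
    expect_equal(estimate_volume(img, full, t), 100 * voxel_volume_ml(img))
  }

  # threshold 1.0 keeps only max-attaining voxels
  vals[3, 3, 3] <- 200
  img2 <- voxel_image(vals, spacing = c(4.8, 4.8, 4.8))
  expect_equal(estimate_volume(img2, full, 1.0), voxel_volume_ml(img2))

  # the in-mask maximum sets the threshold: high activity outside the
  # margin must not change the volume
  sel <- array(FALSE, c(10, 10, 10))
  sel[1:6, 1:7, 1:7] <- TRUE
  margin <- roi_mask(sel)
  vals3 <- vals
  vals3[9, 9, 9] <- 1e6  # hepatic hot spot outside the margin
  img3 <- voxel_image(vals3, spacing = c(4.8, 4.8, 4.8))
  expect_equal(estimate_volume(img3, margin, 1.0),
               estimate_volume(img2, margin, 1.0))

  expect_error(estimate_volume(voxel_image(array(0, c(4, 4, 4)), c(1, 1, 1)),
                               roi_mask(array(TRUE, c(4, 4, 4)))),
               "threshold undefined")
  expect_error(estimate_volume(img, full, 0), "in \\(0, 1\\]")
  expect_error(estimate_volume(img, full, 1.2), "in \\(0, 1\\]")
})

test_that("threshold volume of a blurred sphere matches brute-force voxel counting", {
  spec <- phantom_spec(spheres = list(sphere_spec(c(0, 0, 0), 2.6, 5)),
                       grid_shape = c(48, 48, 48), seed = 2L)
  ph <- generate_phantom(spec)
  mask <- phantom_margin_masks(ph$image, ph$truth, margin_mm = 24)[[1]]
  v <- estimate_volume(ph$image, mask, 0.30)
  # independent brute-force loop over voxels
  mx <- -Inf
  for (i in seq_along(ph$image$values)) {
    if (mask$selected[i] && ph$image$values[i] > mx) mx <- ph$image$values[i]
  }
  count <- 0
  for (i in seq_along(ph$image$values)) {
    if (mask$selected[i] && ph$image$values[i] >= 0.30 * mx) count <- count + 1
  }
  expect_equal(v, count * voxel_volume_ml(ph$image))
})

test_that("absorbed_dose reproduces the tabulated cohort and unit checks", {
  expect_equal(round(absorbed_dose(3.7, 15.3), 1), 3.6)
  expect_equal(round(absorbed_dose(1.3, 13.9), 1), 1.4)
  expect_equal(absorbed_dose(1.06, 15.87), 1)
  expect_equal(absorbed_dose(0, 10), 0)
  expect_error(absorbed_dose(1, 0), "> 0")
  expect_error(absorbed_dose(-1, 1), ">= 0")
})

test_that("dose scales linearly in activity and inversely in volume", {
  set.seed(8)
  for (i in 1:20) {
    a <- runif(1, 0.1, 40)
    v <- runif(1, 0.5, 40)
    k <- runif(1, 0.1, 10)
    expect_equal(absorbed_dose(k * a, v), k * absorbed_dose(a, v))
    expect_equal(absorbed_dose(a, k * v), absorbed_dose(a, v) / k)
  }
})

test_that("estimate_volume is monotone non-increasing in the threshold", {
  sc <- default_scene()
  vols <- vapply(seq(0.05, 1, by = 0.05), function(t) {
    estimate_volume(sc$image, sc$margin_mask, t)
  }, 0)
  expect_true(all(diff(vols) <= 0))
  # and the activity path ignores the threshold entirely
  a <- estimate_activity(sc$image, sc$margin_mask)
  expect_identical(a, estimate_activity(sc$image, sc$margin_mask))
})

test_that("quantify_deposition composes the three estimates consistently", {
  sc <- default_scene()
  rec <- quantify_deposition(sc$image, sc$margin_mask, 0.30)
  expect_s3_class(rec, "deposition_record")
  expect_equal(rec$dose_gy,
               absorbed_dose(rec$activity_mbq, rec$volume_ml),
               tolerance = 1e-9)
  expect_equal(rec$threshold_fraction, 0.30)
  expect_equal(rec$mask_label, "deposition_margin")
  # end-to-end: dose within 20% of the true 3.6 Gy (volume is PSF-dependent)
  true_dose <- absorbed_dose(3.7, 15.3)
  expect_lt(abs(rec$dose_gy - true_dose) / true_dose, 0.20)

  zero <- generate_patient_scene(patient_scene_spec(
    deposition_activity_mbq = 0, liver_activity_mbq = 0, lung_activity_mbq = 0
  ))
  expect_error(quantify_deposition(zero$image, zero$margin_mask),
               "threshold undefined")
})

test_that("two disjoint depositions quantify independently", {
  base <- patient_scene_spec(liver_activity_mbq = 0, lung_activity_mbq = 0,
                             deposition_center = c(110, 0, -20))
  one <- generate_patient_scene(base)
  rec_one <- quantify_deposition(one$image, one$margin_mask, 0.30)
  # add a second blob far away by summing a shifted scene
  other <- generate_patient_scene(patient_scene_spec(
    liver_activity_mbq = 0, lung_activity_mbq = 0,
    deposition_center = c(-110, 0, 100), deposition_activity_mbq = 8,
    deposition_volume_ml = 6
  ))
  both <- voxel_image(one$image$values + other$image$values,
                      one$image$spacing, one$image$origin)
  rec_both <- quantify_deposition(both, one$margin_mask, 0.30)
  expect_equal(rec_both$dose_gy, rec_one$dose_gy, tolerance = 0.01)
  rec_other <- quantify_deposition(both, other$margin_mask, 0.30)
  expect_equal(rec_other$activity_mbq, 8, tolerance = 0.01)
})

test_that("cohort_summary reports order-statistic medians and ranges", {
  pairs <- cohort_pairs()
  records <- Map(deposition_record, pairs$activity_mbq, pairs$volume_ml)
  cs <- cohort_summary(records)
  s <- cs$summary
  dose <- s[s$metric == "dose_gy", ]
  expect_equal(round(dose$upper_median, 1), 3.6)
  expect_equal(round(dose$min, 1), 0.3)
  expect_lte(dose$max, 14)
  expect_equal(s$upper_median[s$metric == "volume_ml"], 15.3)
  expect_equal(s$upper_median[s$metric == "activity_mbq"], 3.7)
  expect_true(all(s$min <= s$lower_median & s$lower_median <= s$median &
                    s$median <= s$upper_median & s$upper_median <= s$max))

  one <- cohort_summary(list(deposition_record(2, 10)))
  expect_equal(one$summary$lower_median, one$summary$upper_median)
  expect_equal(one$summary$median[1], 2)

  # odd n: all three medians coincide
  odd <- cohort_summary(Map(deposition_record, c(1, 2, 3), c(10, 10, 10)))
  so <- odd$summary[odd$summary$metric == "activity_mbq", ]
  expect_equal(so$lower_median, 2)
  expect_equal(so$median, 2)
  expect_equal(so$upper_median, 2)

  expect_error(cohort_summary(list()), "nonempty")
})
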
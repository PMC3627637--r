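test_that("density-mask percentages match hand counts", {
  m4 <- mask_all(c(4, 1, 1))
  expect_equal(percent_voxels_below(vol_from_values(rep(-1000, 4)), m4, -950), 100)
  expect_equal(percent_voxels_below(
    vol_from_values(c(-1000, -960, -900, -800)), m4, -950), 50)
  # strict inequality: a voxel exactly at the threshold is not counted
  expect_equal(percent_voxels_below(vol_from_values(rep(-950, 4)), m4, -950), 0)
})

test_that("mean lung attenuation is the masked arithmetic mean", {
  m2 <- mask_all(c(2, 1, 1))
  expect_equal(mean_lung_attenuation(vol_from_values(c(-900, -700)), m2), -800)
  expect_equal(mean_lung_attenuation(vol_from_values(c(-850, -850)), m2), -850)
})

test_that("relative lung volume partitions non-emphysematous lung", {
  m3 <- mask_all(c(3, 1, 1))
  expect_equal(relative_lung_volume(
    vol_from_values(c(-1000, -900, -800)), m3), 0.5)
  expect_equal(relative_lung_volume(vol_from_values(rep(-900, 3)), m3), 1)
  expect_error(relative_lung_volume(vol_from_values(rep(-1000, 3)), m3),
               "no non-emphysematous lung")
})

test_that("paired measures reduce to simple arithmetic on crafted pairs", {
  # insp relative volume 0.8, exp relative volume 0.4
  insp <- vol_from_values(c(-900, -900, -900, -900, -800))
  expv <- vol_from_values(c(-900, -900, -800, -800, -800))
  m5 <- mask_all(c(5, 1, 1))
  pair <- scan_pair(insp, m5, expv, m5)
  expect_equal(rvc_856_950(pair), -0.4)
  # expiratory MLA -783, inspiratory MLA -900
  pair2 <- scan_pair(vol_from_values(rep(-900, 5)), m5,
                     vol_from_values(rep(-783, 5)), m5)
  expect_equal(ei_mla(pair2), 0.87)
})

test_that("voxel-counting metrics equal a per-voxel loop oracle", {
  set.seed(42)
  for (rep in 1:25) {
    dims <- sample(6:32, 3, replace = TRUE)
    vol <- random_volume(dims)
    msk_arr <- array(stats::runif(prod(dims)) > 0.4, dim = dims)
    msk_arr[1] <- TRUE  # never empty
    msk <- lung_segmentation(msk_arr)
    oracle <- loop_oracle(vol$grid, msk$mask)
    expect_identical(percent_voxels_below(vol, msk, -950),
                     oracle$pct_below_emph)
    expect_identical(percent_voxels_below(vol, msk, -856),
                     oracle$pct_below_trap)
    expect_equal(mean_lung_attenuation(vol, msk), oracle$mla,
                 tolerance = 1e-9)
    if (!is.na(oracle$relvol))
      expect_identical(relative_lung_volume(vol, msk), oracle$relvol)
  }
})

test_that("percent below is monotone in threshold and anti-monotone in HU shift", {
  set.seed(7)
  vol <- random_volume(c(16, 16, 16))
  msk <- mask_all(c(16, 16, 16))
  thresholds <- seq(-1000, -700, by = 50)
  pcts <- vapply(thresholds, function(t) percent_voxels_below(vol, msk, t), 0)
  expect_true(all(diff(pcts) >= 0))
  for (delta in c(5, 50, 200)) {
    shifted <- attenuation_volume(vol$grid + delta, vol$spacing)
    expect_lte(percent_voxels_below(shifted, msk, -950),
               percent_voxels_below(vol, msk, -950))
  }
})

test_that("lung volume converts voxel counts to liters and scales with spacing", {
  expect_equal(lung_volume_liters(
    attenuation_volume(array(-800, dim = c(100, 100, 100))),
    mask_all(c(100, 100, 100))), 1.0)
  expect_equal(lung_volume_liters(
    attenuation_volume(array(-800, dim = c(10, 10, 10)), c(0.7, 0.7, 0.5)),
    mask_all(c(10, 10, 10))), 1000 * 0.245 * 1e-6)
  expect_warning(
    v0 <- lung_volume_liters(
      attenuation_volume(array(-800, dim = c(2, 2, 2))),
      lung_segmentation(array(FALSE, dim = c(2, 2, 2)))),
    "empty segmentation")
  expect_equal(v0, 0)
  # linear in each spacing component
  base <- lung_volume_liters(
    attenuation_volume(array(-800, dim = c(5, 5, 5)), c(1, 2, 3)),
    mask_all(c(5, 5, 5)))
  for (k in 1:3) {
    sp <- c(1, 2, 3); sp[k] <- sp[k] * 2.5
    expect_equal(lung_volume_liters(
      attenuation_volume(array(-800, dim = c(5, 5, 5)), sp),
      mask_all(c(5, 5, 5))), base * 2.5)
  }
})

test_that("emphysema severity uses strict smoking-status-specific cut-points", {
  expect_equal(as.character(classify_emphysema_severity(16, "former")), "severe")
  expect_equal(as.character(classify_emphysema_severity(3.9, "current")), "absent")
  expect_equal(as.character(classify_emphysema_severity(10, "former")),
               "intermediate")
  # sweep straddling every boundary; exact cut-point values are intermediate
  eps <- 0.01
  for (st in c("former", "current")) {
    lo <- if (st == "former") 5 else 4
    hi <- if (st == "former") 15 else 14
    cls <- as.character(classify_emphysema_severity(
      c(lo - eps, lo, lo + eps, hi - eps, hi, hi + eps), st))
    expect_equal(cls, c("absent", "intermediate", "intermediate",
                        "intermediate", "intermediate", "severe"))
  }
  expect_error(classify_emphysema_severity(101, "former"), "\\[0, 100\\]")
  expect_error(classify_emphysema_severity(10, "never"), "smoking_status")
})

test_that("classification is stable under perturbations smaller than the boundary distance", {
  set.seed(11)
  x <- runif(200, 0, 30)
  for (st in c("former", "current")) {
    lo <- if (st == "former") 5 else 4
    hi <- if (st == "former") 15 else 14
    gap <- pmin(abs(x - lo), abs(x - hi))
    keep <- gap > 1e-6
    eps <- 0.9 * gap[keep]
    base <- classify_emphysema_severity(x[keep], st)
    expect_equal(classify_emphysema_severity(pmin(x[keep] + eps, 100), st), base)
    expect_equal(classify_emphysema_severity(pmax(x[keep] - eps, 0), st), base)
  }
})

test_that("full metric panel is consistent and error messages name the metric", {
  pair <- identity_pair(seed = 3)
  m <- compute_scan_pair_metrics(pair)
  expect_equal(m$ei_mla, 1.0)
  expect_equal(m$rvc_856_950, 0.0)
  expect_equal(m$frc_tlc, 1.0)
  expect_equal(m$tlc_l, m$frc_l)
  # all fields finite and inside type ranges on random phantoms
  for (seed in 1:10) {
    sp <- phantom_spec(shape = c(16, 16, 16),
                       f_emph = runif(1, 0, 0.6), f_trap = runif(1, 0, 0.3),
                       seed = seed)
    mm <- compute_scan_pair_metrics(generate_phantom_pair(sp)$pair)
    expect_true(mm$insp_950 >= 0 && mm$insp_950 <= 100)
    expect_true(mm$exp_856 >= 0 && mm$exp_856 <= 100)
    expect_gt(mm$ei_mla, 0)
    expect_true(mm$rvc_856_950 >= -1 && mm$rvc_856_950 <= 1)
    expect_true(mm$tlc_l > 0 && mm$frc_l > 0)
    expect_true(is.finite(mm$frc_tlc))
    expect_true(mm$emphysema_class %in% c("absent", "intermediate", "severe"))
  }
  # degenerate attenuation near zero HU
  flat <- vol_from_values(rep(0.5, 4))
  m4 <- mask_all(c(4, 1, 1))
  expect_error(ei_mla(scan_pair(flat, m4, flat, m4)), "degenerate attenuation")
})

test_that("alignment and empty-mask errors are raised with clear labels", {
  vol <- random_volume(c(4, 4, 4))
  bad_mask <- mask_all(c(4, 4, 5))
  expect_error(percent_voxels_below(vol, bad_mask, -950), "alignment")
  empty <- lung_segmentation(array(FALSE, dim = c(4, 4, 4)))
  expect_error(percent_voxels_below(vol, empty, -950), "empty segmentation")
  expect_error(mean_lung_attenuation(vol, empty), "empty segmentation")
  expect_error(scan_pair(vol, bad_mask, vol, mask_all(c(4, 4, 4))), "alignment")
  expect_warning(attenuation_volume(array(-1100, dim = c(2, 2, 2))),
                 "calibration")
})
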
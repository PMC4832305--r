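# Error projection, localization precision theory and the sweep driver.

test_that("error projection separates axial and lateral components", {
  truth <- data.frame(frame = 1:200, true_x_nm = seq(1000, 3000, length.out = 200),
                      true_y_nm = 500)
  tracks <- data.frame(frame = 1:200, end_x_nm = truth$true_x_nm,
                       end_y_nm = truth$true_y_nm, reliability = TRUE)
  e0 <- project_errors(tracks, truth, axis_angle_rad = 0, n_boot = 50)
  expect_equal(e0$axial_offset, 0)
  expect_equal(e0$axial_precision, 0)
  expect_equal(e0$rmse, 0)

  # constant +10 nm axial shift along a rotated axis
  ang <- 0.7
  tracks$end_x_nm <- truth$true_x_nm + 10 * cos(ang)
  tracks$end_y_nm <- truth$true_y_nm + 10 * sin(ang)
  e1 <- project_errors(tracks, truth, axis_angle_rad = ang, n_boot = 50)
  expect_equal(e1$axial_offset, 10)
  expect_equal(e1$lateral_offset, 0, tolerance = 1e-9)
  expect_equal(e1$axial_precision, 0)
})

test_that("injected Gaussian errors are recovered with bootstrap SEs", {
  set.seed(7)
  n <- 750
  truth <- data.frame(frame = 1:n, true_x_nm = 2000, true_y_nm = 500)
  ax <- rnorm(n, 0, 40)
  tracks <- data.frame(frame = 1:n, end_x_nm = 2000 + ax,
                       end_y_nm = 500 + rnorm(n, 0, 10), reliability = TRUE)
  e <- project_errors(tracks, truth, axis_angle_rad = 0, n_boot = 400,
                      seed = 2)
  expect_equal(e$axial_precision, 40, tolerance = 3 * e$se[["axial_precision"]] / 40)
  expect_equal(e$lateral_precision, 10, tolerance = 0.15)
  # rmse^2 ~ offset^2 + precision^2
  expect_equal(e$rmse^2, e$axial_offset^2 + e$axial_precision^2,
               tolerance = 0.01)
})

test_that("localization precision theory follows the closed forms", {
  # no background, no excess noise: sqrt((s^2 + a^2/12)/N)
  expect_equal(thompson_precision(135, 120, 500, 0, excess_factor = 1),
               sqrt((135^2 + 120^2 / 12) / 500))
  # doubling photons improves by sqrt(2) when background-free
  expect_equal(thompson_precision(135, 120, 1000, 0, 1) * sqrt(2),
               thompson_precision(135, 120, 500, 0, 1))
  # excess noise acts as an effective photon reduction
  expect_equal(thompson_precision(135, 120, 500, 2, 1.4),
               thompson_precision(135, 120, 500 / 1.96, 2, 1))
  # monotone decreasing in N across regimes
  ns <- c(20, 50, 200, 1000, 1e4)
  vals <- thompson_precision(135, 120, ns, 5)
  expect_true(all(diff(vals) < 0))
  expect_error(thompson_precision(135, 120, 0), "positive")
})

test_that("averaging precision and the image count solve are exact", {
  expect_equal(averaging_precision(40, 135, 1), sqrt(40^2 + 135^2))
  expect_equal(averaging_precision(40, 135, 400),
               averaging_precision(40, 135, 100) / 2)
  n <- averaging_images_needed(8, 40, 135)
  expect_equal(n, (40^2 + 135^2) / 64)
  expect_equal(averaging_precision(40, 135, n), 8)
})

test_that("sweep_runner produces one tidy row per condition", {
  conds <- data.frame(v_g_nm_per_s = c(20, 20), seed = c(5, 6),
                      noise = FALSE, labelling_ratio = 1,
                      d_p_nm2_per_s = 0, sigma_ld_nm = 0,
                      taper_length_nm = 0, exposure_s = 0, n_frames = 5L)
  res <- sweep_runner(conds, base_cfg = mt_config(), n_boot = 20)
  expect_identical(nrow(res), 2L)
  expect_true(all(is.finite(res$axial_precision)))
  expect_true(all(res$fraction_tracked == 1))
  expect_true(all(abs(res$axial_offset) < 5))
  # a failing condition yields an NA row, not an error
  bad <- data.frame(v_g_nm_per_s = 1e5, n_frames = 2L, seed = 7)
  res_bad <- sweep_runner(bad, base_cfg = mt_config(), n_boot = 10)
  expect_identical(nrow(res_bad), 1L)
  expect_true(!is.na(res_bad$error) || is.finite(res_bad$axial_precision))
})
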
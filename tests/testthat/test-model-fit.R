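# The Gaussian wall-end model and the sub-pixel least-squares fit.

p_ref <- list(end_x = 3000, end_y = 3800, sigma = 135, sigma_end = 135,
              amplitude = 400, background = 120, angle = 0)

model_frame <- function(p, width = 64, height = 64, a = 120) {
  x <- px_to_nm(col(matrix(0, height, width)), a)
  y <- px_to_nm(row(matrix(0, height, width)), a)
  matrix(wall_end_model(as.numeric(x), as.numeric(y), p), height, width)
}

test_that("wall-end model has the plateau and half-maximum structure", {
  p <- p_ref
  # deep inside the microtubule, on axis: plateau
  expect_equal(wall_end_model(p$end_x - 3000, p$end_y, p),
               p$background + p$amplitude, tolerance = 1e-9)
  # at the end position, on axis: exactly half the plateau above background
  expect_equal(wall_end_model(p$end_x, p$end_y, p),
               p$background + p$amplitude / 2)
  # far beyond the tip: background
  expect_equal(wall_end_model(p$end_x + 3000, p$end_y, p), p$background)
  # lateral profile is Gaussian with width sigma
  off <- wall_end_model(p$end_x - 2000, p$end_y + 135, p) - p$background
  on <- wall_end_model(p$end_x - 2000, p$end_y, p) - p$background
  expect_equal(off / on, exp(-0.5))
})

test_that("the model matches a rendered dense-labelled blunt end to < 2% RMS", {
  ip <- imaging_params(photons_per_fluorophore = 1, background_photons = 0)
  # dense line of emitters (spacing << sigma_PSF) ending at x_e - 4 nm
  img <- line_frame(200, 3000 - 4, y_nm = 3800, spacing = 8 / 13, ip = ip)
  amp <- max(img)
  p <- list(end_x = 3000, end_y = 3800, sigma = 135, sigma_end = 135,
            amplitude = amp, background = 0, angle = 0)
  mod <- model_frame(p)
  sel <- col(img) >= 5 & col(img) <= 35   # region clear of the line's start
  rms <- sqrt(mean((img[sel] - mod[sel])^2)) / amp
  expect_lt(rms, 0.02)
})

test_that("self-consistent fits recover parameters almost exactly", {
  for (ang in c(0, 0.4)) {
    p <- p_ref; p$angle <- ang
    img <- model_frame(p)
    mask <- matrix(TRUE, 64, 64)
    init <- list(end_x = p$end_x + 90, end_y = p$end_y - 70, sigma = 120,
                 amplitude = 300, background = 100, angle = ang + 0.1)
    fit <- fit_end(img, mask, init, imaging_params())
    expect_true(fit$reliability)
    expect_lt(abs(fit$params$end_x - p$end_x), 0.1)
    expect_lt(abs(fit$params$end_y - p$end_y), 0.1)
    expect_lt(abs(fit$params$sigma - p$sigma), 0.1)
    expect_lt(abs(fit$params$amplitude - p$amplitude) / p$amplitude, 0.001)
    expect_lt(abs(fit$params$angle - p$angle), 1e-3)
  }
})

test_that("free sigma_end variant recovers an elongated axial edge", {
  p <- p_ref; p$sigma_end <- 220
  img <- model_frame(p)
  fit <- fit_end(img, matrix(TRUE, 64, 64),
                 list(end_x = 3050, end_y = 3750, sigma = 135,
                      amplitude = 350, background = 110, angle = 0),
                 imaging_params(), variant = "free_sigma_end")
  expect_lt(abs(fit$params$sigma_end - 220), 1)
  expect_lt(abs(fit$params$end_x - p$end_x), 0.5)
})

test_that("fits are translation-equivariant under sub-pixel shifts", {
  ip <- imaging_params(photons_per_fluorophore = 2, background_photons = 1)
  shifts <- c(0, 37, 81)   # nm, sub-pixel
  ends <- vapply(shifts, function(dx) {
    img <- line_frame(200, 2996 + dx, y_nm = 3800, ip = ip)
    img <- img * 50   # detector-ish scale
    fit <- fit_end(img, matrix(TRUE, 64, 64),
                   list(end_x = 3000, end_y = 3800, sigma = 135,
                        amplitude = max(img) - 50, background = 50,
                        angle = 0),
                   ip)
    fit$params$end_x
  }, 0)
  expect_equal(diff(ends), diff(shifts + 3000), tolerance = 0.02)
})

test_that("degenerate masks and convergence failures are reported", {
  img <- model_frame(p_ref)
  small <- matrix(FALSE, 64, 64); small[1:4, 1:4] <- TRUE
  expect_error(fit_end(img, small, p_ref, imaging_params()), "degenerate")

  # standard errors are finite and positive for a noisy fit
  set.seed(1)
  noisy <- img + rnorm(length(img), 0, 10)
  fit <- fit_end(noisy, matrix(TRUE, 64, 64), p_ref, imaging_params())
  expect_true(all(is.finite(fit$param_errors)))
  expect_true(all(fit$param_errors > 0))
  expect_lte(fit$r2, 1)
})

test_that("coef, predict and residuals methods are coherent", {
  img <- model_frame(p_ref)
  fit <- fit_end(img, matrix(TRUE, 64, 64), p_ref, imaging_params())
  expect_named(coef(fit), c("end_x", "end_y", "sigma", "sigma_end",
                            "amplitude", "background", "angle"))
  expect_equal(predict(fit) + residuals(fit), fit$data$z)
  expect_lt(sum(residuals(fit)^2), 1e-6)
})
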
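# Lattice growth, geometry, taper maintenance and thermal bending.

test_that("subunit gain follows the stated normal law", {
  lp <- lattice_params(labelling_ratio = 0.2)
  # zero-variance case: exactly round(v_g * dt * n_pf / d) subunits
  gp0 <- growth_params(v_g_nm_per_s = 50, d_p_nm2_per_s = 0,
                       frame_interval_s = 1, exposure_s = 1,
                       sigma_ld_nm = 0, taper_length_nm = 0)
  st <- new_lattice(lp, 800, seed_length_nm = 16, seed = 1)
  n0 <- sum(st$pf_lengths)
  st1 <- step_growth(st, gp0, lp)$state
  expect_identical(sum(st1$pf_lengths) - n0, 81L)  # round(50*13/8)

  # stochastic case at baseline growth: mean 11*13/8, variance 2*271*(13/8)^2
  gp <- growth_params(v_g_nm_per_s = 11, d_p_nm2_per_s = 271,
                      frame_interval_s = 1, exposure_s = 1,
                      sigma_ld_nm = 0, taper_length_nm = 0)
  set.seed(42)
  draws <- replicate(4000, {
    out <- step_growth(st, gp, lp)$state
    sum(out$pf_lengths) - n0
  })
  expect_equal(mean(draws), 11 * 13 / 8, tolerance = 0.1)
  expect_equal(var(draws), 2 * 271 * (13 / 8)^2, tolerance = 0.08)
})

test_that("taper ramp stays stationary and blunt ends stay blunt", {
  lp <- lattice_params(labelling_ratio = 1)
  gp <- growth_params(v_g_nm_per_s = 50, d_p_nm2_per_s = 100,
                      taper_length_nm = 0, frame_interval_s = 0.5)
  st <- new_lattice(lp, 800, seed = 2)
  for (i in 1:20) st <- step_growth(st, gp, lp)$state
  tips <- mtrack:::pf_tip_axial(st, lp)
  expect_lt(max(tips) - min(tips), 8 + 1e-9)  # within one subunit

  gp_t <- growth_params(v_g_nm_per_s = 50, d_p_nm2_per_s = 100,
                        taper_length_nm = 96, frame_interval_s = 0.5)
  st <- new_lattice(lp, 800, taper_length_nm = 96, seed = 3)
  for (i in 1:20) st <- step_growth(st, gp_t, lp)$state
  expect_equal(true_end(st, lp)$sigma_pf_nm, sigma_pf_from_taper(96),
               tolerance = 0.15)
})

test_that("deterministic growth advances the true end at v_g", {
  lp <- lattice_params(labelling_ratio = 1)
  gp <- growth_params(v_g_nm_per_s = 40, d_p_nm2_per_s = 0, sigma_ld_nm = 0,
                      taper_length_nm = 0, frame_interval_s = 1)
  st <- new_lattice(lp, 800, seed = 4)
  l0 <- true_end(st, lp)$length_nm
  for (i in 1:10) st <- step_growth(st, gp, lp)$state
  # 10 s at 40 nm/s, within one-subunit rounding
  expect_equal(true_end(st, lp)$length_nm - l0, 400, tolerance = 8 / 400)
})

test_that("shrinkage clamps at the seed and flags", {
  lp <- lattice_params()
  gp <- growth_params(v_g_nm_per_s = -500, d_p_nm2_per_s = 0,
                      sigma_ld_nm = 0, taper_length_nm = 0,
                      frame_interval_s = 1)
  st <- new_lattice(lp, 200, seed = 5)
  out <- step_growth(st, gp, lp)$state
  expect_true(out$clamped)
  expect_true(all(out$pf_lengths >= out$seed_lengths))
})

test_that("subunit placement follows the 3-start helical geometry", {
  lp1 <- lattice_params(n_protofilaments = 1, labelling_ratio = 1,
                        helix_start = 1)
  st <- new_lattice(lp1, 16, seed = 6)
  st$pf_lengths <- 3L
  st$labels <- list(rep(TRUE, 3)); st$entry_times <- list(rep(-Inf, 3))
  xy <- place_subunits(st, lp1)
  expect_equal(sort(xy$x), c(0, 8, 16))

  # equal subunit counts: terminal ring spans the helical rise of one turn
  lp <- lattice_params(labelling_ratio = 1)
  st <- new_lattice(lp, 400, seed = 7)
  st$pf_lengths <- rep(50L, 13)
  st$labels <- lapply(1:13, function(k) rep(TRUE, 50))
  st$entry_times <- lapply(1:13, function(k) rep(-Inf, 50))
  ring <- place_subunits(st, lp, which = "terminal")
  expect_equal(max(ring$x) - min(ring$x), 3 * 8 * 12 / 13)

  # labelling ratio 0: no coordinates
  lp0 <- lattice_params(labelling_ratio = 0)
  st0 <- new_lattice(lp0, 400, seed = 8)
  expect_identical(nrow(place_subunits(st0, lp0)), 0L)
})

test_that("label flags are immutable across growth steps", {
  lp <- lattice_params(labelling_ratio = 0.5)
  gp <- growth_params(v_g_nm_per_s = 30, d_p_nm2_per_s = 50,
                      taper_length_nm = 0, frame_interval_s = 0.5)
  st <- new_lattice(lp, 800, seed = 9)
  before <- st$labels
  st2 <- step_growth(st, gp, lp)$state
  for (k in seq_along(before))
    expect_identical(st2$labels[[k]][seq_along(before[[k]])], before[[k]])
})

test_that("cantilever deflection shape and sampling are correct", {
  expect_equal(beam_deflection_shape(0), 0)
  expect_equal(beam_deflection_shape(1), 1)
  u <- seq(0, 1, by = 0.01)
  expect_true(all(diff(beam_deflection_shape(u)) > 0))

  gp0 <- growth_params(sigma_ld_nm = 0)
  coords <- data.frame(x = seq(0, 3000, by = 100), y = 0)
  expect_equal(apply_thermal_deflection(coords, gp0, 500)$y, coords$y)

  # tip displacement SD matches sigma_LD (Monte Carlo)
  gp <- growth_params(sigma_ld_nm = 150)
  set.seed(10)
  tips <- replicate(5000, {
    out <- apply_thermal_deflection(coords, gp, 500)
    out$y[nrow(out)]
  })
  expect_equal(sd(tips), 150, tolerance = 0.05)
  # axial positions never modified
  out <- apply_thermal_deflection(coords, gp, 500, seed = 11)
  expect_identical(out$x, coords$x)
})

test_that("true end is the mean terminal distal edge; sigma_PF is exact", {
  lp <- lattice_params(labelling_ratio = 1, helix_start = 1)
  # helix_start 1 with forced equal lengths: all tips at one axial position
  st <- new_lattice(lp, 400, seed = 12)
  st$pf_lengths <- rep(50L, 13)
  st$labels <- lapply(1:13, function(k) rep(TRUE, 50))
  st$entry_times <- lapply(1:13, function(k) rep(-Inf, 50))
  a <- 49 * 8 + (0:12) * 8 / 13  # per-PF terminal coordinates
  te <- true_end(st, lp)
  expect_equal(te$end[1], mean(a) + 4)   # + half subunit: polymer edge
  expect_equal(te$sigma_pf_nm, sd(a))

  # linear ramp of extent TL: brute-force SD oracle
  expect_equal(sigma_pf_from_taper(0), 0)
  expect_equal(sigma_pf_from_taper(96), sd(seq(0, -96, length.out = 13)))
  expect_equal(sigma_pf_from_taper(480) / sigma_pf_from_taper(96), 5)
})
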
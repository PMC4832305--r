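# Backbone refinement, axial profile, end proposal state machine, mask
# building and the movie-level tracking loop.

test_that("backbone refinement recovers a lateral displacement", {
  ip <- imaging_params(photons_per_fluorophore = 5, background_photons = 1)
  y_true <- px_to_nm(34, 120)          # microtubule two pixels below ...
  frame <- line_frame(500, 7200, y_nm = y_true, ip = ip)
  y_old <- px_to_nm(32, 120)           # ... the previous backbone
  bb_old <- cbind(seq(6, 58, by = 1), 32)
  bb <- refine_backbone(frame, bb_old, search_halfwidth = 5)
  expect_lt(max(abs(bb[, 2] - 34)), 0.5)

  # halfwidth 0 is the identity (up to resampling)
  bb0 <- refine_backbone(frame, bb_old, search_halfwidth = 0)
  expect_equal(bb0[, 2], rep(32, nrow(bb0)))
})

test_that("axial profile samples the backbone and extrapolates over background", {
  ip <- imaging_params(photons_per_fluorophore = 5, background_photons = 1)
  frame <- line_frame(500, 3500, y_nm = px_to_nm(32, 120), ip = ip)
  bb <- cbind(seq(6, 29, by = 1), 32)  # ends at x = 3420 nm, inside the MT
  prof <- axial_profile(frame, bb, n_extrapolate = 12)
  expect_identical(length(prof$values), nrow(bb) + 12L)
  # on-backbone samples equal the pixel row values (integer coordinates)
  expect_equal(prof$values[1:24], frame[32, 6:29])
  # far extrapolated tail sits at the background level
  expect_equal(tail(prof$values, 3), rep(1, 3), tolerance = 0.05)
})

test_that("the dynamic state machine flips once after k_switch misses", {
  gp <- growth_params(v_g_nm_per_s = 10)
  ip <- imaging_params()
  tp <- tracker_params(k_switch = 3, k_refractory = 5)
  bg <- list(mean = 0, sd = 1)
  # flat profile: the end is never detected
  profile <- list(s = 0:60, values = rep(0, 61),
                  points = cbind(0:60, 10))
  ts <- init_track_state(cbind(c(0, 30), c(10, 10)))
  states <- character(8)
  for (i in 1:8) {
    out <- propose_end(profile, ts, gp, ip, tp, bg)
    ts <- out$ts
    states[i] <- ts$dyn_state
    expect_false(out$detected)
  }
  expect_identical(states[1:2], rep("polymerizing", 2))
  expect_identical(states[3], "depolymerizing")        # flip after 3 misses
  # refractory: no flip back before k_refractory frames have passed
  expect_identical(states[4:7], rep("depolymerizing", 4))
  expect_identical(states[8], "polymerizing")
})

test_that("a detected end resets the miss counter (transient dips allowed)", {
  gp <- growth_params(v_g_nm_per_s = 10)
  ip <- imaging_params()
  tp <- tracker_params(k_switch = 3)
  bg <- list(mean = 0, sd = 1)
  bright <- list(s = 0:60, values = c(rep(10, 50), rep(0, 11)),
                 points = cbind(0:60, 10))
  dark <- list(s = 0:60, values = rep(0, 61), points = cbind(0:60, 10))
  ts <- init_track_state(cbind(c(0, 45), c(10, 10)))
  for (i in 1:2) ts <- propose_end(dark, ts, gp, ip, tp, bg)$ts  # 2 misses
  out <- propose_end(bright, ts, gp, ip, tp, bg)
  expect_true(out$detected)
  expect_identical(out$ts$miss_count, 0L)
  expect_identical(out$ts$dyn_state, "polymerizing")
})

test_that("masks are connected dilated ribbons of monotone area", {
  bb <- cbind(5:25, 10)
  m2 <- build_mask(c(32, 32), bb, dilation_radius = 2)
  expect_identical(sum(m2[, 15]), 5L)  # 5-px-wide ribbon
  m3 <- build_mask(c(32, 32), bb, dilation_radius = 3)
  expect_gt(sum(m3), sum(m2))

  # a 1-px gap in the rasterised backbone closes into one component
  bb_gap <- cbind(c(5:14, 16:25), 10)
  mg <- build_mask(c(32, 32), bb_gap, dilation_radius = 1)
  lab <- EBImage::bwlabel(mg)
  expect_equal(max(lab), 1)
})

test_that("noiseless movies track to within a few nm and use raw counts", {
  cfg <- clean_config(v_g_nm_per_s = 25)
  movie <- simulate_movie(cfg, seed = 31, noise = FALSE)
  track <- track_movie(movie)
  expect_identical(nrow(track$tracks), 10L)
  expect_equal(track$fraction_tracked, 1)
  err <- project_errors(track, movie$truth, n_boot = 20)
  expect_lt(abs(err$axial_offset) + err$axial_precision, 5)
  # the fit consumed raw detector counts, not Wallis-normalised values:
  # its background estimate must sit at the camera offset + background level
  bg_raw <- cfg$imaging$camera_offset +
    cfg$imaging$gain * cfg$imaging$background_photons
  expect_equal(median(track$tracks$background), bg_raw, tolerance = 0.05)
})
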
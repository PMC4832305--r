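# Shared fixtures: small deterministic configurations and rendered frames
# built in code at test time.

# configuration helpers that merge defaults with per-test overrides
config_with <- function(defaults, overrides) {
  for (k in names(overrides)) defaults[[k]] <- overrides[[k]]
  do.call(mt_config, defaults)
}

# fast baseline configuration for short test movies
test_config <- function(...) {
  config_with(list(n_frames = 10L), list(...))
}

# a clean, fully deterministic configuration: no noise sources at all
clean_config <- function(...) {
  config_with(list(n_frames = 10L, labelling_ratio = 1, exposure_s = 0,
                   d_p_nm2_per_s = 0, sigma_ld_nm = 0, taper_length_nm = 0),
              list(...))
}

# render a single noiseless frame of a straight horizontal microtubule
# spanning x in [x0, x1] nm at row y_nm, on a blank background
line_frame <- function(x0 = 500, x1 = 4000, y_nm = 3840, spacing = 8 / 13,
                       ip = imaging_params(), width_px = 64, height_px = 64,
                       weight = 1) {
  coords <- data.frame(x = seq(x0, x1, by = spacing), y = y_nm)
  coords$weight <- weight
  render_expected(coords, ip, width_px, height_px)
}

# pooled axial/lateral errors from tracking one simulated movie
track_errors <- function(cfg, seed, noise = TRUE, snr_target = NULL) {
  movie <- simulate_movie(cfg, seed = seed, noise = noise,
                          snr_target = snr_target)
  track <- track_movie(movie)
  list(movie = movie, track = track,
       err = project_errors(track, movie$truth, n_boot = 50, seed = seed))
}
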
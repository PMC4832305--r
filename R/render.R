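# Model-convolution rendering: labelled-subunit coordinates -> expected
# photon image -> Poisson/EMCCD detector counts, plus the end-to-end movie
# simulator and SNR calibration.

#' Render the expected (noiseless) photon image
#'
#' Each fluorophore contributes a unit-peak isotropic 2D Gaussian of width
#' `sigma_psf_nm`, point-sampled at pixel centres (no area integration),
#' scaled by `photons_per_fluorophore` and its exposure weight, on top of a
#' uniform background. The Gaussian is separable, so the image is formed by
#' two dense matrix products.
#'
#' @param coords data frame with `x`, `y` (nm, image frame) and optionally
#'   `weight` (defaults to 1).
#' @param ip [imaging_params()].
#' @param width_px,height_px frame size.
#' @return numeric `height_px x width_px` matrix of expected photons/pixel.
#' @export
render_expected <- function(coords, ip, width_px, height_px) {
  img <- matrix(ip$background_photons, nrow = height_px, ncol = width_px)
  if (!nrow(coords)) return(img)
  w <- if (is.null(coords$weight)) rep(1, nrow(coords)) else coords$weight
  keep <- w > 0
  if (!any(keep)) return(img)
  x <- coords$x[keep]; y <- coords$y[keep]; w <- w[keep]
  a <- ip$pixel_size_nm
  s2 <- 2 * ip$sigma_psf_nm^2
  xc <- px_to_nm(seq_len(width_px), a)
  yc <- px_to_nm(seq_len(height_px), a)
  gx <- exp(-outer(xc, x, "-")^2 / s2)      # width_px x n
  gy <- exp(-outer(yc, y, "-")^2 / s2)      # height_px x n
  img + ip$photons_per_fluorophore * (gy %*% (w * t(gx)))
}

#' Exposure weights for subunits present during part of the exposure
#'
#' The camera integrates over the window `[frame_end - exposure, frame_end]`.
#' A subunit's weight is the fraction of that window during which it was part
#' of the lattice; subunits present throughout get 1. The simulator spreads
#' the `N` subunits gained in a frame evenly across the frame interval, so
#' with exposure equal to the frame interval the `K` subunits added during
#' the exposure receive weights `(K + 1 - j) / (K + 1)` in order of addition.
#' `exposure_s = 0` means an instantaneous end-of-frame snapshot (weight 1
#' for everything present at `frame_end`).
#'
#' @param entry_times incorporation times (s); `-Inf` for pre-existing.
#' @param frame_end end-of-frame time (s).
#' @param exposure_s exposure duration (s).
#' @param removal_times optional removal times (s); `Inf` if still present.
#' @return numeric weights in `[0, 1]`.
#' @export
exposure_weights <- function(entry_times, frame_end, exposure_s,
                             removal_times = Inf) {
  removal_times <- rep_len(removal_times, length(entry_times))
  if (exposure_s <= 0)
    return(as.numeric(entry_times <= frame_end & removal_times > frame_end))
  t0 <- frame_end - exposure_s
  ov <- (pmin(removal_times, frame_end) - pmax(entry_times, t0)) / exposure_s
  pmin(pmax(ov, 0), 1)
}

#' Apply detector noise to an expected photon image
#'
#' Photon arrivals are Poisson with variance equal to the mean; the sample is
#' multiplied by the camera gain, added to the constant offset and
#' integerized. Electron-multiplication excess noise is not simulated
#' per-pixel (it enters only the localization-precision theory as a factor
#' 1.4); read noise is a constant offset.
#'
#' @param mean_image expected photons/pixel (non-negative matrix).
#' @param ip [imaging_params()].
#' @param seed optional RNG seed.
#' @return integer-valued matrix of detector counts, clipped to 16 bits.
#' @export
add_noise <- function(mean_image, ip, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(mean_image >= 0))
  counts <- stats::rpois(length(mean_image), mean_image) * ip$gain +
    ip$camera_offset
  m <- matrix(round(counts), nrow = nrow(mean_image))
  m[m > 65535] <- 65535
  m
}

# expected photon image for one simulation step: present labelled subunits
# (with partial weights for those added during the exposure) plus labelled
# subunits removed during the exposure, bent, rotated and translated.
render_frame_state <- function(state, removed, deflection_nm, cfg) {
  lp <- cfg$lattice; gp <- cfg$growth; geo <- cfg$geometry
  coords <- place_subunits(state, lp, which = "labelled")
  coords$removal_time <- Inf
  if (nrow(removed)) {
    rem <- removed[removed$labelled, , drop = FALSE]
    if (nrow(rem)) {
      theta <- 2 * pi * (rem$pf - 1) / lp$n_protofilaments
      rem_coords <- data.frame(x = subunit_axial(rem$idx, rem$pf, lp),
                               y = lp$lattice_radius_nm * sin(theta),
                               pf = rem$pf, idx = rem$idx, labelled = TRUE,
                               entry_time = rem$entry_time,
                               removal_time = rem$removal_time)
      coords <- rbind(coords, rem_coords)
    }
  }
  coords$weight <- exposure_weights(coords$entry_time, state$time,
                                    gp$exposure_s, coords$removal_time)
  tip_x <- max(pf_tip_axial(state, lp))
  coords <- apply_thermal_deflection(coords, gp, geo$clamp_length_nm,
                                     tip_x_nm = tip_x,
                                     deflection_nm = deflection_nm)
  coords <- to_image_frame(coords, geo$axis_angle_rad, geo$seed_origin_nm)
  render_expected(coords, cfg$imaging, geo$width_px, geo$height_px)
}

#' Simulate a dynamic-microtubule movie with ground truth
#'
#' Runs the full pipeline per frame: stochastic lattice growth, thermal
#' bending with an independently resampled tip deflection, exposure-weighted
#' model-convolution rendering, and (optionally) Poisson/EMCCD noise. Frame
#' `f` shows the lattice during the exposure window ending at `f * dt`; the
#' ground truth is recorded at the end-of-frame state.
#'
#' @param cfg [mt_config()].
#' @param seed RNG seed for the whole movie (defaults to `cfg$seed`).
#' @param noise simulate detector noise (`FALSE` gives noiseless images on
#'   the detector count scale, for infinite-SNR runs).
#' @param snr_target if non-`NULL`, calibrate an illumination scale factor
#'   (signal and background photons together) by bisection so the measured
#'   first-frame SNR hits this value.
#' @return an object of class `mt_movie`: list with `frames` (list of count
#'   matrices), `truth` (data frame: `frame`, `true_x_nm`, `true_y_nm`,
#'   `length_nm`, `sigma_pf_nm`, `state`, `deflection_nm`), `cfg`, `seed`,
#'   `photon_scale`, `snr_first`.
#' @export
simulate_movie <- function(cfg, seed = cfg$seed, noise = TRUE,
                           snr_target = NULL) {
  stopifnot(inherits(cfg, "mt_config"))
  if (!is.null(snr_target)) {
    scale <- calibrate_photon_scale(cfg, snr_target, seed = seed)
    cfg$imaging$photons_per_fluorophore <-
      cfg$imaging$photons_per_fluorophore * scale
    cfg$imaging$background_photons <- cfg$imaging$background_photons * scale
  } else scale <- 1
  lp <- cfg$lattice; gp <- cfg$growth; geo <- cfg$geometry
  set.seed(seed)
  state <- new_lattice(lp, geo$initial_length_nm, gp$taper_length_nm,
                       seed_length_nm = geo$clamp_length_nm)
  frames <- vector("list", geo$n_frames)
  truth <- vector("list", geo$n_frames)
  prev_len <- geo$initial_length_nm
  for (f in seq_len(geo$n_frames)) {
    stepped <- step_growth(state, gp, lp)
    state <- stepped$state
    defl <- if (gp$sigma_ld_nm > 0) stats::rnorm(1, 0, gp$sigma_ld_nm) else 0
    mean_img <- render_frame_state(state, stepped$removed, defl, cfg)
    frames[[f]] <- if (noise) add_noise(mean_img, cfg$imaging) else
      mean_img * cfg$imaging$gain + cfg$imaging$camera_offset
    te <- true_end(state, lp, gp, geo$clamp_length_nm, defl)
    end_img <- to_image_frame(data.frame(x = te$end[1], y = te$end[2]),
                              geo$axis_angle_rad, geo$seed_origin_nm)
    truth[[f]] <- data.frame(
      frame = f, true_x_nm = end_img$x, true_y_nm = end_img$y,
      length_nm = te$length_nm, sigma_pf_nm = te$sigma_pf_nm,
      state = if (te$length_nm >= prev_len) "polymerizing" else
        "depolymerizing",
      deflection_nm = defl)
    prev_len <- te$length_nm
  }
  movie <- structure(list(frames = frames, truth = do.call(rbind, truth),
                          cfg = cfg, seed = seed, photon_scale = scale,
                          snr_first = NA_real_),
                     class = "mt_movie")
  movie$snr_first <- tryCatch(movie_first_frame_snr(movie),
                              error = function(e) NA_real_)
  movie
}

# nominal backbone of a movie (nm polyline in the image frame), from the
# configured geometry and the recorded ground truth of frame `f`.
nominal_backbone_nm <- function(movie, f = 1) {
  geo <- movie$cfg$geometry
  tr <- movie$truth[f, ]
  end <- c(tr$true_x_nm, tr$true_y_nm)
  tvec <- c(cos(geo$axis_angle_rad), sin(geo$axis_angle_rad))
  len <- sqrt(sum((end - geo$seed_origin_nm)^2))
  s <- seq(0, len, length.out = max(2, ceiling(len / 100)))
  cbind(geo$seed_origin_nm[1] + s * tvec[1],
        geo$seed_origin_nm[2] + s * tvec[2])
}

# first-frame SNR of a movie, measured with the standard two-box method on
# the nominal backbone; the background box is placed on both perpendicular
# sides and the two estimates averaged (halves the background-statistics
# noise of the single-frame estimate).
movie_first_frame_snr <- function(movie) {
  tr <- movie$truth[1, ]
  vals <- c()
  for (side in c(1000, -1000)) {
    v <- tryCatch(
      measure_snr(movie$frames[[1]], movie$cfg$imaging,
                  nominal_backbone_nm(movie, 1),
                  c(tr$true_x_nm, tr$true_y_nm), bk_offset_nm = side),
      error = function(e) NA_real_)
    vals <- c(vals, v)
  }
  if (all(is.na(vals))) stop("no valid background box placement")
  mean(vals, na.rm = TRUE)
}

#' Calibrate the illumination scale for a target first-frame SNR
#'
#' Renders the first frame of the configured movie at a trial illumination
#' scale (photons per fluorophore and background scaled together), adds
#' noise, measures the two-box SNR, and bisects the scale until the measured
#' SNR matches `snr_target`. The growth realisation and the noise draw are
#' held fixed across trials so the objective is monotone.
#'
#' @param cfg [mt_config()].
#' @param snr_target desired first-frame SNR.
#' @param seed RNG seed (growth uses `seed`, noise a derived stream).
#' @param tol absolute SNR tolerance.
#' @param max_iter bisection iterations.
#' @return the scale factor.
#' @export
calibrate_photon_scale <- function(cfg, snr_target, seed = cfg$seed,
                                   tol = 0.02, max_iter = 60) {
  lp <- cfg$lattice; gp <- cfg$growth; geo <- cfg$geometry
  set.seed(seed)
  state <- new_lattice(lp, geo$initial_length_nm, gp$taper_length_nm,
                       seed_length_nm = geo$clamp_length_nm)
  stepped <- step_growth(state, gp, lp)
  state <- stepped$state
  defl <- if (gp$sigma_ld_nm > 0) stats::rnorm(1, 0, gp$sigma_ld_nm) else 0
  te <- true_end(state, lp, gp, geo$clamp_length_nm, defl)
  end_img <- to_image_frame(data.frame(x = te$end[1], y = te$end[2]),
                            geo$axis_angle_rad, geo$seed_origin_nm)
  tvec <- c(cos(geo$axis_angle_rad), sin(geo$axis_angle_rad))
  len <- sqrt(sum((c(end_img$x, end_img$y) - geo$seed_origin_nm)^2))
  s <- seq(0, len, length.out = max(2, ceiling(len / 100)))
  backbone <- cbind(geo$seed_origin_nm[1] + s * tvec[1],
                    geo$seed_origin_nm[2] + s * tvec[2])
  # expected SNR at a trial scale: the single-frame two-box estimate is
  # noisy (few independent patches per box), so average over several fixed
  # noise realizations to get a smooth, monotone objective.
  snr_at <- function(scale, n_rep = 8) {
    ip <- cfg$imaging
    ip$photons_per_fluorophore <- ip$photons_per_fluorophore * scale
    ip$background_photons <- ip$background_photons * scale
    cfg2 <- cfg; cfg2$imaging <- ip
    mean_img <- render_frame_state(state, stepped$removed, defl, cfg2)
    vals <- vapply(seq_len(n_rep), function(r) {
      frame <- add_noise(mean_img, ip, seed = seed + 7919L * r)
      if (any(frame >= 65535)) return(Inf)   # saturated: too bright
      v <- measure_snr(frame, ip, backbone, c(end_img$x, end_img$y))
      if (!is.finite(v)) 0 else v            # blank frame: too dim
    }, 0)
    mean(vals)
  }
  lo <- 1e-4; hi <- 1e4
  if (snr_at(lo) > snr_target || snr_at(hi) < snr_target)
    stop("snr_target outside the calibratable range")
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    v <- snr_at(mid)
    if (abs(v - snr_target) < tol) return(mid)
    if (v < snr_target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' @export
print.mt_movie <- function(x, ...) {
  geo <- x$cfg$geometry
  cat("mt_movie:", geo$n_frames, "frames,", geo$height_px, "x", geo$width_px,
      "px @", x$cfg$imaging$pixel_size_nm, "nm/px\n")
  cat("  first-frame SNR:", format(x$snr_first, digits = 3),
      " photon scale:", format(x$photon_scale, digits = 3),
      " seed:", x$seed, "\n")
  cat("  true length:", format(x$truth$length_nm[1], digits = 5), "->",
      format(x$truth$length_nm[nrow(x$truth)], digits = 5), "nm\n")
  invisible(x)
}

#' @export
plot.mt_movie <- function(x, frame = 1, ...) {
  img <- x$frames[[frame]]
  graphics::image(t(img)[, rev(seq_len(nrow(img)))],
                  col = grDevices::gray.colors(256), asp = nrow(img) / ncol(img),
                  axes = FALSE, main = paste("frame", frame), ...)
  invisible(x)
}
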
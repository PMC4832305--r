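# Error analysis against ground truth and localization-precision theory.

#' Project tracking errors onto the microtubule axis and summarise
#'
#' Per-frame localization errors (tracked minus true end) are rotated into
#' the microtubule's axial/lateral frame; the mean error is the *offset*
#' (accuracy) and the SD the *precision*. Bootstrap standard errors (seeded,
#' percentile form) accompany each summary. `rmse` is the root mean squared
#' axial error over the frames used.
#'
#' @param track an `mt_track` (or its `tracks` data frame).
#' @param truth ground-truth data frame with `frame`, `true_x_nm`,
#'   `true_y_nm` (an `mt_movie$truth`).
#' @param axis_angle_rad microtubule axis orientation; defaults to the
#'   tracking configuration's geometry.
#' @param reliable_only use only frames with a reliable fit (default TRUE).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an object of class `mt_errors`.
#' @export
project_errors <- function(track, truth, axis_angle_rad = NULL,
                           reliable_only = TRUE, n_boot = 1000, seed = 1) {
  if (inherits(track, "mt_track")) {
    if (is.null(axis_angle_rad))
      axis_angle_rad <- track$cfg$geometry$axis_angle_rad
    track <- track$tracks
  }
  if (inherits(truth, "mt_movie")) truth <- truth$truth
  stopifnot(!is.null(axis_angle_rad))
  m <- merge(track, truth, by = "frame")
  if (!nrow(m)) stop("no overlapping frames between track and truth")
  if (reliable_only) m <- m[m$reliability & !is.na(m$end_x_nm), , drop = FALSE]
  if (!nrow(m)) stop("no reliable frames to evaluate")
  ex <- m$end_x_nm - m$true_x_nm
  ey <- m$end_y_nm - m$true_y_nm
  ca <- cos(axis_angle_rad); sa <- sin(axis_angle_rad)
  axial <- ex * ca + ey * sa
  lateral <- -ex * sa + ey * ca
  set.seed(seed)
  boot <- function(v, f) {
    idx <- matrix(sample.int(length(v), length(v) * n_boot, replace = TRUE),
                  ncol = n_boot)
    stats::sd(apply(idx, 2, function(i) f(v[i])))
  }
  structure(list(
    axial_offset = mean(axial), lateral_offset = mean(lateral),
    axial_precision = stats::sd(axial), lateral_precision = stats::sd(lateral),
    rmse = sqrt(mean(axial^2)), n_frames = nrow(m),
    se = c(axial_offset = boot(axial, mean),
           lateral_offset = boot(lateral, mean),
           axial_precision = boot(axial, stats::sd),
           lateral_precision = boot(lateral, stats::sd)),
    errors = data.frame(frame = m$frame, axial_nm = axial,
                        lateral_nm = lateral)),
    class = "mt_errors")
}

#' @export
print.mt_errors <- function(x, ...) {
  cat("mt_errors over", x$n_frames, "frames (nm):\n")
  cat(sprintf("  axial   offset %7.2f +/- %.2f   precision %7.2f +/- %.2f\n",
              x$axial_offset, x$se[["axial_offset"]],
              x$axial_precision, x$se[["axial_precision"]]))
  cat(sprintf("  lateral offset %7.2f +/- %.2f   precision %7.2f +/- %.2f\n",
              x$lateral_offset, x$se[["lateral_offset"]],
              x$lateral_precision, x$se[["lateral_precision"]]))
  cat(sprintf("  axial rmse %7.2f\n", x$rmse))
  invisible(x)
}

#' @export
plot.mt_errors <- function(x, ...) {
  graphics::plot(x$errors$axial_nm, x$errors$lateral_nm,
                 xlab = "axial error (nm)", ylab = "lateral error (nm)", ...)
  graphics::abline(h = 0, v = 0, col = "grey")
  invisible(x)
}

#' Single-emitter localization precision (Thompson theory)
#'
#' `sigma^2 = (s^2 + a^2/12) / N_eff + 8 pi s^4 b^2 / (a^2 N_eff^2)` with
#' `N_eff = N / excess_factor^2`: PSF width `s`, pixel size `a`, detected
#' photons `N`, background noise `b` per pixel, and EMCCD
#' electron-multiplication excess noise folded in as an effective-photon
#' reduction (factor 1.4 by default).
#'
#' @param sigma_psf_nm PSF sigma `s` (nm).
#' @param pixel_size_nm pixel size `a` (nm).
#' @param photons detected photon number `N` (> 0).
#' @param background_sd background noise `b` (photons per pixel).
#' @param excess_factor EMCCD multiplicative noise factor.
#' @return predicted localization precision (nm).
#' @export
thompson_precision <- function(sigma_psf_nm, pixel_size_nm, photons,
                               background_sd = 0, excess_factor = 1.4) {
  n_eff <- photons / excess_factor^2
  if (any(n_eff <= 0)) stop("effective photon number must be positive")
  s <- sigma_psf_nm; a <- pixel_size_nm
  sqrt((s^2 + a^2 / 12) / n_eff +
         8 * pi * s^4 * background_sd^2 / (a^2 * n_eff^2))
}

#' Precision of an end-aligned average image
#'
#' Averaging `n` images aligned on the tracked end position yields a
#' localization precision `sqrt(sigma_track^2 + sigma_PSF^2) / sqrt(n)`
#' (standard deviation of the sample mean).
#'
#' @param sigma_track_nm tracking precision (nm).
#' @param sigma_psf_nm PSF sigma of the averaged channel (nm).
#' @param n_images number of images averaged (>= 1).
#' @return precision of the average (nm).
#' @export
averaging_precision <- function(sigma_track_nm, sigma_psf_nm, n_images) {
  stopifnot(all(n_images >= 1))
  sqrt(sigma_track_nm^2 + sigma_psf_nm^2) / sqrt(n_images)
}

#' @rdname averaging_precision
#' @param target_nm desired precision of the average image (nm).
#' @return `averaging_images_needed`: the (real-valued) number of images for
#'   which the averaged precision reaches `target_nm`.
#' @export
averaging_images_needed <- function(target_nm, sigma_track_nm, sigma_psf_nm) {
  (sigma_track_nm^2 + sigma_psf_nm^2) / target_nm^2
}

#' Run a simulate-track-evaluate parameter sweep
#'
#' Takes a data frame of conditions (columns are flat [mt_config()] override
#' keys, plus optional `snr_target`, `noise`, `seed`, `n_boot`), runs each
#' through the full pipeline and returns one tidy row per condition with the
#' measured first-frame SNR, offsets, precisions, bootstrap SEs and tracked
#' fraction. Per-condition failures are recorded as NA rows, not errors.
#'
#' @param conditions data frame of conditions. An `n_seeds` column pools
#'   per-frame errors over that many independently seeded microtubules of
#'   the same condition.
#' @param base_cfg baseline [mt_config()] the overrides are applied to.
#' @param seed base RNG seed; condition `i` without its own `seed` column
#'   uses `seed + i`.
#' @param n_boot bootstrap resamples for the error summaries.
#' @return data frame: the condition columns plus `snr_first`,
#'   `axial_offset`, `lateral_offset`, `axial_precision`,
#'   `lateral_precision`, `rmse`, `se_*`, `fraction_tracked`, and
#'   `n_pooled` (total frames pooled across seeds).
#' @export
sweep_runner <- function(conditions, base_cfg = mt_config(), seed = 1,
                         n_boot = 200) {
  out <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    cond <- conditions[i, , drop = FALSE]
    res <- tryCatch({
      run_condition(cond, base_cfg,
                    seed = if ("seed" %in% names(cond)) cond$seed else
                      seed + i,
                    n_boot = n_boot)
    }, error = function(e) {
      data.frame(snr_first = NA_real_, axial_offset = NA_real_,
                 lateral_offset = NA_real_, axial_precision = NA_real_,
                 lateral_precision = NA_real_, rmse = NA_real_,
                 se_axial_offset = NA_real_, se_axial_precision = NA_real_,
                 fraction_tracked = NA_real_, n_pooled = NA_integer_,
                 error = conditionMessage(e))
    })
    if (is.null(res$error)) res$error <- NA_character_
    out[[i]] <- cbind(cond, res, row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

run_condition <- function(cond, base_cfg, seed, n_boot) {
  overrides <- as.list(cond)
  overrides$snr_target <- NULL; overrides$noise <- NULL
  overrides$seed <- NULL; overrides$label <- NULL
  overrides$varied <- NULL; overrides$n_boot <- NULL
  overrides$n_seeds <- NULL
  cfg <- do.call(mt_config, c(list(lattice = base_cfg$lattice,
                                   growth = base_cfg$growth,
                                   imaging = base_cfg$imaging,
                                   tracker = base_cfg$tracker,
                                   geometry = base_cfg$geometry,
                                   seed = seed), overrides))
  noise <- if ("noise" %in% names(cond)) isTRUE(cond$noise) else TRUE
  snr_target <- if ("snr_target" %in% names(cond) &&
                    is.finite(cond$snr_target)) cond$snr_target else NULL
  n_seeds <- if ("n_seeds" %in% names(cond)) cond$n_seeds else 1L
  # pool per-frame errors over independent microtubules of this condition
  ax <- lat <- c(); snr1 <- NA_real_; tracked <- 0; total <- 0
  for (r in seq_len(n_seeds)) {
    seed_r <- seed + 1000L * (r - 1L)
    movie <- simulate_movie(cfg, seed = seed_r, noise = noise,
                            snr_target = snr_target)
    if (r == 1L) snr1 <- movie$snr_first
    track <- track_movie(movie)
    err <- project_errors(track, movie$truth, n_boot = 2, seed = seed_r + 1L)
    ax <- c(ax, err$errors$axial_nm)
    lat <- c(lat, err$errors$lateral_nm)
    tracked <- tracked + track$fraction_tracked
    total <- total + 1
  }
  set.seed(seed + 7L)
  boot <- function(v, f) {
    idx <- matrix(sample.int(length(v), length(v) * n_boot, replace = TRUE),
                  ncol = n_boot)
    stats::sd(apply(idx, 2, function(i) f(v[i])))
  }
  data.frame(snr_first = snr1,
             axial_offset = mean(ax),
             lateral_offset = mean(lat),
             axial_precision = stats::sd(ax),
             lateral_precision = stats::sd(lat),
             rmse = sqrt(mean(ax^2)),
             se_axial_offset = boot(ax, mean),
             se_axial_precision = boot(ax, stats::sd),
             fraction_tracked = tracked / total,
             n_pooled = length(ax))
}

#' Standard imaging-parameter sweep conditions
#'
#' Builds the mixed sweep used to characterize tracking performance against
#' the signal-to-noise ratio: labelling ratio, exposure time, pixel size and
#' illumination intensity are varied one at a time around the baseline
#' (labelling ratio 0.2, exposure 200 ms, pixel 120 nm). Photon budgets
#' follow the physics of each knob: signal and background scale with
#' exposure, illumination and pixel area (constant irradiance), and the
#' background additionally scales linearly with labelling ratio (free
#' labelled tubulin).
#'
#' @param scale illumination scale applied to the baseline photon budget
#'   (for example from [calibrate_photon_scale()]).
#' @param n_frames frames per condition.
#' @param ip baseline [imaging_params()].
#' @return data frame of flat configuration overrides, one row per
#'   condition, with a `varied` label column.
#' @export
imaging_sweep_conditions <- function(scale = 1, n_frames = 100L,
                                     ip = imaging_params()) {
  p0 <- ip$photons_per_fluorophore * scale
  b0 <- ip$background_photons * scale
  rows <- list()
  add <- function(varied, lr = 0.2, exposure = 0.2, pixel = 120,
                  intensity = 1, width = 64L) {
    rows[[length(rows) + 1L]] <<- data.frame(
      varied = varied, labelling_ratio = lr, exposure_s = exposure,
      pixel_size_nm = pixel,
      photons_per_fluorophore = p0 * intensity * (exposure / 0.2) *
        (pixel / 120)^2,
      background_photons = b0 * intensity * (exposure / 0.2) *
        (lr / 0.2) * (pixel / 120)^2,
      width_px = width, height_px = width, n_frames = n_frames)
  }
  for (lr in c(0.1, 0.15, 0.2, 0.5, 1)) add("labelling_ratio", lr = lr)
  for (ex in c(0.1, 0.15, 0.3, 0.4)) add("exposure", exposure = ex)
  for (px in c(75, 100, 140)) add("pixel_size", pixel = px,
                                  width = if (px < 100) 80L else 64L)
  for (it in c(0.4, 1.5, 2.5)) add("intensity", intensity = it)
  do.call(rbind, rows)
}
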
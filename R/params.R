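# Parameter containers and configuration IO.
#
# Every run of the simulator / tracker is described by one flat configuration:
# lattice geometry, growth dynamics, imaging/detector settings, tracker and
# fit settings, movie geometry, and the RNG seed. Defaults are the baseline
# imaging conditions used throughout the characterization: labelling ratio
# 0.2, exposure 200 ms, pixel size 120 nm, PSF sigma 135 nm, growth speed
# 11 nm/s, tip diffusion 271 nm^2/s, lateral deflection SD 150 nm and taper
# length 96 nm.

#' Microtubule lattice geometry parameters
#'
#' @param n_protofilaments number of protofilaments (13 for the canonical
#'   B lattice).
#' @param subunit_length_nm axial length of one alpha-beta tubulin subunit
#'   (8 nm).
#' @param lattice_radius_nm cylinder radius used when projecting subunit
#'   positions into the image plane. The canonical outer diameter is 25 nm;
#'   the default radius is therefore 12.5 nm, configurable.
#' @param helix_start number of helix starts (3-start B lattice).
#' @param labelling_ratio probability that a newly incorporated subunit
#'   carries a fluorophore.
#' @return an object of class `lattice_params`.
#' @export
lattice_params <- function(n_protofilaments = 13L,
                           subunit_length_nm = 8,
                           lattice_radius_nm = 12.5,
                           helix_start = 3L,
                           labelling_ratio = 0.2) {
  stopifnot(n_protofilaments >= 1, subunit_length_nm > 0,
            labelling_ratio >= 0, labelling_ratio <= 1,
            lattice_radius_nm >= 0, helix_start >= 1)
  structure(list(n_protofilaments = as.integer(n_protofilaments),
                 subunit_length_nm = subunit_length_nm,
                 lattice_radius_nm = lattice_radius_nm,
                 helix_start = as.integer(helix_start),
                 labelling_ratio = labelling_ratio),
            class = "lattice_params")
}

#' Growth dynamics parameters
#'
#' @param v_g_nm_per_s mean growth speed (nm/s); negative values mean net
#'   depolymerization.
#' @param d_p_nm2_per_s effective diffusion coefficient of the tip position
#'   about its mean trajectory (nm^2/s), i.e. the growth-speed fluctuations.
#' @param sigma_ld_nm SD of the thermally driven lateral tip deflection (nm).
#' @param taper_length_nm axial extent of the linear protofilament-length
#'   ramp maintained at the tip (nm).
#' @param frame_interval_s time between successive frames (s).
#' @param exposure_s camera exposure per frame (s); 0 means an instantaneous
#'   snapshot. Must not exceed `frame_interval_s`.
#' @return an object of class `growth_params`.
#' @export
growth_params <- function(v_g_nm_per_s = 11,
                          d_p_nm2_per_s = 271,
                          sigma_ld_nm = 150,
                          taper_length_nm = 96,
                          frame_interval_s = 0.5,
                          exposure_s = 0.2) {
  stopifnot(d_p_nm2_per_s >= 0, sigma_ld_nm >= 0, taper_length_nm >= 0,
            frame_interval_s > 0, exposure_s >= 0,
            exposure_s <= frame_interval_s)
  structure(list(v_g_nm_per_s = v_g_nm_per_s,
                 d_p_nm2_per_s = d_p_nm2_per_s,
                 sigma_ld_nm = sigma_ld_nm,
                 taper_length_nm = taper_length_nm,
                 frame_interval_s = frame_interval_s,
                 exposure_s = exposure_s),
            class = "growth_params")
}

#' Imaging and detector parameters
#'
#' @param pixel_size_nm detector pixel size in sample space (nm).
#' @param sigma_psf_nm Gaussian approximation to the microscope PSF (nm).
#' @param photons_per_fluorophore expected peak photon contribution of one
#'   labelled subunit per full exposure.
#' @param background_photons expected background photons per pixel per
#'   exposure (free labelled tubulin).
#' @param gain detector counts per photon.
#' @param camera_offset constant detector baseline (counts).
#' @return an object of class `imaging_params`.
#' @export
imaging_params <- function(pixel_size_nm = 120,
                           sigma_psf_nm = 135,
                           photons_per_fluorophore = 0.05,
                           background_photons = 3,
                           gain = 4,
                           camera_offset = 100) {
  stopifnot(pixel_size_nm > 0, sigma_psf_nm > 0,
            photons_per_fluorophore >= 0, background_photons >= 0,
            gain > 0, camera_offset >= 0)
  structure(list(pixel_size_nm = pixel_size_nm,
                 sigma_psf_nm = sigma_psf_nm,
                 photons_per_fluorophore = photons_per_fluorophore,
                 background_photons = background_photons,
                 gain = gain,
                 camera_offset = camera_offset),
            class = "imaging_params")
}

#' Tracker and fit parameters
#'
#' @param wiener_window_px Wiener pre-filter window (odd, pixels).
#' @param wallis_window_px Wallis local-normalisation window (odd, pixels).
#' @param smooth_window_px averaging filter window used before backbone
#'   refinement (odd, pixels).
#' @param wallis_gain_limit cap on the Wallis contrast gain.
#' @param search_halfwidth_px perpendicular search half-width for backbone
#'   refinement (pixels).
#' @param k_switch consecutive missed detections before the dynamic state
#'   flips between polymerization and depolymerization.
#' @param k_refractory minimum frames between two state flips.
#' @param detect_nsd detection threshold: the proposed end intensity must
#'   exceed background mean + `detect_nsd` background SDs.
#' @param dilation_radius_px dilation radius of the binary mask (pixels).
#' @param fit_window_sigmas half-width of the fit window around the proposed
#'   end, in units of `sigma_psf_nm`.
#' @param variant `"wall"` (sigma_end tied to sigma) or `"free_sigma_end"`.
#' @param r2_min minimum coefficient of determination for a reliable fit.
#' @return an object of class `tracker_params`.
#' @export
tracker_params <- function(wiener_window_px = 5L,
                           wallis_window_px = 15L,
                           smooth_window_px = 3L,
                           wallis_gain_limit = 5,
                           search_halfwidth_px = 5L,
                           k_switch = 3L,
                           k_refractory = 5L,
                           detect_nsd = 2,
                           dilation_radius_px = 3L,
                           fit_window_sigmas = 6,
                           variant = c("wall", "free_sigma_end"),
                           r2_min = 0.2) {
  variant <- match.arg(variant)
  stopifnot(wiener_window_px %% 2 == 1, wallis_window_px %% 2 == 1,
            smooth_window_px %% 2 == 1, k_switch >= 1, k_refractory >= 0,
            dilation_radius_px >= 1, fit_window_sigmas > 0)
  structure(list(wiener_window_px = as.integer(wiener_window_px),
                 wallis_window_px = as.integer(wallis_window_px),
                 smooth_window_px = as.integer(smooth_window_px),
                 wallis_gain_limit = wallis_gain_limit,
                 search_halfwidth_px = as.integer(search_halfwidth_px),
                 k_switch = as.integer(k_switch),
                 k_refractory = as.integer(k_refractory),
                 detect_nsd = detect_nsd,
                 dilation_radius_px = as.integer(dilation_radius_px),
                 fit_window_sigmas = fit_window_sigmas,
                 variant = variant,
                 r2_min = r2_min),
            class = "tracker_params")
}

#' Movie geometry
#'
#' @param width_px,height_px frame size in pixels.
#' @param n_frames number of frames to simulate.
#' @param seed_origin_nm `[x, y]` position of the microtubule seed (minus
#'   end) in nm, image-corner origin.
#' @param axis_angle_rad orientation of the microtubule axis (rad, measured
#'   from the +x axis).
#' @param initial_length_nm microtubule length at frame 0 (nm).
#' @param clamp_length_nm rigid seed region for the cantilever bending model
#'   (nm from the seed origin).
#' @return an object of class `movie_geometry`.
#' @export
movie_geometry <- function(width_px = 64L, height_px = 64L, n_frames = 100L,
                           seed_origin_nm = c(600, 2600),
                           axis_angle_rad = 0.2,
                           initial_length_nm = 3000,
                           clamp_length_nm = 500) {
  stopifnot(width_px >= 8, height_px >= 8, n_frames >= 1,
            initial_length_nm > 0, clamp_length_nm >= 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 n_frames = as.integer(n_frames),
                 seed_origin_nm = as.numeric(seed_origin_nm),
                 axis_angle_rad = axis_angle_rad,
                 initial_length_nm = initial_length_nm,
                 clamp_length_nm = clamp_length_nm),
            class = "movie_geometry")
}

#' Assemble a complete run configuration
#'
#' @param lattice,growth,imaging,tracker,geometry parameter objects (see the
#'   individual constructors); defaults are the baseline conditions.
#' @param seed integer RNG seed for the whole run.
#' @param ... flat key overrides applied to whichever component owns the key,
#'   e.g. `mt_config(labelling_ratio = 1, v_g_nm_per_s = 50)`.
#' @return an object of class `mt_config`.
#' @export
mt_config <- function(lattice = lattice_params(), growth = growth_params(),
                      imaging = imaging_params(), tracker = tracker_params(),
                      geometry = movie_geometry(), seed = 1L, ...) {
  cfg <- list(lattice = lattice, growth = growth, imaging = imaging,
              tracker = tracker, geometry = geometry, seed = as.integer(seed))
  dots <- list(...)
  for (key in names(dots)) {
    hit <- FALSE
    for (comp in c("lattice", "growth", "imaging", "tracker", "geometry")) {
      if (key %in% names(cfg[[comp]])) {
        cfg[[comp]][[key]] <- dots[[key]]
        hit <- TRUE
        break
      }
    }
    if (!hit) stop("unknown configuration key: ", key)
  }
  # re-validate through the constructors
  cfg$lattice <- do.call(lattice_params, unclass(cfg$lattice))
  cfg$growth <- do.call(growth_params, unclass(cfg$growth))
  cfg$imaging <- do.call(imaging_params, unclass(cfg$imaging))
  cfg$tracker <- do.call(tracker_params, unclass(cfg$tracker))
  cfg$geometry <- do.call(movie_geometry, unclass(cfg$geometry))
  structure(cfg, class = "mt_config")
}

#' Read / write a run configuration as flat YAML
#'
#' The file holds one flat key/value mapping (units are part of the key
#' names); `read_config()` reconstructs a validated [mt_config()].
#'
#' @param cfg an `mt_config` object.
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "mt_config"))
  flat <- c(unclass(cfg$lattice), unclass(cfg$growth), unclass(cfg$imaging),
            unclass(cfg$tracker), unclass(cfg$geometry), list(seed = cfg$seed))
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  flat <- yaml::read_yaml(path)
  seed <- if (is.null(flat$seed)) 1L else flat$seed
  flat$seed <- NULL
  if (!is.null(flat$seed_origin_nm)) flat$seed_origin_nm <- as.numeric(flat$seed_origin_nm)
  do.call(mt_config, c(list(seed = seed), flat))
}

#' @export
print.mt_config <- function(x, ...) {
  cat("mtrack run configuration (seed", x$seed, ")\n")
  for (comp in c("lattice", "growth", "imaging", "tracker", "geometry")) {
    vals <- unclass(x[[comp]])
    vals <- vapply(vals, function(v) paste(format(v, digits = 4), collapse = ","), "")
    cat(" ", comp, ": ", paste(names(vals), vals, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
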
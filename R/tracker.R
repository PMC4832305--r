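# Per-frame microtubule identification and rough end proposal: backbone
# refinement on the filtered image, 1D axial profile with extrapolation,
# predictive dynamic model (polymerizing/depolymerizing with hysteresis),
# Gaussian proposed-growth weighting, morphological mask building, and the
# movie-level driver feeding the 2D fit on the raw frames.

#' Initialise a track state from a user-style backbone
#'
#' @param backbone_px 2-column matrix of `[x, y]` pixel coordinates (coarse
#'   clicks are fine; the polyline is densely interpolated at 1 point per
#'   pixel of arclength).
#' @return an object of class `mt_track_state`.
#' @export
init_track_state <- function(backbone_px) {
  stopifnot(is.matrix(backbone_px), nrow(backbone_px) >= 2)
  bb <- resample_polyline(backbone_px, by = 1)
  s <- polyline_arclength(bb)
  structure(list(backbone = bb, dyn_state = "polymerizing",
                 miss_count = 0L, refractory_count = 1000L,
                 consecutive_miss = 0L,
                 last_end_s = s[length(s)],
                 last_end = bb[nrow(bb), ]),
            class = "mt_track_state")
}

# nominal initial backbone of a simulated movie, in pixel coordinates
# (stand-in for the user's mouse clicks along the contour).
#' @rdname init_track_state
#' @param movie an `mt_movie`.
#' @export
initial_backbone <- function(movie) {
  bb_nm <- nominal_backbone_nm(movie, 1)
  nm_to_px(bb_nm, movie$cfg$imaging$pixel_size_nm)
}

#' Refine a backbone against the current (smoothed) frame
#'
#' Each densely interpolated backbone point moves to the intensity argmax
#' along its perpendicular within `+/- search_halfwidth` pixels. The raw
#' per-point displacements are then projected onto a smooth two-mode model -
#' a rigid lateral translation plus the first uniformly loaded cantilever
#' bending mode (clamped at the seed end) - so the refined backbone stays a
#' simple curve: this recovers both image drift and thermal wiggling while
#' suppressing per-point noise. `search_halfwidth = 0` is the identity.
#'
#' @param smoothed_frame filtered/smoothed image matrix.
#' @param backbone_px current backbone (2-column `[x, y]` pixel matrix).
#' @param search_halfwidth perpendicular search half-width (px).
#' @return refined backbone matrix.
#' @export
refine_backbone <- function(smoothed_frame, backbone_px, search_halfwidth = 5) {
  bb <- resample_polyline(backbone_px, by = 1)
  if (search_halfwidth <= 0) return(bb)
  n <- nrow(bb)
  # local tangents
  tn <- rbind(bb[2, ] - bb[1, ],
              bb[c(3:n, n), ] - bb[c(1, 1:(n - 2)), , drop = FALSE])
  tn <- tn / pmax(sqrt(rowSums(tn^2)), 1e-9)
  nv <- cbind(-tn[, 2], tn[, 1])
  offsets <- seq(-search_halfwidth, search_halfwidth, by = 0.5)
  disp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    px <- bb[i, 1] + offsets * nv[i, 1]
    py <- bb[i, 2] + offsets * nv[i, 2]
    vals <- bilinear(smoothed_frame, py, px)
    if (all(is.na(vals))) next
    disp[i] <- offsets[which.max(vals)]
  }
  ok <- !is.na(disp)
  if (sum(ok) >= 4) {
    s <- polyline_arclength(bb)
    mode <- beam_deflection_shape(s / max(s))
    co <- stats::coef(stats::lm(disp[ok] ~ mode[ok]))
    fitted <- co[1] + co[2] * mode
    out <- bb + fitted * nv
  } else out <- bb
  out[, 1] <- pmin(pmax(out[, 1], 1), ncol(smoothed_frame))
  out[, 2] <- pmin(pmax(out[, 2], 1), nrow(smoothed_frame))
  resample_polyline(out, by = 1)
}

#' Axial intensity profile with extrapolation beyond the end
#'
#' Samples the image (bilinear) at the backbone points and at
#' `n_extrapolate` further points continuing along the end tangent;
#' off-frame samples truncate the profile.
#'
#' @param frame image matrix to sample (the filtered frame).
#' @param backbone_px backbone polyline (px).
#' @param n_extrapolate number of 1-px extrapolation steps.
#' @return list with `s` (arclength, px), `values`, `points` (2-col matrix).
#' @export
axial_profile <- function(frame, backbone_px, n_extrapolate = 10) {
  bb <- resample_polyline(backbone_px, by = 1)
  tvec <- end_tangent(bb)
  extra <- if (n_extrapolate > 0)
    sweep(outer(seq_len(n_extrapolate), tvec), 2,
          bb[nrow(bb), ], "+") else NULL
  pts <- rbind(bb, extra)
  vals <- bilinear(frame, pts[, 2], pts[, 1])
  keep <- !is.na(vals)
  if (any(!keep)) {  # truncate at first off-frame sample
    cut <- which(!keep)[1] - 1L
    if (cut < 2) stop("backbone leaves the frame")
    pts <- pts[seq_len(cut), , drop = FALSE]
    vals <- vals[seq_len(cut)]
  }
  list(s = polyline_arclength(pts), values = vals, points = pts)
}

#' Propose a new end position using the predictive dynamic model
#'
#' The expected end advances from the last end by the state-signed mean
#' displacement `v_g * dt`; an approximately Gaussian proposed-growth weight
#' centred there, with width `sqrt(2 D_p dt + w_min^2)` (floor
#' `w_min = 2 sigma_PSF`, so transient depolymerization remains reachable in
#' the polymerizing state), multiplies the intensity profile and the argmax
#' becomes the proposed end. If the profile value there does not exceed
#' `bg_mean + detect_nsd * bg_sd`, the detection is a miss: the last end is
#' carried forward and, after `k_switch` consecutive misses (and at least
#' `k_refractory` frames since the previous flip), the dynamic state flips.
#'
#' @param profile output of [axial_profile()].
#' @param ts an `mt_track_state`.
#' @param gp [growth_params()]; @param ip [imaging_params()].
#' @param tp [tracker_params()].
#' @param bg list with `mean` and `sd` of the background in the profile's
#'   intensity scale.
#' @return list with `ts` (updated state), `proposed_s` (arclength, px),
#'   `proposed_xy` (px), `detected`, `weights`.
#' @export
propose_end <- function(profile, ts, gp, ip, tp, bg) {
  a <- ip$pixel_size_nm
  dt <- gp$frame_interval_s
  sign <- if (ts$dyn_state == "polymerizing") 1 else -1
  centre <- ts$last_end_s + sign * abs(gp$v_g_nm_per_s) * dt / a
  w_min <- 2 * ip$sigma_psf_nm
  width <- sqrt(2 * gp$d_p_nm2_per_s * dt + w_min^2) / a
  wts <- exp(-(profile$s - centre)^2 / (2 * width^2))
  # weight the background-subtracted profile: the background level carries
  # no end information and would otherwise drag the argmax to the weight
  # centre.
  i_star <- which.max((profile$values - bg$mean) * wts)  # ties: first wins
  detected <- profile$values[i_star] > bg$mean + tp$detect_nsd * bg$sd
  ts$refractory_count <- ts$refractory_count + 1L
  if (detected) {
    ts$miss_count <- 0L
    ts$consecutive_miss <- 0L
    proposed_s <- profile$s[i_star]
  } else {
    ts$miss_count <- ts$miss_count + 1L
    ts$consecutive_miss <- ts$consecutive_miss + 1L
    proposed_s <- min(max(centre, 0), profile$s[length(profile$s)])
    if (ts$miss_count >= tp$k_switch &&
        ts$refractory_count >= tp$k_refractory) {
      ts$dyn_state <- if (ts$dyn_state == "polymerizing")
        "depolymerizing" else "polymerizing"
      ts$miss_count <- 0L
      ts$refractory_count <- 0L
    }
  }
  xy <- cbind(stats::approx(profile$s, profile$points[, 1], xout = proposed_s)$y,
              stats::approx(profile$s, profile$points[, 2], xout = proposed_s)$y)
  list(ts = ts, proposed_s = proposed_s, proposed_xy = as.numeric(xy),
       detected = detected, weights = wts)
}

#' Build the binary microtubule mask
#'
#' Rasterises the accepted backbone pixels up to (and including) the
#' proposed-end pixel, dilates with a disc and applies morphological closing,
#' producing a connected ribbon.
#'
#' @param dim frame dimensions `c(nrow, ncol)`.
#' @param backbone_px backbone polyline (px), already truncated at the
#'   proposed end.
#' @param dilation_radius disc radius (px).
#' @return logical matrix.
#' @export
build_mask <- function(dim, backbone_px, dilation_radius = 3) {
  m <- matrix(0, dim[1], dim[2])
  r <- pmin(pmax(round(backbone_px[, 2]), 1), dim[1])
  c <- pmin(pmax(round(backbone_px[, 1]), 1), dim[2])
  m[cbind(r, c)] <- 1
  brush <- EBImage::makeBrush(2 * dilation_radius + 1, shape = "disc")
  m <- EBImage::dilate(m, brush)
  m <- EBImage::closing(m, EBImage::makeBrush(3, shape = "box"))
  m <- as.array(m)
  matrix(m > 0, nrow = dim[1])
}

# arclength of the closest point on a polyline to `pt` (all px units).
project_arclength <- function(xy, pt) {
  s <- polyline_arclength(xy)
  n <- nrow(xy)
  best <- c(Inf, 0)
  for (i in seq_len(n - 1)) {
    d <- xy[i + 1, ] - xy[i, ]
    L2 <- sum(d^2)
    t <- if (L2 > 0) sum((pt - xy[i, ]) * d) / L2 else 0
    t <- min(max(t, 0), 1)
    q <- xy[i, ] + t * d
    dist2 <- sum((pt - q)^2)
    if (dist2 < best[1]) best <- c(dist2, s[i] + t * sqrt(L2))
  }
  best[2]
}

#' Track a movie end-to-end
#'
#' For every frame: Wiener + Wallis filtering, box smoothing, backbone
#' refinement, axial profile, proposed end from the predictive dynamic
#' model, morphological mask, and the 2D wall-end fit on the *raw* frame.
#' Filtered images are used only for segmentation and the proposal.
#'
#' @param movie an `mt_movie`, or a list of frame matrices.
#' @param init_backbone_px initial backbone in px; defaults to the movie's
#'   nominal backbone ([initial_backbone()]).
#' @param cfg [mt_config()]; defaults to the movie's configuration.
#' @return an object of class `mt_track`: `tracks` data frame (one row per
#'   frame), `cfg`, `loss_frame`, `fraction_tracked`.
#' @export
track_movie <- function(movie, init_backbone_px = NULL, cfg = NULL) {
  if (inherits(movie, "mt_movie")) {
    frames <- movie$frames
    if (is.null(cfg)) cfg <- movie$cfg
    if (is.null(init_backbone_px)) init_backbone_px <- initial_backbone(movie)
  } else frames <- movie
  stopifnot(!is.null(cfg), !is.null(init_backbone_px))
  ip <- cfg$imaging; gp <- cfg$growth; tp <- cfg$tracker
  a <- ip$pixel_size_nm
  ts <- init_track_state(init_backbone_px)
  n_extrap <- ceiling((abs(gp$v_g_nm_per_s) * gp$frame_interval_s +
                         3 * sqrt(2 * gp$d_p_nm2_per_s * gp$frame_interval_s) +
                         6 * ip$sigma_psf_nm) / a)
  rows <- vector("list", length(frames))
  loss_frame <- NA_integer_
  for (f in seq_along(frames)) {
    raw <- frames[[f]]
    filt <- prep_frame(raw, tp)
    sm <- smooth_box(filt, tp$smooth_window_px)
    bb <- refine_backbone(sm, ts$backbone, tp$search_halfwidth_px)
    prof <- axial_profile(sm, bb, n_extrapolate = n_extrap)
    bg <- robust_bg(sm)
    prop <- propose_end(prof, ts, gp, ip, tp, bg)
    ts <- prop$ts
    if (ts$consecutive_miss >= 2L * tp$k_switch + tp$k_refractory) {
      loss_frame <- f
      break
    }
    keep <- prof$s <= prop$proposed_s + 1e-9
    bb_to_end <- prof$points[keep, , drop = FALSE]
    if (nrow(bb_to_end) < 2) bb_to_end <- prof$points[1:2, , drop = FALSE]
    mask <- build_mask(dim(raw), bb_to_end, tp$dilation_radius_px)
    fmask <- fit_window_mask(dim(raw), mask, prop$proposed_xy,
                             tp$fit_window_sigmas * ip$sigma_psf_nm / a,
                             exclude_pt = prof$points[1, ],
                             exclude_radius_px = 4 * ip$sigma_psf_nm / a)
    rb <- robust_bg(raw)
    near <- bilinear(raw, prop$proposed_xy[2] - c(2, 0, -2, 0),
                     prop$proposed_xy[1] - c(0, 2, 0, -2))
    init <- list(end_x = px_to_nm(prop$proposed_xy[1], a),
                 end_y = px_to_nm(prop$proposed_xy[2], a),
                 sigma = ip$sigma_psf_nm,
                 amplitude = max(max(near, na.rm = TRUE) - rb$mean,
                                 3 * rb$sd, 1),
                 background = rb$mean,
                 angle = atan2(end_tangent(bb_to_end)[2],
                               end_tangent(bb_to_end)[1]))
    fit <- tryCatch(
      fit_end(raw, fmask, init, ip, variant = tp$variant,
              r2_min = tp$r2_min),
      error = function(e) NULL)
    if (!is.null(fit) && fit$reliability) {
      end_px <- nm_to_px(c(fit$params$end_x, fit$params$end_y), a)
      s_fit <- project_arclength(prof$points, end_px)
      keep2 <- prof$s <= s_fit
      newbb <- prof$points[keep2, , drop = FALSE]
      if (nrow(newbb) >= 2) {
        ts$backbone <- resample_polyline(rbind(newbb, end_px), by = 1)
      }
      s <- polyline_arclength(ts$backbone)
      ts$last_end_s <- s[length(s)]
      ts$last_end <- end_px
    } else {
      # keep proposal as working end; backbone truncated at proposal
      ts$backbone <- resample_polyline(bb_to_end, by = 1)
      s <- polyline_arclength(ts$backbone)
      ts$last_end_s <- s[length(s)]
      ts$last_end <- prop$proposed_xy
    }
    p <- if (!is.null(fit)) fit$params else
      list(end_x = NA, end_y = NA, sigma = NA, sigma_end = NA,
           amplitude = NA, background = NA, angle = NA)
    rows[[f]] <- data.frame(
      frame = f,
      end_x_px = if (!is.null(fit)) nm_to_px(p$end_x, a) else NA,
      end_y_px = if (!is.null(fit)) nm_to_px(p$end_y, a) else NA,
      end_x_nm = p$end_x, end_y_nm = p$end_y,
      sigma_nm = p$sigma, sigma_end_nm = p$sigma_end,
      amplitude = p$amplitude, background = p$background,
      angle_rad = p$angle,
      r2 = if (!is.null(fit)) fit$r2 else NA_real_,
      reliability = if (!is.null(fit)) fit$reliability else FALSE,
      detected = prop$detected,
      dyn_state = ts$dyn_state)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  tracks <- if (length(rows)) do.call(rbind, rows) else NULL
  structure(list(tracks = tracks, cfg = cfg, loss_frame = loss_frame,
                 fraction_tracked = if (is.null(tracks)) 0 else
                   sum(tracks$reliability) / length(frames)),
            class = "mt_track")
}

# union of the square fit window around the proposed end and nearby mask
# pixels (keeps the least-squares loss local, as in the fit design). Pixels
# within `exclude_radius_px` of `exclude_pt` (the seed end of the backbone,
# where the semi-infinite plateau assumption of the wall model breaks down)
# are removed from the loss.
fit_window_mask <- function(dim, mask, end_px, halfwidth_px,
                            exclude_pt = NULL, exclude_radius_px = 0) {
  r <- seq_len(dim[1]); c <- seq_len(dim[2])
  win <- outer(abs(r - end_px[2]) <= halfwidth_px,
               abs(c - end_px[1]) <= halfwidth_px, "&")
  near <- outer(abs(r - end_px[2]) <= 2 * halfwidth_px,
                abs(c - end_px[1]) <= 2 * halfwidth_px, "&")
  out <- win | (mask & near)
  if (!is.null(exclude_pt) && exclude_radius_px > 0) {
    d2 <- outer((r - exclude_pt[2])^2, (c - exclude_pt[1])^2, "+")
    out <- out & d2 > exclude_radius_px^2
  }
  out
}

#' @export
print.mt_track <- function(x, ...) {
  n <- if (is.null(x$tracks)) 0 else nrow(x$tracks)
  cat("mt_track:", n, "frames,",
      format(100 * x$fraction_tracked, digits = 4), "% reliably tracked\n")
  if (!is.na(x$loss_frame)) cat("  track lost at frame", x$loss_frame, "\n")
  invisible(x)
}

#' @export
summary.mt_track <- function(object, ...) {
  tr <- object$tracks
  cat("frames:", nrow(tr), " reliable:", sum(tr$reliability),
      " detected:", sum(tr$detected), "\n")
  cat("dyn states:", paste(names(table(tr$dyn_state)),
                           table(tr$dyn_state), collapse = ", "), "\n")
  invisible(object)
}

#' @export
plot.mt_track <- function(x, ...) {
  tr <- x$tracks
  graphics::plot(tr$frame, sqrt(tr$end_x_nm^2 + tr$end_y_nm^2),
                 xlab = "frame", ylab = "end distance from origin (nm)",
                 col = ifelse(tr$reliability, "black", "red"), ...)
  invisible(x)
}
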
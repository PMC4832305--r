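# SNR measurement and the pre-fit filtering stack (Wiener, Wallis, box
# smoothing). Filtering is used only for segmentation and end proposal; the
# sub-pixel fit always consumes the raw frame.

#' Two-box signal-to-noise ratio of a microtubule image
#'
#' Places a 1.0 um x 0.4 um box along the backbone with its leading edge one
#' PSF FWHM behind the microtubule end (so tip taper does not bias the
#' signal), and an identical background box shifted 1 um perpendicular to the
#' axis. SNR = (I_MT - I_BK) / sqrt(sigma_MT^2 + sigma_BK^2) over the pixels
#' whose centres fall inside each box. The measure is invariant under affine
#' rescaling of the frame intensities.
#'
#' @param frame numeric matrix of detector counts.
#' @param ip [imaging_params()] (pixel size, PSF sigma).
#' @param backbone_nm 2-column matrix, backbone polyline in nm (image frame).
#' @param end_nm `[x, y]` end position in nm.
#' @param box_length_nm,box_width_nm box dimensions (defaults 1000 x 400 nm).
#' @param bk_offset_nm perpendicular shift of the background box (1000 nm).
#' @param structure_correct remove each box's mean lateral intensity profile
#'   before computing the box SDs (default `TRUE`). The microtubule's own
#'   deterministic lateral Gaussian profile otherwise dominates `sigma_MT`
#'   and caps the measurable SNR regardless of photon budget; with the
#'   correction the SDs reflect noise (and labelling speckle) about the
#'   structural expectation. `structure_correct = FALSE` gives the literal
#'   raw per-pixel statistics.
#' @return the SNR (dimensionless scalar).
#' @export
measure_snr <- function(frame, ip, backbone_nm, end_nm,
                        box_length_nm = 1000, box_width_nm = 400,
                        bk_offset_nm = 1000, structure_correct = TRUE) {
  boxes <- snr_boxes(ip, backbone_nm, end_nm, box_length_nm, box_width_nm,
                     bk_offset_nm)
  stats <- lapply(boxes, function(b) {
    v <- box_pixel_values(frame, ip, b)
    n <- length(v$values)
    if (n < 10) stop("fewer than 10 pixels inside an SNR box")
    if (!structure_correct)
      return(list(mean = mean(v$values), var = stats::var(v$values)))
    lat <- round(v$v / ip$pixel_size_nm)
    resid <- v$values - stats::ave(v$values, lat)
    k <- length(unique(lat))
    list(mean = mean(v$values), var = sum(resid^2) / max(n - k, 1))
  })
  num <- stats$mt$mean - stats$bk$mean
  if (num == 0) return(0)   # blank / featureless frame
  num / sqrt(stats$mt$var + stats$bk$var)
}

#' Geometry of the two SNR boxes
#'
#' @inheritParams measure_snr
#' @return list of two boxes (`mt`, `bk`), each a list with `centre_nm`
#'   (`[x, y]`), `tangent` (unit vector), `half_length_nm`, `half_width_nm`.
#' @export
snr_boxes <- function(ip, backbone_nm, end_nm, box_length_nm = 1000,
                      box_width_nm = 400, bk_offset_nm = 1000) {
  tvec <- end_tangent(backbone_nm)
  nvec <- c(-tvec[2], tvec[1])
  fwhm <- 2 * sqrt(2 * log(2)) * ip$sigma_psf_nm
  centre <- end_nm - tvec * (fwhm + box_length_nm / 2)
  list(mt = list(centre_nm = centre, tangent = tvec,
                 half_length_nm = box_length_nm / 2,
                 half_width_nm = box_width_nm / 2),
       bk = list(centre_nm = centre + nvec * bk_offset_nm, tangent = tvec,
                 half_length_nm = box_length_nm / 2,
                 half_width_nm = box_width_nm / 2))
}

# pixel values whose centres fall inside an oriented rectangle; errors if
# the rectangle sticks out of the frame.
box_pixel_values <- function(frame, ip, box) {
  a <- ip$pixel_size_nm
  xc <- px_to_nm(seq_len(ncol(frame)), a)
  yc <- px_to_nm(seq_len(nrow(frame)), a)
  corners_t <- box$half_length_nm * c(-1, 1)
  corners_n <- box$half_width_nm * c(-1, 1)
  nvec <- c(-box$tangent[2], box$tangent[1])
  cx <- box$centre_nm[1] + outer(corners_t * box$tangent[1], corners_n * nvec[1], "+")
  cy <- box$centre_nm[2] + outer(corners_t * box$tangent[2], corners_n * nvec[2], "+")
  if (min(cx) < 0 || max(cx) > ncol(frame) * a ||
      min(cy) < 0 || max(cy) > nrow(frame) * a)
    stop("SNR box outside the frame")
  dx <- outer(rep(1, nrow(frame)), xc) - box$centre_nm[1]
  dy <- outer(yc, rep(1, ncol(frame))) - box$centre_nm[2]
  u <- dx * box$tangent[1] + dy * box$tangent[2]
  v <- -dx * box$tangent[2] + dy * box$tangent[1]
  inside <- abs(u) <= box$half_length_nm & abs(v) <= box$half_width_nm
  list(values = frame[inside], u = u[inside], v = v[inside])
}

#' Adaptive Wiener (local MMSE) denoising
#'
#' Pixel-wise linear minimum-mean-square-error smoothing: with local mean `m`
#' and variance `v` over a `window x window` neighbourhood and global noise
#' variance estimated as the mean of the local variances, the output is
#' `m + max(0, v - noise) / max(v, noise) * (x - m)`. A window of 1 is the
#' identity.
#'
#' @param frame numeric matrix.
#' @param window odd window size in pixels (>= 3 for any smoothing).
#' @return filtered matrix.
#' @export
wiener_denoise <- function(frame, window = 5) {
  if (window <= 1) return(frame)
  stopifnot(window %% 2 == 1)
  st <- box_stats(frame, window)
  noise <- mean(st$var)
  gain <- ifelse(st$var > noise, (st$var - noise) / st$var, 0)
  st$mean + gain * (frame - st$mean)
}

#' Wallis local contrast normalisation
#'
#' Maps the local mean to `target_mean` and the local SD to `target_sd`
#' within a sliding window, removing slow spatial variations of intensity
#' and contrast. The contrast gain `target_sd / local_sd` is clamped to
#' `[1/gain_limit, gain_limit]`, so `gain_limit = 1` reduces to a pure local
#' mean shift and flat (zero-SD) regions stay bounded.
#'
#' @param frame numeric matrix.
#' @param window odd window size in pixels; should exceed the apparent
#'   microtubule width.
#' @param target_mean,target_sd desired local statistics; default to the
#'   global mean/SD of the frame.
#' @param gain_limit cap on the contrast gain (>= 1).
#' @return filtered matrix.
#' @export
wallis_normalize <- function(frame, window = 15, target_mean = mean(frame),
                             target_sd = stats::sd(frame), gain_limit = 5) {
  stopifnot(window %% 2 == 1, gain_limit >= 1)
  st <- box_stats(frame, window)
  sd_local <- sqrt(st$var)
  gain <- ifelse(sd_local > 0, target_sd / sd_local, gain_limit)
  gain <- pmin(pmax(gain, 1 / gain_limit), gain_limit)
  (frame - st$mean) * gain + target_mean
}

#' Box-average smoothing
#'
#' Plain `kernel x kernel` running-mean convolution with reflective borders;
#' a kernel of 1 is the identity.
#'
#' @param frame numeric matrix.
#' @param kernel odd kernel size in pixels.
#' @return smoothed matrix.
#' @export
smooth_box <- function(frame, kernel = 3) {
  box_mean(frame, kernel)
}

# the segmentation filter stack used by the tracker: Wiener then Wallis
# (end proposal thresholds are expressed in the Wallis-normalised scale).
prep_frame <- function(frame, tp) {
  w <- wiener_denoise(frame, tp$wiener_window_px)
  wallis_normalize(w, tp$wallis_window_px, gain_limit = tp$wallis_gain_limit)
}
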
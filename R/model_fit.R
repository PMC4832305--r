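# Sub-pixel 2D least-squares fit of the microtubule end to the raw image.
#
# The wall-end model describes a blunt tip: a Gaussian profile of width
# `sigma` perpendicular to the microtubule axis, multiplied by an
# integrated-Gaussian (error-function) edge of width `sigma_end` along the
# axis. The fitted end position is the half-maximum point of the axial
# intensity. The wall variant ties `sigma_end = sigma`; the free variant
# fits `sigma_end` separately, which reports the apparent axial end width
# (related to tip taper via sigma_end = sqrt(sigma_PSF^2 + sigma_PF^2)) at
# the cost of precision.

#' Gaussian wall-end model intensity
#'
#' With axial/lateral coordinates `(u, v)` of a point relative to the end
#' position and microtubule direction `angle`,
#' `I = background + amplitude * exp(-v^2 / (2 sigma^2)) * Phi(-u / sigma_end)`
#' where `Phi` is the standard normal CDF and `u` increases beyond the tip.
#' Far inside the microtubule the on-axis intensity plateaus at
#' `background + amplitude`; at the end position it is exactly
#' `background + amplitude / 2`.
#'
#' @param x,y evaluation coordinates (nm, image frame).
#' @param p named list: `end_x`, `end_y` (nm), `sigma`, `sigma_end` (nm),
#'   `amplitude`, `background` (counts), `angle` (rad).
#' @return expected intensities.
#' @export
wall_end_model <- function(x, y, p) {
  dx <- x - p$end_x; dy <- y - p$end_y
  u <- dx * cos(p$angle) + dy * sin(p$angle)
  v <- -dx * sin(p$angle) + dy * cos(p$angle)
  p$background + p$amplitude * exp(-v^2 / (2 * p$sigma^2)) *
    stats::pnorm(-u / p$sigma_end)
}

# residuals (model - data) and analytic Jacobian for the optimizer.
# par order, wall: x0 y0 sigma A bg angle; free: ... sigma_end appended.
wall_end_residuals <- function(par, x, y, z, free_sigma_end) {
  p <- par_to_list(par, free_sigma_end)
  wall_end_model(x, y, p) - z
}

wall_end_jacobian <- function(par, x, y, z, free_sigma_end) {
  p <- par_to_list(par, free_sigma_end)
  ca <- cos(p$angle); sa <- sin(p$angle)
  dx <- x - p$end_x; dy <- y - p$end_y
  u <- dx * ca + dy * sa
  v <- -dx * sa + dy * ca
  E <- exp(-v^2 / (2 * p$sigma^2))
  P <- stats::pnorm(-u / p$sigma_end)
  phi <- stats::dnorm(u / p$sigma_end)
  dI_du <- -p$amplitude * E * phi / p$sigma_end
  dI_dv <- -p$amplitude * E * P * v / p$sigma^2
  J <- cbind(
    x0 = -ca * dI_du + sa * dI_dv,
    y0 = -sa * dI_du - ca * dI_dv,
    sigma = p$amplitude * E * P * v^2 / p$sigma^3 +
      if (free_sigma_end) 0 else p$amplitude * E * phi * u / p$sigma^2,
    A = E * P,
    bg = rep(1, length(x)),
    angle = dI_du * v - dI_dv * u)
  if (free_sigma_end)
    J <- cbind(J, sigma_end = p$amplitude * E * phi * u / p$sigma_end^2)
  J
}

par_to_list <- function(par, free_sigma_end) {
  list(end_x = par[1], end_y = par[2], sigma = par[3],
       sigma_end = if (free_sigma_end) par[7] else par[3],
       amplitude = par[4], background = par[5], angle = par[6])
}

#' Fit the microtubule end model to raw image pixels
#'
#' Levenberg-Marquardt (damped Gauss-Newton) least squares with an analytic
#' Jacobian over the masked raw pixels. Parameter standard errors come from
#' the local quadratic approximation at the optimum; the reliability flag
#' requires convergence, `r2 > r2_min` and a fitted `sigma` within
#' `[0.5, 3] * sigma_psf`.
#'
#' @param raw_frame numeric matrix of raw detector counts (never filtered).
#' @param mask logical matrix (same shape) selecting the pixels that enter
#'   the loss; at least 20 pixels.
#' @param init named list of start values as in [wall_end_model()] (`angle`
#'   and `end_x`/`end_y` from the tracker's proposal).
#' @param ip [imaging_params()] (pixel size and PSF sigma).
#' @param variant `"wall"` (sigma_end = sigma) or `"free_sigma_end"`.
#' @param r2_min reliability threshold on the coefficient of determination.
#' @return an object of class `mt_end_fit` with elements `params`,
#'   `param_errors`, `r2`, `reliability`, `converged`, `n_pixels`, `variant`.
#' @export
fit_end <- function(raw_frame, mask, init, ip,
                    variant = c("wall", "free_sigma_end"), r2_min = 0.2) {
  variant <- match.arg(variant)
  free <- variant == "free_sigma_end"
  stopifnot(is.matrix(raw_frame), identical(dim(raw_frame), dim(mask)))
  idx <- which(mask)
  if (length(idx) < 20) stop("degenerate mask: fewer than 20 pixels")
  a <- ip$pixel_size_nm
  rc <- arrayInd(idx, dim(raw_frame))
  x <- px_to_nm(rc[, 2], a)
  y <- px_to_nm(rc[, 1], a)
  z <- raw_frame[idx]
  par <- c(init$end_x, init$end_y,
           if (is.null(init$sigma)) ip$sigma_psf_nm else init$sigma,
           init$amplitude, init$background, init$angle)
  if (free) par <- c(par, if (is.null(init$sigma_end)) ip$sigma_psf_nm else
    init$sigma_end)
  lower <- c(-Inf, -Inf, 20, 0, 0, -Inf)
  upper <- c(Inf, Inf, 10 * ip$sigma_psf_nm, Inf, Inf, Inf)
  if (free) { lower <- c(lower, 5); upper <- c(upper, 3000) }
  fit <- minpack.lm::nls.lm(
    par = par, lower = lower, upper = upper,
    fn = wall_end_residuals, jac = wall_end_jacobian,
    x = x, y = y, z = z, free_sigma_end = free,
    control = minpack.lm::nls.lm.control(
      maxiter = 200, ftol = 1e-9, ptol = 1e-9))
  converged <- fit$info %in% c(1, 2, 3, 4)
  p <- par_to_list(fit$par, free)
  res <- fit$fvec
  sse <- sum(res^2)
  sst <- sum((z - mean(z))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  dof <- length(z) - length(fit$par)
  ses <- rep(NA_real_, length(fit$par))
  jtj <- try(chol2inv(chol(crossprod(
    wall_end_jacobian(fit$par, x, y, z, free)))), silent = TRUE)
  if (!inherits(jtj, "try-error") && dof > 0)
    ses <- sqrt(pmax(diag(jtj), 0) * sse / dof)
  names(ses) <- c("end_x", "end_y", "sigma", "amplitude", "background",
                  "angle", if (free) "sigma_end")
  reliable <- isTRUE(converged) && !is.na(r2) && r2 > r2_min &&
    p$sigma >= 0.5 * ip$sigma_psf_nm && p$sigma <= 3 * ip$sigma_psf_nm
  structure(list(params = p, param_errors = ses, r2 = r2,
                 reliability = reliable, converged = converged,
                 info = fit$info, n_pixels = length(z), variant = variant,
                 sse = sse, ip = ip,
                 data = list(x = x, y = y, z = z)),
            class = "mt_end_fit")
}

#' @export
print.mt_end_fit <- function(x, ...) {
  cat("mt_end_fit (", x$variant, " model, ", x$n_pixels, " px)\n", sep = "")
  cat("  end: (", format(x$params$end_x, digits = 6), ", ",
      format(x$params$end_y, digits = 6), ") nm  +/- (",
      format(x$param_errors[["end_x"]], digits = 3), ", ",
      format(x$param_errors[["end_y"]], digits = 3), ")\n", sep = "")
  cat("  sigma:", format(x$params$sigma, digits = 4), "nm  sigma_end:",
      format(x$params$sigma_end, digits = 4), "nm  angle:",
      format(x$params$angle, digits = 3), "rad\n")
  cat("  amplitude:", format(x$params$amplitude, digits = 4),
      " background:", format(x$params$background, digits = 4),
      " r2:", format(x$r2, digits = 3),
      " reliable:", x$reliability, "\n")
  invisible(x)
}

#' @export
coef.mt_end_fit <- function(object, ...) {
  p <- object$params
  c(end_x = p$end_x, end_y = p$end_y, sigma = p$sigma,
    sigma_end = p$sigma_end, amplitude = p$amplitude,
    background = p$background, angle = p$angle)
}

#' @export
predict.mt_end_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- list(x = object$data$x, y = object$data$y)
  wall_end_model(newdata$x, newdata$y, object$params)
}

#' @export
residuals.mt_end_fit <- function(object, ...) {
  object$data$z - predict(object)
}
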
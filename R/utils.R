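# Shared low-level helpers: the single nm <-> pixel convention, bilinear
# sampling, and separable box statistics used by the filtering stack.

#' Convert nanometre coordinates to (fractional) pixel indices
#'
#' The package-wide convention: images are matrices indexed `img[row, col]`
#' with `col` along x and `row` along y; the centre of pixel `(i, j)`
#' (1-based) lies at `x = (j - 0.5) * pixel_size`, `y = (i - 0.5) * pixel_size`
#' with the origin at the image corner. All conversions go through this pair
#' of functions.
#'
#' @param nm numeric vector of positions in nm.
#' @param pixel_size pixel edge length in nm.
#' @return fractional 1-based pixel index.
#' @export
nm_to_px <- function(nm, pixel_size) nm / pixel_size + 0.5

#' @rdname nm_to_px
#' @param px fractional 1-based pixel index.
#' @export
px_to_nm <- function(px, pixel_size) (px - 0.5) * pixel_size

# Bilinear interpolation of a matrix at fractional (row, col) positions.
# Points outside the image return NA.
bilinear <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc & is.finite(row) & is.finite(col)
  out <- rep(NA_real_, length(row))
  if (!any(ok)) return(out)
  r <- pmin(pmax(row[ok], 1), nr); c <- pmin(pmax(col[ok], 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  out[ok] <- img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
  out
}

# Reflective padding by `k` pixels on every side.
pad_reflect <- function(img, k) {
  if (k == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rev(seq_len(min(k, nr))), seq_len(nr), nr + 1 - rev(seq_len(min(k, nr))))
  ci <- c(rev(seq_len(min(k, nc))), seq_len(nc), nc + 1 - rev(seq_len(min(k, nc))))
  img[ri, ci, drop = FALSE]
}

# Separable running-mean over a w x w window (odd w), reflective borders.
box_mean <- function(img, w) {
  if (w <= 1) return(img)
  stopifnot(w %% 2 == 1)
  k <- (w - 1L) / 2L
  p <- pad_reflect(img, k)
  ker <- rep(1 / w, w)
  # filter() along columns then rows of the padded image
  p <- apply(p, 2, function(v) stats::filter(v, ker, sides = 2))
  p <- t(apply(p, 1, function(v) stats::filter(v, ker, sides = 2)))
  p[(k + 1):(k + nrow(img)), (k + 1):(k + ncol(img)), drop = FALSE]
}

# Local mean and variance over a w x w window.
box_stats <- function(img, w) {
  m <- box_mean(img, w)
  v <- box_mean(img^2, w) - m^2
  v[v < 0] <- 0
  list(mean = m, var = v)
}

# Robust background statistics of a frame (median/MAD); microtubule pixels
# are sparse so these estimate the background level and noise.
robust_bg <- function(img) {
  med <- stats::median(img)
  list(mean = med, sd = stats::mad(img, center = med))
}

# Arclength parameterisation of a polyline given as a 2-column matrix.
polyline_arclength <- function(xy) {
  d <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  c(0, cumsum(d))
}

# Resample a polyline at regular arclength spacing `by` (same units as xy).
resample_polyline <- function(xy, by = 1) {
  s <- polyline_arclength(xy)
  keep <- c(TRUE, diff(s) > 1e-9)
  xy <- xy[keep, , drop = FALSE]; s <- s[keep]
  if (nrow(xy) < 2) return(xy)
  sout <- seq(0, s[length(s)], by = by)
  if (sout[length(sout)] < s[length(s)]) sout <- c(sout, s[length(s)])
  cbind(stats::approx(s, xy[, 1], xout = sout)$y,
        stats::approx(s, xy[, 2], xout = sout)$y)
}

# Unit tangent of a polyline at its last point, averaged over the final
# `npts` points for stability.
end_tangent <- function(xy, npts = 10) {
  n <- nrow(xy)
  i0 <- max(1, n - npts)
  v <- xy[n, ] - xy[i0, ]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) c(1, 0) else v / nv
}
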
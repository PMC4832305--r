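# Ground-truth microtubule lattice: stochastic growth with a maintained
# linear tip taper, static fluorophore labelling, 3-start helical geometry
# and first-order cantilever thermal bending.
#
# A lattice state stores, per protofilament, the subunit count plus parallel
# vectors of label flags and incorporation times. Label flags are drawn once
# at incorporation and never resampled (static photophysics; no bleaching).

#' Create a fresh lattice state
#'
#' Initialises a microtubule of the requested length whose protofilament tips
#' already form the linear taper ramp, with labels drawn at the configured
#' labelling ratio.
#'
#' @param lp [lattice_params()].
#' @param initial_length_nm mean tip axial position at frame 0 (nm).
#' @param taper_length_nm axial extent of the tip ramp (nm).
#' @param seed_length_nm length of the stabilized seed region below which
#'   depolymerization cannot proceed (defaults to the full initial length,
#'   i.e. a non-shrinkable construct; the movie simulator passes its clamp
#'   length).
#' @param seed optional RNG seed for the initial label draw.
#' @return an object of class `lattice_state`.
#' @export
new_lattice <- function(lp, initial_length_nm, taper_length_nm = 0,
                        seed_length_nm = initial_length_nm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  npf <- lp$n_protofilaments
  sub <- lp$subunit_length_nm
  ramp <- pf_ramp_offsets(taper_length_nm, npf)
  stagger <- pf_stagger(lp)
  # choose counts so tip axial positions approximate initial_length + ramp
  target <- initial_length_nm + taper_length_nm / 2 + ramp - stagger
  n <- pmax(2L, as.integer(round(target / sub)) + 1L)
  labels <- lapply(n, function(k) stats::runif(k) < lp$labelling_ratio)
  entry <- lapply(n, function(k) rep(-Inf, k))
  seed_n <- pmin(n, pmax(2L, as.integer(round(seed_length_nm / sub))))
  structure(list(pf_lengths = n, labels = labels, entry_times = entry,
                 seed_lengths = seed_n, time = 0, clamped = FALSE),
            class = "lattice_state")
}

# fixed per-protofilament ramp offsets (nm): rank k sits TL*(k-1)/(npf-1)
# behind the leading protofilament.
pf_ramp_offsets <- function(taper_length_nm, npf) {
  if (npf == 1) return(0)
  -taper_length_nm * (seq_len(npf) - 1) / (npf - 1)
}

# intrinsic axial stagger of each protofilament from the helical rise:
# going once around the npf protofilaments rises helix_start subunits.
pf_stagger <- function(lp) {
  (seq_len(lp$n_protofilaments) - 1) *
    lp$helix_start * lp$subunit_length_nm / lp$n_protofilaments
}

# axial position (nm) of subunit i (1-based) on protofilament k
subunit_axial <- function(i, k, lp) {
  (i - 1) * lp$subunit_length_nm + pf_stagger(lp)[k]
}

# tip axial positions, one per protofilament
pf_tip_axial <- function(state, lp) {
  subunit_axial(state$pf_lengths, seq_along(state$pf_lengths), lp)
}

#' Advance the lattice by one frame interval
#'
#' The net number of subunits gained is drawn from a normal distribution with
#' mean `v_g * dt * n_pf / subunit_length` and variance
#' `2 * D_p * dt * (n_pf / subunit_length)^2`, rounded half-to-even; a
#' negative draw removes subunits. Additions go to the protofilament
#' currently furthest behind its taper ramp position (removals take from the
#' one furthest ahead), which keeps the sorted tip offsets on a stationary
#' linear ramp of extent `taper_length_nm`. Incorporation/removal times are
#' spread evenly across the frame interval for later exposure weighting.
#'
#' @param state a `lattice_state`.
#' @param gp [growth_params()].
#' @param lp [lattice_params()].
#' @param seed optional RNG seed.
#' @return list with elements `state` (advanced) and `removed`, a data frame
#'   of subunits lost during the step (`pf`, `idx`, `labelled`, `entry_time`,
#'   `removal_time`).
#' @export
step_growth <- function(state, gp, lp, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- gp$frame_interval_s
  per_sub <- lp$n_protofilaments / lp$subunit_length_nm
  mu <- gp$v_g_nm_per_s * dt * per_sub
  sdev <- sqrt(2 * gp$d_p_nm2_per_s * dt) * per_sub
  n <- round(if (sdev > 0) stats::rnorm(1, mu, sdev) else mu)
  t0 <- state$time
  ramp <- pf_ramp_offsets(gp$taper_length_nm, lp$n_protofilaments)
  removed <- list()
  if (n != 0) {
    times <- t0 + seq_len(abs(n)) * dt / (abs(n) + 1)
    for (j in seq_len(abs(n))) {
      tips <- pf_tip_axial(state, lp)
      score <- tips - ramp   # how far ahead of its ramp slot each tip sits
      if (n > 0) {
        k <- which.min(score)
        state$pf_lengths[k] <- state$pf_lengths[k] + 1L
        state$labels[[k]] <- c(state$labels[[k]],
                               stats::runif(1) < lp$labelling_ratio)
        state$entry_times[[k]] <- c(state$entry_times[[k]], times[j])
      } else {
        k <- which.max(score)
        if (state$pf_lengths[k] <= state$seed_lengths[k]) {
          state$clamped <- TRUE
          next
        }
        i <- state$pf_lengths[k]
        removed[[length(removed) + 1L]] <-
          data.frame(pf = k, idx = i, labelled = state$labels[[k]][i],
                     entry_time = state$entry_times[[k]][i],
                     removal_time = times[j])
        state$pf_lengths[k] <- i - 1L
        state$labels[[k]] <- state$labels[[k]][-i]
        state$entry_times[[k]] <- state$entry_times[[k]][-i]
      }
    }
  }
  state$time <- t0 + dt
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(pf = integer(), idx = integer(), labelled = logical(),
               entry_time = numeric(), removal_time = numeric())
  list(state = state, removed = removed)
}

#' Project lattice subunits into the 2D image plane (lattice frame)
#'
#' Returns the `[x, y]` coordinates (nm) of subunits in the microtubule's own
#' frame: x along the axis from the seed, y the in-plane projection of the
#' helical position, `y = r * sin(2 pi (k-1) / n_pf)`.
#'
#' @param state a `lattice_state`.
#' @param lp [lattice_params()].
#' @param which `"labelled"` (default), `"terminal"` (one tip subunit per
#'   protofilament, regardless of label), or `"all"`.
#' @return data frame with `x`, `y`, `pf`, `idx`, `labelled`, `entry_time`.
#' @export
place_subunits <- function(state, lp, which = c("labelled", "terminal", "all")) {
  which <- match.arg(which)
  npf <- length(state$pf_lengths)
  theta <- 2 * pi * (seq_len(npf) - 1) / npf
  rows <- lapply(seq_len(npf), function(k) {
    idx <- seq_len(state$pf_lengths[k])
    lab <- state$labels[[k]]
    ent <- state$entry_times[[k]]
    if (which == "labelled") {
      sel <- which(lab)
    } else if (which == "terminal") {
      sel <- state$pf_lengths[k]
    } else sel <- idx
    if (!length(sel)) return(NULL)
    data.frame(x = subunit_axial(sel, k, lp),
               y = lp$lattice_radius_nm * sin(theta[k]),
               pf = k, idx = sel, labelled = lab[sel], entry_time = ent[sel])
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(x = numeric(), y = numeric(), pf = integer(),
                      idx = integer(), labelled = logical(),
                      entry_time = numeric()))
  do.call(rbind, rows)
}

#' Normalised deflection shape of a uniformly loaded cantilever
#'
#' First-order beam theory for a clamped, uniformly loaded cantilever:
#' `w(u) = u^2 (6 - 4u + u^2) / 3` with `w(0) = 0`, `w(1) = 1`, monotone on
#' `[0, 1]`.
#'
#' @param u normalised arclength beyond the clamp, in `[0, 1]` (clamped to
#'   that range).
#' @export
beam_deflection_shape <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^2 * (6 - 4 * u + u^2) / 3
}

#' Apply a thermal bending deflection to lattice-frame coordinates
#'
#' The seed region (`x <= clamp_length_nm`) is rigid; beyond it each subunit
#' is displaced perpendicular to the axis by `d * w(s / L_free)` where `d` is
#' the tip deflection and `w` the cantilever shape. Axial positions are not
#' modified (deflections are small relative to the length). If
#' `deflection_nm` is `NULL` a fresh tip deflection is drawn from
#' `Normal(0, sigma_ld^2)`.
#'
#' @param coords data frame with at least `x`, `y` (nm, lattice frame).
#' @param gp [growth_params()].
#' @param clamp_length_nm rigid seed length (nm).
#' @param tip_x_nm axial position of the tip (nm); defaults to `max(x)`.
#' @param deflection_nm tip deflection to apply (nm), or `NULL` to draw one.
#' @param seed optional RNG seed.
#' @return `coords` with displaced `y` and the tip deflection attached as
#'   attribute `"deflection_nm"`.
#' @export
apply_thermal_deflection <- function(coords, gp, clamp_length_nm,
                                     tip_x_nm = NULL, deflection_nm = NULL,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(deflection_nm))
    deflection_nm <- if (gp$sigma_ld_nm > 0)
      stats::rnorm(1, 0, gp$sigma_ld_nm) else 0
  if (nrow(coords)) {
    if (is.null(tip_x_nm)) tip_x_nm <- max(coords$x)
    l_free <- tip_x_nm - clamp_length_nm
    if (l_free > 0 && deflection_nm != 0) {
      u <- (coords$x - clamp_length_nm) / l_free
      coords$y <- coords$y + deflection_nm * beam_deflection_shape(u)
    }
  }
  attr(coords, "deflection_nm") <- deflection_nm
  coords
}

# rotate lattice-frame coordinates by `angle` and translate by `origin`
# (image frame, nm).
to_image_frame <- function(coords, angle, origin) {
  x <- coords$x * cos(angle) - coords$y * sin(angle) + origin[1]
  y <- coords$x * sin(angle) + coords$y * cos(angle) + origin[2]
  coords$x <- x
  coords$y <- y
  coords
}

#' Ground-truth end position of the lattice
#'
#' The true end is the mean of the coordinates of the final subunit on each
#' protofilament, independent of labelling state. Also reports the mean tip
#' axial position (`length_nm`) and the SD of the protofilament tip axial
#' positions (`sigma_pf_nm`).
#'
#' @param state a `lattice_state`.
#' @param lp [lattice_params()].
#' @param gp optional [growth_params()]; together with `clamp_length_nm` and
#'   `deflection_nm` applies the same bending the rendered image sees.
#' @param clamp_length_nm rigid seed length (nm).
#' @param deflection_nm tip deflection (nm) to apply, default 0.
#' @return list with `end` (`[x, y]` nm, lattice frame), `length_nm`,
#'   `sigma_pf_nm`.
#' @details The subunit coordinate used throughout the lattice marks the
#'   subunit's lattice site; the polymer of a protofilament extends half a
#'   subunit length beyond its terminal site. The true end is therefore the
#'   mean of the terminal distal edges, i.e. the mean terminal coordinate
#'   plus `subunit_length / 2` along the axis. This is also where the
#'   half-maximum of the PSF-convolved intensity edge of a blunt tip falls,
#'   so a perfect tracker has zero axial offset by construction.
#' @export
true_end <- function(state, lp, gp = NULL, clamp_length_nm = 0,
                     deflection_nm = 0) {
  tips <- place_subunits(state, lp, which = "terminal")
  if (!is.null(gp) && deflection_nm != 0)
    tips <- apply_thermal_deflection(tips, gp, clamp_length_nm,
                                     tip_x_nm = max(tips$x),
                                     deflection_nm = deflection_nm)
  half <- lp$subunit_length_nm / 2
  list(end = c(mean(tips$x) + half, mean(tips$y)),
       length_nm = mean(tips$x) + half,
       sigma_pf_nm = stats::sd(tips$x))
}

#' Protofilament-length SD of a linear taper
#'
#' SD of the tip axial positions when the protofilament tips form a linear
#' ramp of extent `taper_length_nm` across `n_pf` protofilaments; this is the
#' `sigma_PF` entering the axial end-width relation
#' `sigma_end = sqrt(sigma_PSF^2 + sigma_PF^2)`.
#'
#' @param taper_length_nm ramp extent (nm).
#' @param n_pf number of protofilaments.
#' @export
sigma_pf_from_taper <- function(taper_length_nm, n_pf = 13) {
  vapply(taper_length_nm,
         function(tl) stats::sd(seq(0, -tl, length.out = n_pf)), 0)
}
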
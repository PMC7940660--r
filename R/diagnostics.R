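# Diagnostics on simulated trajectories: conservation, pulse tracking,
# deviation from analytic references, persistence times, and the linear
# damped-harmonic-oscillator spectrum.

#' Integrated density deviation (mass)
#'
#' Trapezoidal integral of drho' over the grid.  In flux form the scheme
#' conserves this to round-off for compact pulses away from the
#' boundaries.
#'
#' @param rho field values per node (or a `field_state`).
#' @param dx spatial step.
#' @return scalar integral.
#' @export
field_mass <- function(rho, dx) {
  if (inherits(rho, "field_state")) rho <- rho$rho
  n <- length(rho)
  dx * (sum(rho) - 0.5 * (rho[1] + rho[n]))
}

#' Track the dominant pulse through a trajectory
#'
#' Per snapshot, locates the extremum of the density deviation (parabolic
#' interpolation through the three nodes around the grid extremum), its
#' amplitude, and the width at half the extremum; the propagation velocity
#' is the least-squares slope of position against time.
#'
#' @param traj `trajectory`.
#' @param noise_floor minimum |amplitude| for the extremum to count as a
#'   pulse; below it tracking is declared lost.
#' @return object of class `pulse_track`: a tibble with columns `time`,
#'   `peak_position`, `peak_amplitude`, `width_half_max` and
#'   `delta_measured` (width / (2 acosh sqrt 2), the sech^2 width
#'   parameter), with the fitted velocity in
#'   `attr(, "fitted_velocity")` (NA with fewer than 3 snapshots).
#' @export
track_pulse <- function(traj, noise_floor = 1e-8) {
  x <- traj$x
  dx <- traj$grid$dx
  one <- function(j) {
    r <- traj$rho[, j]
    i0 <- which.max(abs(r))
    a0 <- r[i0]
    if (abs(a0) < noise_floor)
      abort(sprintf("tracking lost: no extremum above the noise floor at t' = %g",
                    traj$t[j]),
            class = "aquasoliton_error_tracking")
    if (i0 > 1 && i0 < length(r)) {
      ym <- r[i0 - 1]; y0 <- r[i0]; yp <- r[i0 + 1]
      denom <- ym - 2 * y0 + yp
      shift <- if (abs(denom) > 0) 0.5 * (ym - yp) / denom else 0
      shift <- max(min(shift, 0.5), -0.5)
      pos <- x[i0] + shift * dx
      amp <- y0 - 0.25 * (ym - yp) * shift
    } else {
      pos <- x[i0]; amp <- a0
    }
    half <- amp / 2
    # scan outward from the peak for the half-maximum crossings
    cross <- function(idx_seq) {
      prev <- i0
      for (i in idx_seq) {
        if (abs(r[i]) <= abs(half)) {
          frac <- (abs(r[prev]) - abs(half)) / (abs(r[prev]) - abs(r[i]))
          return(x[prev] + frac * (x[i] - x[prev]))
        }
        prev <- i
      }
      NA_real_
    }
    xl <- cross(seq(i0 - 1, 1))
    xr <- cross(seq(i0 + 1, length(r)))
    c(pos = pos, amp = amp, width = abs(xr - xl))
  }
  m <- vapply(seq_along(traj$t), one, c(pos = 0, amp = 0, width = 0))
  out <- tibble(time = traj$t,
                peak_position = m["pos", ],
                peak_amplitude = m["amp", ],
                width_half_max = m["width", ],
                delta_measured = m["width", ] / (2 * ACOSH_SQRT2))
  v <- NA_real_
  if (length(traj$t) >= 3)
    v <- unname(coef(lm(peak_position ~ time, data = out))[2])
  structure(out, fitted_velocity = v, class = c("pulse_track", class(out)))
}

#' @rdname track_pulse
#' @param object a `pulse_track`.
#' @param ... unused.
#' @method autoplot pulse_track
#' @export
autoplot.pulse_track <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            c("peak_position", "peak_amplitude",
                              "width_half_max"),
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "t'", title = "Pulse track")
}

#' Deviation of a trajectory from a reference profile
#'
#' Relative L2 (and Linf) distance between the simulated density field and
#' a reference, per snapshot.  The reference may be a `soliton` (evaluated
#' analytically at each snapshot time, i.e. co-moving for traveling
#' pulses), a function of (x, t), or a matrix of the same shape as
#' `traj$rho`.
#'
#' @param traj `trajectory`.
#' @param reference `soliton` (in grid units), function(x, t), or matrix.
#' @param center,direction passed to [soliton_profile()] when `reference`
#'   is a soliton; `center` defaults to the domain midpoint.
#' @return object of class `deviation_series`: tibble with columns `time`,
#'   `l2`, `linf`.
#' @export
deviation_series <- function(traj, reference, center = NULL, direction = 1) {
  x <- traj$x
  nt <- length(traj$t)
  ref_at <- function(j) {
    if (inherits(reference, "soliton"))
      soliton_profile(reference, x, time = traj$t[j],
                      center = center %||% (traj$grid$length / 2),
                      direction = direction)
    else if (is.function(reference)) reference(x, traj$t[j])
    else reference[, j]
  }
  l2 <- numeric(nt)
  linf <- numeric(nt)
  for (j in seq_len(nt)) {
    ref <- ref_at(j)
    nref <- sqrt(sum(ref^2))
    if (nref == 0)
      abort("reference profile has zero norm",
            class = "aquasoliton_error_domain")
    d <- traj$rho[, j] - ref
    l2[j] <- sqrt(sum(d^2)) / nref
    linf[j] <- max(abs(d)) / max(abs(ref))
  }
  structure(tibble(time = traj$t, l2 = l2, linf = linf),
            class = c("deviation_series", "tbl_df", "tbl", "data.frame"))
}

#' @rdname deviation_series
#' @param object a `deviation_series`.
#' @param threshold optional horizontal guide line.
#' @param ... unused.
#' @method autoplot deviation_series
#' @export
autoplot.deviation_series <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$time, .data$l2)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t'", y = "relative L2 deviation",
                  title = "Deviation from the reference profile")
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                                 colour = "firebrick")
  p
}

#' First time a deviation series crosses a threshold
#'
#' Linear interpolation between the two bracketing snapshots; returns `Inf`
#' when the threshold is never reached within the simulated window.  This
#' operationalizes the persistence time of a pulse under thermal forcing.
#'
#' @param dev `deviation_series` (or tibble with `time`, `l2`).
#' @param threshold relative L2 threshold (default 0.05); "negligible
#'   deviation" has no universal definition, so the value is exposed.
#' @return scalar crossing time (dimensionless), or `Inf`.
#' @export
persistence_time <- function(dev, threshold = 0.05) {
  if (threshold <= 0)
    abort("`threshold` must be positive", class = "aquasoliton_error_input")
  tt <- dev$time
  y <- dev$l2
  above <- which(y >= threshold)
  if (length(above) == 0) return(Inf)
  j <- above[1]
  if (j == 1) return(tt[1])
  t0 <- tt[j - 1]; t1 <- tt[j]
  y0 <- y[j - 1]; y1 <- y[j]
  t0 + (threshold - y0) / (y1 - y0) * (t1 - t0)
}

#' Damped-harmonic-oscillator spectrum
#'
#' The normalized dynamic structure factor of the linearized model,
#' S(q, omega)/S(q) = 2 Gamma omega0^2 / ((omega^2 - omega0^2)^2 +
#' 4 Gamma^2 omega^2) with Gamma(q) = (eta_L / 2 rho0) q^2.  At
#' omega = omega0 the value is 1/(2 Gamma), and the integral over
#' d(omega)/(2 pi) on the real line equals 1/2.
#'
#' @param omega angular-frequency grid (rad/s).
#' @param q wavenumber (1/m).
#' @param coeff `dispersion_coefficients`/`dispersion_fit` giving omega0(q).
#' @param eta_L_over_rho0 kinematic longitudinal viscosity (m^2/s).
#' @return numeric vector, same length as `omega`.
#' @export
dho_spectrum <- function(omega, q, coeff, eta_L_over_rho0) {
  stopifnot_scalar(q, "q")
  stopifnot_scalar(eta_L_over_rho0, "eta_L_over_rho0")
  w0 <- omega0(q, coeff, warn = FALSE)
  g <- 0.5 * eta_L_over_rho0 * q^2
  2 * g * w0^2 / ((omega^2 - w0^2)^2 + 4 * g^2 * omega^2)
}
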
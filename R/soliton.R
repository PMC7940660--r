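# Closed-form sech^2 soliton machinery of the Boussinesq equation
#   rho_tt - k1 rho_xx + k2 rho_xxxx - alpha (rho rho_x)_x = 0 .
# The one-parameter family
#   drho(x, t) = A sech^2((x - v t)/delta),
#   A = -12 k2 / (alpha delta^2),   v^2 = k1 - 4 k2 / delta^2
# describes subsonic rarefaction pulses (A < 0); the width delta is the free
# parameter, admissible for delta^2 >= 4 k2/k1.  At the lower bound the
# velocity vanishes and the stationary pulse
#   delta^2 = 4 k2/k1,  A = -3 k1/alpha,  v = 0
# is additionally an exact steady solution of the *damped* equation, since
# its flux k1 rho - k2 rho_xx + (alpha/2) rho^2 vanishes identically.

ACOSH_SQRT2 <- acosh(sqrt(2))  # half-width of sech^2 in units of delta

new_soliton <- function(A, delta, v, k1, k2, alpha) {
  structure(list(A = A, delta = delta, v = v,
                 fwhm = soliton_fwhm(delta),
                 k1 = k1, k2 = k2, alpha = alpha),
            class = "soliton")
}

#' @export
print.soliton <- function(x, ...) {
  cat("<sech^2 soliton (rarefaction pulse)>\n")
  cat(sprintf("  A = %.4g (|A| = %.4g), delta = %.4g, FWHM = %.4g, v = %.4g\n",
              x$A, abs(x$A), x$delta, x$fwhm, x$v))
  invisible(x)
}

#' The one-parameter soliton family
#'
#' Given the width parameter delta and the generating coefficients, returns
#' the (A, delta, v) triple with A = -12 k2/(alpha delta^2) and
#' v = sqrt(k1 - 4 k2/delta^2).  The velocity is real only for
#' delta^2 >= 4 k2/k1 and is always strictly below the long-wavelength
#' sound speed sqrt(k1): the pulses are subsonic and slow down as they
#' narrow.
#'
#' @param delta width parameter (m, or model units if `coeff` is
#'   dimensionless).
#' @param coeff `dispersion_coefficients`/`dispersion_fit`, or
#'   `dimensionless_params` to work in primed units.
#' @param alpha nonlinearity coefficient matching the unit system of
#'   `coeff`; defaults to `coeff$alphap` for dimensionless input.
#' @return object of class `soliton` with fields `A` (negative), `delta`,
#'   `v` (non-negative root; propagation direction is chosen at profile
#'   construction), `fwhm`, and the generating `k1`, `k2`, `alpha`.
#' @examples
#' co <- dispersion_coefficients(3.9e6, 4.8e-13)
#' soliton_family(2.113e-9, co, alpha = 3.0e4)
#' @export
soliton_family <- function(delta, coeff, alpha = NULL) {
  ka <- soliton_coeffs(coeff, alpha)
  stopifnot_scalar(delta, "delta")
  dmin <- 2 * sqrt(ka$k2 / ka$k1)
  if (delta^2 < dmin^2 * (1 - 1e-12))
    abort(sprintf(paste0("imaginary velocity: delta^2 < 4 k2/k1; the minimum ",
                         "admissible width is delta = %.6g"), dmin),
          class = "aquasoliton_error_imaginary_velocity")
  v2 <- max(ka$k1 - 4 * ka$k2 / delta^2, 0)
  new_soliton(A = -12 * ka$k2 / (ka$alpha * delta^2), delta = delta,
              v = sqrt(v2), k1 = ka$k1, k2 = ka$k2, alpha = ka$alpha)
}

soliton_coeffs <- function(coeff, alpha) {
  if (inherits(coeff, "dimensionless_params")) {
    list(k1 = coeff$k1p, k2 = coeff$k2p, alpha = alpha %||% coeff$alphap)
  } else {
    coeff <- as_coefficients(coeff)
    if (is.null(alpha))
      abort("`alpha` is required with dimensional coefficients",
            class = "aquasoliton_error_input")
    list(k1 = coeff$k1, k2 = coeff$k2, alpha = alpha)
  }
}

#' The stationary soliton
#'
#' The zero-velocity member of the family: delta = 2 sqrt(k2/k1),
#' A = -3 k1/alpha.  This profile is an exact steady solution of the damped
#' deterministic equation, interpreted as a stationary nanosized region of
#' rarefaction.
#'
#' @inheritParams soliton_family
#' @return `soliton` object with `v = 0`.
#' @examples
#' stationary_soliton(dispersion_coefficients(3.9e6, 4.8e-13), alpha = 3.0e4)
#' @export
stationary_soliton <- function(coeff, alpha = NULL) {
  ka <- soliton_coeffs(coeff, alpha)
  new_soliton(A = -3 * ka$k1 / ka$alpha, delta = 2 * sqrt(ka$k2 / ka$k1),
              v = 0, k1 = ka$k1, k2 = ka$k2, alpha = ka$alpha)
}

#' Width from a prescribed amplitude magnitude
#'
#' Inverts A = -12 k2/(alpha delta^2): delta = sqrt(12 k2/(alpha |A|)).
#' Used to construct the propagating pulse whose amplitude equals the
#' thermal density-fluctuation magnitude A*.  Amplitudes above the
#' stationary bound 3 k1/alpha would imply an imaginary velocity and are
#' rejected.
#'
#' @param abs_A amplitude magnitude (kg/m^3 in SI, or model units).
#' @param k2 quartic dispersion coefficient.
#' @param alpha nonlinearity coefficient.
#' @param k1 optional; when given, the admissibility bound
#'   `abs_A <= 3 k1/alpha` is enforced.
#' @return width delta in the same length unit system.
#' @examples
#' delta_from_amplitude(43, k2 = 4.8e-13, alpha = 3.0e4, k1 = 3.9e6)
#' @export
delta_from_amplitude <- function(abs_A, k2, alpha, k1 = NULL) {
  stopifnot_scalar(abs_A, "abs_A")
  stopifnot_scalar(k2, "k2")
  stopifnot_scalar(alpha, "alpha")
  if (!is.null(k1) && abs_A > 3 * k1 / alpha * (1 + 1e-12))
    abort(sprintf(paste0("imaginary velocity: |A| exceeds the stationary ",
                         "bound 3 k1/alpha = %.6g"), 3 * k1 / alpha),
          class = "aquasoliton_error_imaginary_velocity")
  sqrt(12 * k2 / (alpha * abs_A))
}

#' Full width at half maximum of a sech^2 pulse
#'
#' For A sech^2(x/delta) the half-maximum points sit at
#' |x| = acosh(sqrt(2)) delta, so FWHM = 2 acosh(sqrt(2)) delta
#' (approximately 1.7627 delta).
#'
#' @param delta width parameter.
#' @return FWHM in the same units.
#' @export
soliton_fwhm <- function(delta) {
  if (any(delta <= 0))
    abort("`delta` must be positive", class = "aquasoliton_error_input")
  2 * ACOSH_SQRT2 * delta
}

#' Sample the soliton profile on a grid
#'
#' drho(x, t) = A sech^2((x - center - v t)/delta).  The peak value is A at
#' x = center + v t and the spatial integral is 2 A delta.
#'
#' @param sol `soliton` object.
#' @param x positions (same unit system as the soliton).
#' @param time evaluation time (default 0).
#' @param center pulse centre at time 0 (default 0).
#' @param direction +1 or -1, the sign given to the stored non-negative
#'   velocity.
#' @return numeric vector of density deviations.
#' @export
soliton_profile <- function(sol, x, time = 0, center = 0, direction = 1) {
  if (!inherits(sol, "soliton"))
    abort("`sol` must be a soliton object", class = "aquasoliton_error_input")
  sol$A / cosh((x - center - direction * sol$v * time) / sol$delta)^2
}

#' Initial field state for the wave solver
#'
#' Builds the dimensionless (drho', u') pair on a grid from a soliton.  For
#' a soliton in SI units the `dimless` scales convert amplitude, width and
#' velocity into primed units.  The velocity field follows the exact
#' traveling-wave relation of the undamped Boussinesq soliton,
#' u' = v' drho' (identically zero for the stationary pulse); the
#' continuity equation then transports the profile at speed v'.
#'
#' @param sol `soliton` object, in SI units (give `dimless`) or already in
#'   primed model units (leave `dimless` NULL).
#' @param grid `grid_1d` object.
#' @param dimless optional `dimensionless_params` carrying the scales.
#' @param center pulse centre in grid units (default: domain midpoint).
#' @param direction +1 (rightward) or -1.
#' @param clearance_fwhm minimum distance from the centre to either
#'   boundary, in pulse FWHMs (default 5); closer placements are rejected
#'   so that the pulse support never overlaps the absorbing boundary zones.
#' @return object of class `field_state`: list with `rho`, `u`, `time`.
#' @export
soliton_initial_state <- function(sol, grid, dimless = NULL,
                                  center = NULL, direction = 1,
                                  clearance_fwhm = 5) {
  if (!inherits(sol, "soliton"))
    abort("`sol` must be a soliton object", class = "aquasoliton_error_input")
  if (!is.null(dimless)) {
    s <- dimless$scales
    A_p <- sol$A / s$A_star
    delta_p <- sol$delta * s$q_star
    v_p <- sol$v * s$q_star / s$omega_star
  } else {
    A_p <- sol$A
    delta_p <- sol$delta
    v_p <- sol$v
  }
  center <- center %||% (grid$length / 2)
  fwhm_p <- soliton_fwhm(delta_p)
  clearance <- min(center, grid$length - center)
  if (clearance < clearance_fwhm * fwhm_p)
    abort(sprintf(paste0("pulse too close to the boundary: clearance %.3g < ",
                         "%g FWHM (= %.3g)"),
                  clearance, clearance_fwhm, clearance_fwhm * fwhm_p),
          class = "aquasoliton_error_placement")
  rho <- A_p / cosh((grid$x - center) / delta_p)^2
  field_state(rho = rho, u = direction * v_p * rho, time = 0)
}

#' Construct a field state
#'
#' @param rho density-deviation field (primed units), one value per node.
#' @param u velocity-like field, one value per node.
#' @param time dimensionless time stamp.
#' @return object of class `field_state`.
#' @export
field_state <- function(rho, u, time = 0) {
  if (length(rho) != length(u))
    abort("`rho` and `u` must have the same length",
          class = "aquasoliton_error_input")
  if (any(!is.finite(rho)) || any(!is.finite(u)))
    abort("field values must be finite", class = "aquasoliton_error_stability")
  structure(list(rho = as.numeric(rho), u = as.numeric(u), time = time),
            class = "field_state")
}

#' @rdname soliton_family
#' @param x a `soliton` object.
#' @param ... unused.
#' @method tidy soliton
#' @export
tidy.soliton <- function(x, ...) {
  tibble(term = c("A", "abs_A", "delta", "fwhm", "v"),
         value = c(x$A, abs(x$A), x$delta, x$fwhm, x$v))
}

#' @rdname soliton_family
#' @param object a `soliton` object.
#' @method autoplot soliton
#' @export
autoplot.soliton <- function(object, ...) {
  xx <- seq(-4 * object$delta, 4 * object$delta, length.out = 401)
  df <- tibble(x = xx, drho = soliton_profile(object, xx))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$drho)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$A / 2, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "x", y = expression(delta * rho),
                  title = "sech^2 rarefaction pulse",
                  subtitle = sprintf("A = %.3g, delta = %.3g, v = %.3g",
                                     object$A, object$delta, object$v))
}
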
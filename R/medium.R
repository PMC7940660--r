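# Physical parameters of the medium and the map to dimensionless model
# units.  The crossover wavenumber q*, the excitation frequency omega0(q*)
# and the thermal density-fluctuation amplitude A* define the scales
#   x' = q* x,   t' = omega0(q*) t,   drho' = drho / A*,
# under which the damped stochastic Boussinesq equation has coefficients
#   k1' = q*^2 k1 / omega0(q*)^2,   k2' = q*^4 k2 / omega0(q*)^2,
#   alpha' = A* q*^2 alpha / omega0(q*)^2,   nu'_L = 2 Gamma(q*) / omega0(q*).

#' Crossover point of the viscoelastic transition
#'
#' The characteristic wavenumber q* where the viscoelastic transition
#' predominantly takes place (the inflection point of the sound dispersion
#' curve, fixed by inspection rather than auto-detected) together with the
#' excitation frequency there.  omega0(q*) is deliberately an independent
#' input rather than recomputed from fitted coefficients, so that printed
#' crossover frequencies can be used verbatim.
#'
#' @param q_star crossover wavenumber (1/m).
#' @param omega0_star angular excitation frequency at q* (rad/s).
#' @return object of class `crossover_point` with fields `q_star`,
#'   `omega0_star` and the apparent sound velocity `c_star = omega0_star/q_star`.
#' @examples
#' crossover_point(invnm_to_si(2.0), invps_to_si(4.9))
#' @export
crossover_point <- function(q_star, omega0_star) {
  stopifnot_scalar(q_star, "q_star")
  stopifnot_scalar(omega0_star, "omega0_star")
  structure(list(q_star = q_star, omega0_star = omega0_star,
                 c_star = omega0_star / q_star),
            class = "crossover_point")
}

#' @export
print.crossover_point <- function(x, ...) {
  cat(sprintf("<crossover point  q* = %.3g nm^-1, omega0(q*) = %.3g ps^-1, c(q*) = %.4g m/s>\n",
              si_to_invnm(x$q_star), si_to_invps(x$omega0_star), x$c_star))
  invisible(x)
}

#' Physical parameters of the medium
#'
#' Bundles the dimensional inputs of the model: equilibrium density,
#' temperature, acoustic nonlinearity, compressibility, the nonlinear
#' free-energy coefficient alpha, the thermal density-fluctuation amplitude
#' A*, and the damping ratio 2 Gamma(q*)/omega0(q*).
#'
#' @param rho0 equilibrium mass density (kg/m^3).
#' @param temperature absolute temperature (K).
#' @param beta acoustic nonlinearity coefficient (dimensionless, > 1 for
#'   water-like media; about 3.5 for water at room temperature).
#' @param kappa_T isothermal compressibility (1/Pa).  Not directly printed
#'   in most dispersion studies; the default 4.9e-10 is a standard value
#'   for water near 277 K.
#' @param probe_volume volume over which density fluctuations are counted
#'   (m^3); default (1 nm)^3, about the smallest scale examinable outside
#'   the local structure around individual molecules.
#' @param damping_ratio 2 Gamma(q*)/omega0(q*) (dimensionless): about 0.60
#'   for bulk water at room temperature, about 0.32 for DNA/protein
#'   hydration water at low q.
#' @param alpha nonlinearity coefficient of the cubic free-energy term
#'   (m^5/(kg s^2)); computed from `beta` via [nonlinearity_from_beta()]
#'   when a crossover velocity is available, or given directly.
#' @param A_star characteristic density-fluctuation magnitude (kg/m^3);
#'   computed via [thermal_amplitude()] when NULL.
#' @return object of class `medium_parameters`.
#' @export
medium_parameters <- function(rho0 = 1.0e3, temperature = 277, beta = 3.5,
                              kappa_T = 4.9e-10, probe_volume = 1e-27,
                              damping_ratio = 0.60, alpha = NULL,
                              A_star = NULL) {
  for (nm in c("rho0", "temperature", "beta", "kappa_T", "probe_volume",
               "damping_ratio"))
    stopifnot_scalar(get(nm), nm)
  if (beta < 1)
    abort("`beta` must be >= 1 for a water-like medium",
          class = "aquasoliton_error_input")
  if (is.null(A_star))
    A_star <- thermal_amplitude(temperature, kappa_T, probe_volume, rho0)
  out <- list(rho0 = rho0, temperature = temperature, beta = beta,
              kappa_T = kappa_T, probe_volume = probe_volume,
              damping_ratio = damping_ratio, alpha = alpha, A_star = A_star)
  structure(out, class = "medium_parameters")
}

#' @export
print.medium_parameters <- function(x, ...) {
  cat("<medium parameters>\n")
  cat(sprintf("  rho0 = %.4g kg/m^3, T = %.4g K, beta = %.3g, kappa_T = %.3g 1/Pa\n",
              x$rho0, x$temperature, x$beta, x$kappa_T))
  cat(sprintf("  A* = %.4g kg/m^3 (probe volume %.3g m^3)\n",
              x$A_star, x$probe_volume))
  if (!is.null(x$alpha))
    cat(sprintf("  alpha = %.4g m^5/(kg s^2)\n", x$alpha))
  cat(sprintf("  damping ratio nu'_L = 2 Gamma(q*)/omega0(q*) = %.3g\n",
              x$damping_ratio))
  invisible(x)
}

#' Nonlinearity coefficient from the acoustic nonlinearity parameter
#'
#' The coefficient of the cubic term of the free-energy density is
#' identified with the second derivative of pressure with respect to
#' density, alpha = 2 c^2 (beta - 1) / rho0, with c the apparent sound
#' velocity at the crossover.
#'
#' @param beta acoustic nonlinearity coefficient (>= 1).
#' @param c apparent sound velocity at q* (m/s).
#' @param rho0 equilibrium density (kg/m^3).
#' @return alpha in m^5/(kg s^2); zero for a linear medium (beta = 1).
#' @examples
#' nonlinearity_from_beta(3.5, invps_to_si(4.9) / invnm_to_si(2.0), 1e3)
#' @export
nonlinearity_from_beta <- function(beta, c, rho0) {
  stopifnot_scalar(beta, "beta")
  stopifnot_scalar(c, "c")
  stopifnot_scalar(rho0, "rho0")
  if (beta < 1)
    abort("`beta` must be >= 1", class = "aquasoliton_error_input")
  2 * c^2 * (beta - 1) / rho0
}

#' Thermal density-fluctuation amplitude
#'
#' Characteristic magnitude of equilibrium density fluctuations in a probe
#' volume V, from the root-mean-square relative fluctuation of the particle
#' number: A* = rho0 * sqrt(kB T kappa_T / V).  For water near 277 K with
#' V = 1 nm^3 this is about 43 kg/m^3, i.e. 4.3% of the mean density.
#'
#' @param temperature absolute temperature (K).
#' @param kappa_T isothermal compressibility (1/Pa).
#' @param probe_volume probe volume (m^3).
#' @param rho0 equilibrium density (kg/m^3).
#' @return A* in kg/m^3.
#' @export
thermal_amplitude <- function(temperature, kappa_T, probe_volume, rho0) {
  stopifnot_scalar(temperature, "temperature")
  stopifnot_scalar(rho0, "rho0")
  stopifnot_scalar(probe_volume, "probe_volume")
  if (!is.numeric(kappa_T) || length(kappa_T) != 1L || kappa_T < 0)
    abort("`kappa_T` must be a non-negative scalar",
          class = "aquasoliton_error_input")
  rho0 * sqrt(k_boltzmann * temperature * kappa_T / probe_volume)
}

#' Map dimensional parameters to dimensionless model coefficients
#'
#' Applies the scales (q*, omega0(q*), A*) to produce the coefficient set
#' (k1', k2', alpha', nu'_L) of the dimensionless damped stochastic
#' Boussinesq equation.  nu'_L is taken directly from the measured damping
#' ratio of the medium rather than reconstructed from a viscosity.
#'
#' @param coeff `dispersion_coefficients` or `dispersion_fit` (SI units).
#' @param medium `medium_parameters` (must carry `alpha` and `A_star`).
#' @param crossover `crossover_point`.
#' @return object of class `dimensionless_params`: fields `k1p`, `k2p`,
#'   `alphap`, `nuLp` and `scales` (list with `q_star`, `omega_star`,
#'   `A_star`).
#' @examples
#' co <- dispersion_coefficients(3.9e6, 4.8e-13, invnm_to_si(3))
#' cr <- crossover_point(invnm_to_si(2), invps_to_si(4.9))
#' med <- medium_parameters(alpha = 3.0e4)
#' nondimensionalize(co, med, cr)
#' @export
nondimensionalize <- function(coeff, medium, crossover) {
  coeff <- as_coefficients(coeff)
  if (!inherits(medium, "medium_parameters"))
    abort("`medium` must be a medium_parameters object",
          class = "aquasoliton_error_input")
  if (!inherits(crossover, "crossover_point"))
    abort("`crossover` must be a crossover_point object",
          class = "aquasoliton_error_input")
  if (is.null(medium$alpha))
    abort("`medium` must carry `alpha` (set it or use nonlinearity_from_beta)",
          class = "aquasoliton_error_input")
  qs <- crossover$q_star
  ws <- crossover$omega0_star
  structure(list(
    k1p = qs^2 * coeff$k1 / ws^2,
    k2p = qs^4 * coeff$k2 / ws^2,
    alphap = medium$A_star * qs^2 * medium$alpha / ws^2,
    nuLp = medium$damping_ratio,
    scales = list(q_star = qs, omega_star = ws, A_star = medium$A_star)),
    class = "dimensionless_params")
}

#' Construct dimensionless coefficients directly
#'
#' For working purely in model units (identity scales by default).
#'
#' @param k1p,k2p,alphap,nuLp dimensionless coefficients.
#' @param q_star,omega_star,A_star scales mapping primed to SI quantities.
#' @return `dimensionless_params` object.
#' @export
dimensionless_params <- function(k1p, k2p, alphap = 0, nuLp = 0,
                                 q_star = 1, omega_star = 1, A_star = 1) {
  stopifnot_scalar(k1p, "k1p")
  stopifnot_scalar(k2p, "k2p")
  if (alphap < 0 || nuLp < 0)
    abort("`alphap` and `nuLp` must be non-negative",
          class = "aquasoliton_error_input")
  structure(list(k1p = k1p, k2p = k2p, alphap = alphap, nuLp = nuLp,
                 scales = list(q_star = q_star, omega_star = omega_star,
                               A_star = A_star)),
            class = "dimensionless_params")
}

#' @export
print.dimensionless_params <- function(x, ...) {
  cat(sprintf("<dimensionless parameters  k1' = %.4g, k2' = %.4g, alpha' = %.4g, nu'_L = %.3g>\n",
              x$k1p, x$k2p, x$alphap, x$nuLp))
  cat(sprintf("  scales: q* = %.3g nm^-1, omega0(q*) = %.3g ps^-1, A* = %.4g kg/m^3\n",
              si_to_invnm(x$scales$q_star), si_to_invps(x$scales$omega_star),
              x$scales$A_star))
  invisible(x)
}

#' Convert primed (dimensionless) quantities back to SI
#'
#' Inverse of the scale map: x = x'/q*, t = t'/omega0(q*),
#' drho = A* drho', velocities v = v' omega0(q*)/q*.
#'
#' @param dimless `dimensionless_params` object (its `scales` are used).
#' @param x,t,rho,v optional primed quantities to convert.
#' @return named list with the converted SI quantities (only those given).
#' @examples
#' dp <- dimensionless_params(0.65, 0.32, q_star = 2e9, omega_star = 4.9e12, A_star = 43)
#' redimensionalize(dp, t = 4.9)  # -> 1 ps
#' @export
redimensionalize <- function(dimless, x = NULL, t = NULL, rho = NULL,
                             v = NULL) {
  s <- dimless$scales
  out <- list()
  if (!is.null(x)) out$x <- x / s$q_star
  if (!is.null(t)) out$t <- t / s$omega_star
  if (!is.null(rho)) out$rho <- rho * s$A_star
  if (!is.null(v)) out$v <- v * s$omega_star / s$q_star
  out
}

#' Longitudinal kinematic viscosity from the damping ratio
#'
#' Convenience accessor inverting Gamma(q) = (eta_L / 2 rho0) q^2 at the
#' crossover: eta_L/rho0 = damping_ratio * omega0(q*) / q*^2.
#'
#' @param medium `medium_parameters`.
#' @param crossover `crossover_point`.
#' @return kinematic longitudinal viscosity eta_L/rho0 (m^2/s).
#' @export
kinematic_longitudinal_viscosity <- function(medium, crossover) {
  medium$damping_ratio * crossover$omega0_star / crossover$q_star^2
}
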
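# Synthetic inputs: parameter bundles for the literature water cases, and
# noisy dispersion curves emulating the statistical structure of terahertz
# scattering measurements (multiplicative Gaussian noise on omega0).

# Printed coefficient sets for the water cases:
#   I   inelastic X-ray scattering, water ~278 K
#   II  molecular-dynamics SPC/E heavy water at its density maximum
#   III supercooled water 250 K, coefficients from the exact two-reference-
#       point construction (low-q sound speed + crossover-edge sound speed)
case_constants <- list(
  I = list(k1 = 3.9e6, k2 = 4.8e-13, q_u_invnm = 3.0,
           q_star_invnm = 2.0, omega0_star_invps = 4.9,
           temperature = 277, damping_ratio = 0.60),
  II = list(k1 = 3.2e6, k2 = 7.7e-13, q_u_invnm = 3.1,
            q_star_invnm = 2.5, omega0_star_invps = 6.8,
            temperature = 277, damping_ratio = 0.60),
  III = list(k1 = 1.8e6, k2 = 1.2e-12, q_u_invnm = 3.0,
             temperature = 250,
             two_point = list(q_invnm = c(0.023, 3.0),
                              c_m_per_s = c(1.3e3, 3.5e3))),
  `hydration-DNA` = list(base = "I", damping_ratio = 0.32,
                         temperature = 300)
)

#' Parameter bundle for a literature water case
#'
#' Builds the full chain of objects for one of the studied cases:
#' dispersion coefficients, crossover point, medium parameters (with the
#' nonlinearity alpha computed from beta = 3.5 at the crossover velocity
#' and the thermal amplitude A* from the compressibility), and the
#' dimensionless coefficient set.
#'
#' Cases: `"I"` (bulk water ~278 K, X-ray scattering), `"II"` (SPC/E
#' heavy-water simulation at the density maximum), `"III"` (supercooled
#' water 250 K; coefficients from the two-reference-point construction, no
#' crossover scales), and `"hydration-DNA"` (case-I coefficients with the
#' low-q damping ratio 0.32 of DNA/protein hydration water).
#'
#' @param label case label; `"hydration"` is accepted as an alias.
#' @param kappa_T isothermal compressibility override (1/Pa).
#' @return object of class `case_bundle`: list with `label`,
#'   `coefficients`, `crossover`, `medium`, `dimless` (NULL for case III),
#'   and for case III also `two_point_fit`, the package's own exact
#'   two-point solve alongside the printed coefficients.
#' @examples
#' make_case("I")$dimless$k2p  # ~0.32
#' @export
make_case <- function(label = c("I", "II", "III", "hydration-DNA",
                                "hydration"),
                      kappa_T = 4.9e-10) {
  label <- match.arg(label)
  if (label == "hydration") label <- "hydration-DNA"
  cc <- case_constants[[label]]
  if (!is.null(cc$base)) {
    base <- case_constants[[cc$base]]
    base$damping_ratio <- cc$damping_ratio
    base$temperature <- cc$temperature
    cc <- base
  }
  coeff <- dispersion_coefficients(cc$k1, cc$k2,
                                   q_max_valid = invnm_to_si(cc$q_u_invnm))
  crossover <- NULL
  medium <- NULL
  dimless <- NULL
  if (!is.null(cc$q_star_invnm)) {
    crossover <- crossover_point(invnm_to_si(cc$q_star_invnm),
                                 invps_to_si(cc$omega0_star_invps))
    # thermal amplitude uses 277 K water throughout (the hydration case
    # keeps the bulk-water fluctuation scale of the reference estimate)
    medium <- medium_parameters(temperature = 277, kappa_T = kappa_T,
                                damping_ratio = cc$damping_ratio)
    medium$alpha <- nonlinearity_from_beta(medium$beta, crossover$c_star,
                                           medium$rho0)
    dimless <- nondimensionalize(coeff, medium, crossover)
  }
  out <- list(label = label, coefficients = coeff, crossover = crossover,
              medium = medium, dimless = dimless)
  if (!is.null(cc$two_point)) {
    tp <- cc$two_point
    pts <- dispersion_points(
      q_invnm = tp$q_invnm,
      omega0_invps = tp$c_m_per_s * invnm_to_si(tp$q_invnm) / 1e12)
    out$two_point_fit <- fit_dispersion(pts, mode = "exact_two_point")
  }
  structure(out, class = "case_bundle")
}

#' @export
print.case_bundle <- function(x, ...) {
  cat(sprintf("<case %s>\n", x$label))
  print(x$coefficients)
  if (!is.null(x$crossover)) print(x$crossover)
  if (!is.null(x$dimless)) print(x$dimless)
  if (!is.null(x$two_point_fit)) {
    cat("  exact two-point solve from the printed (q, c) pairs:\n")
    print(x$two_point_fit$coefficients)
  }
  invisible(x)
}

#' Synthesize a noisy dispersion curve
#'
#' Generates (q, omega0) points from a known q^2 + q^4 law with
#' multiplicative Gaussian noise, omega0 = sqrt(k1 q^2 + k2 q^4)(1 + sigma
#' xi): relative noise matches how dispersion uncertainties from scattering
#' spectra scale.  Draws that would produce omega0 <= 0 are redrawn (and
#' counted in `attr(, "n_redraws")`).
#'
#' @param k1,k2 true coefficients (SI).
#' @param q_min,q_max wavenumber range (1/m); points equally spaced.
#' @param n_points number of points.
#' @param relative_noise multiplicative noise level sigma (default 0.02).
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return tibble as from [dispersion_points()], with attributes
#'   `truth` (list with k1, k2) and `n_redraws`.
#' @export
synth_dispersion <- function(k1, k2, q_min, q_max, n_points,
                             relative_noise = 0.02, seed = NULL) {
  stopifnot_scalar(k1, "k1")
  stopifnot_scalar(k2, "k2")
  if (relative_noise < 0)
    abort("`relative_noise` must be >= 0", class = "aquasoliton_error_input")
  q <- seq(q_min, q_max, length.out = n_points)
  w_true <- sqrt(k1 * q^2 + k2 * q^4)
  n_redraws <- 0L
  w <- with_seed(seed, {
    w <- w_true * (1 + relative_noise * rnorm(n_points))
    while (any(bad <- w <= 0)) {
      n_redraws <- n_redraws + sum(bad)
      w[bad] <- w_true[bad] * (1 + relative_noise * rnorm(sum(bad)))
    }
    w
  })
  out <- dispersion_points(q = q, omega0 = w)
  attr(out, "truth") <- list(k1 = k1, k2 = k2)
  attr(out, "n_redraws") <- n_redraws
  out
}

#' Parameter-recovery experiment on synthetic dispersion data
#'
#' Repeatedly synthesizes a noisy dispersion curve and refits it, then
#' summarizes bias and root-mean-square error of the recovered (k1, k2).
#'
#' @inheritParams synth_dispersion
#' @param n_replicates number of synthesize-and-fit replicates.
#' @param seed master seed; replicate seeds are derived from it.
#' @param mode,space passed to [fit_dispersion()].
#' @return object of class `recovery_report`: list with `estimates`
#'   (tibble: replicate, k1, k2), `summary` (tibble: term, true, mean
#'   estimate, bias, rel_bias, rmse), `n_replicates`, `seed`.
#' @export
recovery_experiment <- function(k1, k2, q_min, q_max, n_points,
                                relative_noise = 0.02, n_replicates = 100,
                                seed = 1L, mode = "least_squares",
                                space = "omega2") {
  if (n_replicates < 1)
    abort("`n_replicates` must be >= 1", class = "aquasoliton_error_input")
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                          n_replicates))
  est <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    pts <- synth_dispersion(k1, k2, q_min, q_max, n_points,
                            relative_noise, seed = sub_seeds[i])
    fit <- fit_dispersion(pts, mode = mode, space = space)
    tibble(replicate = i, k1 = fit$coefficients$k1, k2 = fit$coefficients$k2)
  })
  summ <- purrr::map_dfr(c("k1", "k2"), function(term) {
    truth <- if (term == "k1") k1 else k2
    e <- est[[term]]
    tibble(term = term, true = truth, estimate = mean(e),
           bias = mean(e) - truth, rel_bias = (mean(e) - truth) / truth,
           rmse = sqrt(mean((e - truth)^2)))
  })
  structure(list(estimates = est, summary = summ,
                 n_replicates = n_replicates, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery report  %d replicates, seed %s>\n",
              x$n_replicates, format(x$seed)))
  print(x$summary)
  invisible(x)
}

#' @rdname recovery_experiment
#' @param x a `recovery_report`.
#' @param ... unused.
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) x$summary
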
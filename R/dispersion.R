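# Dispersion law of the terahertz longitudinal acoustic-like mode:
#   omega0^2(q) = k1 q^2 + k2 q^4,   valid for q below the upper bound of
# the viscoelastic crossover region.  k1 sets the long-wavelength (squared)
# sound speed; the positive k2 term encodes the upward bending of
# omega0(q)/q ("positive sound dispersion") towards the high-frequency
# sound speed.

#' Build a table of dispersion points
#'
#' Constructs the tabular representation of a dispersion curve: one row per
#' measured (wavenumber, excitation frequency) point.  All downstream
#' functions take this tibble.  Inputs may be given either in SI units
#' (`q` in 1/m, `omega0` in rad/s) or in the units dispersion curves are
#' usually published in (`q_invnm` in nm^-1, `omega0_invps` in ps^-1).
#'
#' @param q,omega0 numeric vectors, wavenumber (1/m) and angular excitation
#'   frequency (rad/s).
#' @param q_invnm,omega0_invps alternative input in nm^-1 / ps^-1; converted
#'   to SI.  Supply either the SI pair or this pair, not both.
#' @return a tibble with columns `q` (1/m) and `omega0` (rad/s).
#' @examples
#' dispersion_points(q_invnm = c(1, 2, 3), omega0_invps = c(2.1, 4.9, 8.6))
#' @export
dispersion_points <- function(q = NULL, omega0 = NULL,
                              q_invnm = NULL, omega0_invps = NULL) {
  si_given <- !is.null(q) || !is.null(omega0)
  paper_given <- !is.null(q_invnm) || !is.null(omega0_invps)
  if (si_given && paper_given)
    abort("supply either (q, omega0) in SI or (q_invnm, omega0_invps), not both",
          class = "aquasoliton_error_input")
  if (paper_given) {
    q <- invnm_to_si(q_invnm)
    omega0 <- invps_to_si(omega0_invps)
  }
  if (is.null(q) || is.null(omega0) || length(q) != length(omega0))
    abort("`q` and `omega0` must be numeric vectors of equal length",
          class = "aquasoliton_error_input")
  if (any(!is.finite(q)) || any(!is.finite(omega0)) ||
      any(q <= 0) || any(omega0 < 0))
    abort("dispersion points require q > 0 and omega0 >= 0",
          class = "aquasoliton_error_input")
  tibble(q = as.numeric(q), omega0 = as.numeric(omega0))
}

#' Read a dispersion table from CSV
#'
#' Expects the columnar text format with header `q_invnm,omega0_invps`
#' (wavenumber in nm^-1, angular frequency in ps^-1) and converts to SI.
#'
#' @param file path to a CSV file.
#' @return tibble as from [dispersion_points()].
#' @export
read_dispersion_csv <- function(file) {
  d <- read.csv(file)
  if (!all(c("q_invnm", "omega0_invps") %in% names(d)))
    abort("dispersion CSV must have columns `q_invnm` and `omega0_invps`",
          class = "aquasoliton_error_input")
  dispersion_points(q_invnm = d$q_invnm, omega0_invps = d$omega0_invps)
}

#' Write a dispersion table to CSV
#'
#' @param points tibble from [dispersion_points()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_dispersion_csv <- function(points, file) {
  d <- data.frame(q_invnm = si_to_invnm(points$q),
                  omega0_invps = si_to_invps(points$omega0))
  utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Construct dispersion coefficients directly
#'
#' @param k1 coefficient of q^2 (m^2/s^2); the long-wavelength sound speed
#'   is sqrt(k1).
#' @param k2 coefficient of q^4 (m^4/s^2); drives the positive sound
#'   dispersion.
#' @param q_max_valid upper validity bound of the q^2 + q^4 law (1/m),
#'   typically the upper edge of the viscoelastic crossover region.
#' @return an object of class `dispersion_coefficients`.
#' @export
dispersion_coefficients <- function(k1, k2, q_max_valid = Inf) {
  stopifnot_scalar(k1, "k1")
  stopifnot_scalar(k2, "k2")
  if (!is.numeric(q_max_valid) || length(q_max_valid) != 1L || q_max_valid <= 0)
    abort("`q_max_valid` must be a positive scalar (possibly Inf)",
          class = "aquasoliton_error_input")
  structure(list(k1 = k1, k2 = k2, q_max_valid = q_max_valid),
            class = "dispersion_coefficients")
}

#' @export
print.dispersion_coefficients <- function(x, ...) {
  cat("<dispersion coefficients  omega0^2 = k1 q^2 + k2 q^4>\n")
  cat(sprintf("  k1 = %.4g m^2/s^2   (sqrt(k1) = %.4g m/s)\n", x$k1, sqrt(x$k1)))
  cat(sprintf("  k2 = %.4g m^4/s^2\n", x$k2))
  cat(sprintf("  valid for q <= %.4g 1/m (%.3g nm^-1)\n",
              x$q_max_valid, si_to_invnm(x$q_max_valid)))
  invisible(x)
}

as_coefficients <- function(coeff) {
  if (inherits(coeff, "dispersion_fit")) coeff$coefficients
  else if (inherits(coeff, "dispersion_coefficients")) coeff
  else abort("expected a `dispersion_coefficients` or `dispersion_fit` object",
             class = "aquasoliton_error_input")
}

#' Fit the q^2 + q^4 dispersion law
#'
#' Estimates (k1, k2) in omega0^2(q) = k1 q^2 + k2 q^4.  The default mode is
#' a linear least-squares fit of omega0^2 against the regressors (q^2, q^4);
#' fitting in omega0^2 space makes the problem linear in the coefficients.
#' A nonlinear fit in omega0 space is available via `space = "omega"` (the
#' two choices coincide for noiseless data and for two-point interpolation).
#' `mode = "exact_two_point"` solves the 2x2 linear system through exactly
#' two reference points, the procedure used to extrapolate coefficients for
#' supercooled water from a low-q sound speed and the crossover-edge sound
#' speed.
#'
#' @param points tibble from [dispersion_points()] (columns `q`, `omega0`).
#' @param mode `"least_squares"` (default) or `"exact_two_point"`.
#' @param space `"omega2"` (default; linear fit of omega0^2) or `"omega"`
#'   (nonlinear least squares on omega0, Gauss-Newton refinement started
#'   from the omega2 solution).
#' @return an object of class `dispersion_fit` with elements
#'   `coefficients` (a [dispersion_coefficients()] object with
#'   `q_max_valid` set to the largest input q), `mode`, `space`, `points`,
#'   and for least-squares fits the underlying `lm` object.
#' @examples
#' pts <- dispersion_points(q_invnm = c(0.023, 3), omega0_invps = c(0.023 * 1.3, 3 * 3.5))
#' fit_dispersion(pts, mode = "exact_two_point")
#' @export
fit_dispersion <- function(points,
                           mode = c("least_squares", "exact_two_point"),
                           space = c("omega2", "omega")) {
  mode <- match.arg(mode)
  space <- match.arg(space)
  q <- points$q
  w <- points$omega0
  if (length(unique(q)) < 2L)
    abort("degenerate input: need at least two distinct wavenumbers",
          class = "aquasoliton_error_degenerate")

  # fit with wavenumbers rescaled by their maximum: in SI units q^2 and q^4
  # regressors span ~20 decades, which is numerically hopeless unscaled
  qs <- max(q)
  qn <- q / qs
  se_scaled <- NULL
  if (mode == "exact_two_point") {
    if (length(q) != 2L)
      abort("exact_two_point mode requires exactly two points",
            class = "aquasoliton_error_input")
    # omega0^2/q^2 = k1 + k2 q^2 is linear in q^2: exact interpolation
    y <- (w / q)^2
    k2 <- (y[2] - y[1]) / (q[2]^2 - q[1]^2)
    k <- c(y[1] - k2 * q[1]^2, k2)
    lmfit <- NULL
  } else {
    q2 <- qn^2
    q4 <- qn^4
    y <- w^2
    lmfit <- lm(y ~ 0 + q2 + q4)
    k <- unname(coef(lmfit))
    se_scaled <- suppressWarnings(unname(sqrt(diag(stats::vcov(lmfit)))))
    if (space == "omega") {
      # Gauss-Newton on residuals omega0 - sqrt(k1 q^2 + k2 q^4)
      for (it in 1:50) {
        pred <- sqrt(pmax(k[1] * q2 + k[2] * q4, 0))
        ok <- pred > 0
        jac <- cbind(q2[ok] / (2 * pred[ok]), q4[ok] / (2 * pred[ok]))
        step <- tryCatch(solve(crossprod(jac), crossprod(jac, w[ok] - pred[ok])),
                         error = function(e) NULL)
        if (is.null(step)) break
        k <- k + as.numeric(step)
        if (max(abs(step) / pmax(abs(k), 1e-300)) < 1e-14) break
      }
      se_scaled <- NULL
    }
    k <- k / c(qs^2, qs^4)
    if (!is.null(se_scaled)) se_scaled <- se_scaled / c(qs^2, qs^4)
  }
  if (any(!is.finite(k)) || any(k <= 0))
    abort(sprintf(paste0("non-physical fit: coefficients must be positive ",
                         "(got k1 = %.4g, k2 = %.4g)"), k[1], k[2]),
          class = "aquasoliton_error_nonphysical")
  structure(
    list(coefficients = dispersion_coefficients(k[1], k[2],
                                                q_max_valid = max(q)),
         mode = mode, space = space, points = points, lm = lmfit,
         std.error = se_scaled),
    class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf("<dispersion fit  mode = %s, space = %s, n = %d>\n",
              x$mode, x$space, nrow(x$points)))
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_dispersion
#' @param x a `dispersion_fit` object.
#' @param ... unused.
#' @method tidy dispersion_fit
#' @export
tidy.dispersion_fit <- function(x, ...) {
  k <- x$coefficients
  se <- x$std.error %||% c(NA_real_, NA_real_)
  tibble(term = c("k1", "k2"),
         estimate = c(k$k1, k$k2),
         std.error = se,
         unit = c("m^2/s^2", "m^4/s^2"))
}

#' @rdname fit_dispersion
#' @method glance dispersion_fit
#' @export
glance.dispersion_fit <- function(x, ...) {
  pred <- omega0(x$points$q, x$coefficients, warn = FALSE)
  res <- x$points$omega0 - pred
  tibble(nobs = nrow(x$points),
         mode = x$mode,
         space = x$space,
         rmse_omega0 = sqrt(mean(res^2)),
         q_max_valid = x$coefficients$q_max_valid)
}

#' Evaluate the dispersion law
#'
#' omega0(q) = sqrt(k1 q^2 + k2 q^4).  The law has no physical meaning above
#' the crossover bound `q_max_valid`; evaluation there is flagged with a
#' warning.
#'
#' @param q wavenumber(s), 1/m; must be non-negative.
#' @param coeff a `dispersion_coefficients` or `dispersion_fit` object.
#' @param warn warn when evaluating above `q_max_valid` (default TRUE).
#' @return angular frequency (rad/s), same length as `q`.
#' @export
omega0 <- function(q, coeff, warn = TRUE) {
  coeff <- as_coefficients(coeff)
  if (any(q < 0))
    abort("`q` must be non-negative", class = "aquasoliton_error_input")
  if (warn && any(q > coeff$q_max_valid))
    warn(sprintf(paste0("evaluating the q^2 + q^4 law above its validity ",
                        "bound q_max_valid = %.4g 1/m"), coeff$q_max_valid),
         class = "aquasoliton_warning_validity")
  sqrt(coeff$k1 * q^2 + coeff$k2 * q^4)
}

#' Apparent (q-dependent) sound velocity
#'
#' c(q) = omega0(q)/q.  For k2 > 0 this increases with q from the
#' long-wavelength sound speed sqrt(k1): the positive sound dispersion of
#' the viscoelastic crossover.
#'
#' @param q wavenumber(s), 1/m; strictly positive.
#' @param coeff a `dispersion_coefficients`/`dispersion_fit` object, or NULL
#'   when `omega0_value` is supplied directly.
#' @param omega0_value optional angular frequency (rad/s) to use instead of
#'   evaluating the law, for the common case where a printed omega0(q*) is
#'   taken as an independent input.
#' @param warn passed to [omega0()].
#' @return velocity in m/s.
#' @examples
#' apparent_velocity(invnm_to_si(2.0), omega0_value = invps_to_si(4.9))
#' @export
apparent_velocity <- function(q, coeff = NULL, omega0_value = NULL,
                              warn = TRUE) {
  if (any(q <= 0))
    abort("apparent velocity requires q > 0",
          class = "aquasoliton_error_domain")
  w <- if (!is.null(omega0_value)) omega0_value else omega0(q, coeff, warn = warn)
  w / q
}

#' @rdname fit_dispersion
#' @param object a `dispersion_fit` object.
#' @method autoplot dispersion_fit
#' @export
autoplot.dispersion_fit <- function(object, ...) {
  pts <- object$points
  qq <- seq(min(pts$q), max(pts$q), length.out = 200)
  curve_df <- tibble(q_invnm = si_to_invnm(qq),
                     omega0_invps = si_to_invps(omega0(qq, object,
                                                       warn = FALSE)))
  pts_df <- tibble(q_invnm = si_to_invnm(pts$q),
                   omega0_invps = si_to_invps(pts$omega0))
  ggplot2::ggplot(pts_df, ggplot2::aes(.data$q_invnm, .data$omega0_invps)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve_df, colour = "firebrick") +
    ggplot2::labs(x = expression(q ~ (nm^-1)),
                  y = expression(omega[0] ~ (ps^-1)),
                  title = "Dispersion of the longitudinal acoustic-like mode")
}
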
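# End-to-end orchestration: regeneration of every closed-form estimate for
# the literature water cases, and the noise-persistence ensemble experiment.

# printed reference values for the reproduction report
paper_values <- list(
  I = c(alpha = 3.0e4, A_star = 43, k1p = 0.65, k2p = 0.32, alphap = 0.22,
        abs_A = 3.9e2, delta_nm = 0.70, fwhm_nm = 1.2,
        delta_thermal_nm = 2.1, fwhm_thermal_nm = 3.7, v_thermal = 1.9e3,
        delta_two_point_nm = 1.3),
  II = c(alpha = 3.7e4, A_star = 43, k1p = 0.44, k2p = 0.65, alphap = 0.22,
         abs_A = 2.6e2, delta_nm = 0.97, fwhm_nm = 1.7,
         delta_thermal_nm = 2.4, fwhm_thermal_nm = 4.2, v_thermal = 1.6e3),
  III = c(k1_two_point = 1.8e6, k2_two_point = 1.2e-12, delta_nm = 1.6)
)

# printed case-I variant fitted through the same two reference wavenumbers
# as case III (used for the temperature comparison of delta)
case_I_two_point <- list(k1 = 1.8e6, k2 = 7.3e-13)

#' Regenerate the closed-form estimates for the water cases
#'
#' Recomputes, from the printed dispersion coefficients and crossover
#' inputs, every closed-form quantity of the analysis: the nonlinearity
#' alpha, thermal amplitude A*, dimensionless coefficients, the
#' stationary-soliton amplitude/width/FWHM, the thermal-amplitude
#' (|A| = A*) traveling-soliton width/FWHM/velocity, and for supercooled
#' water the exact two-point coefficient estimates and the stationary
#' width.  Each row carries the published value and the relative
#' difference, so that genuine reproduction and documented rounding
#' discrepancies stay distinguishable.
#'
#' @param cases character vector of case labels (default I, II, III).
#' @return tibble with columns `case`, `quantity`, `value`, `unit`,
#'   `paper_value`, `rel_diff`, `formula`.
#' @examples
#' reproduce_estimates("I")
#' @export
reproduce_estimates <- function(cases = c("I", "II", "III")) {
  empty <- tibble(case = character(), quantity = character(),
                  value = numeric(), unit = character(),
                  paper_value = numeric(), rel_diff = numeric(),
                  formula = character())
  if (length(cases) == 0) return(empty)
  rows <- purrr::map_dfr(cases, function(lab) {
    cb <- make_case(lab)
    pv <- paper_values[[lab]]
    if (lab == "III") {
      tp <- cb$two_point_fit$coefficients
      sol <- stationary_soliton(cb$coefficients, alpha = 1)  # delta only
      return(tibble(
        case = lab,
        quantity = c("k1_two_point", "k2_two_point", "delta_nm"),
        value = c(tp$k1, tp$k2, sol$delta * 1e9),
        unit = c("m^2/s^2", "m^4/s^2", "nm"),
        paper_value = unname(pv[c("k1_two_point", "k2_two_point",
                                  "delta_nm")]),
        formula = c("2x2 solve of omega0^2 = k1 q^2 + k2 q^4",
                    "2x2 solve of omega0^2 = k1 q^2 + k2 q^4",
                    "2 sqrt(k2/k1), printed coefficients")))
    }
    med <- cb$medium
    dl <- cb$dimless
    sol0 <- stationary_soliton(cb$coefficients, alpha = med$alpha)
    dtherm <- delta_from_amplitude(med$A_star, cb$coefficients$k2,
                                   med$alpha, k1 = cb$coefficients$k1)
    solt <- soliton_family(dtherm, cb$coefficients, alpha = med$alpha)
    q <- c(alpha = med$alpha, A_star = med$A_star, k1p = dl$k1p,
           k2p = dl$k2p, alphap = dl$alphap,
           abs_A = abs(sol0$A), delta_nm = sol0$delta * 1e9,
           fwhm_nm = sol0$fwhm * 1e9,
           delta_thermal_nm = solt$delta * 1e9,
           fwhm_thermal_nm = solt$fwhm * 1e9, v_thermal = solt$v)
    f <- c(alpha = "2 c(q*)^2 (beta - 1) / rho0",
           A_star = "rho0 sqrt(kB T kappa_T / V)",
           k1p = "q*^2 k1 / omega0(q*)^2", k2p = "q*^4 k2 / omega0(q*)^2",
           alphap = "A* q*^2 alpha / omega0(q*)^2",
           abs_A = "3 k1 / alpha", delta_nm = "2 sqrt(k2/k1)",
           fwhm_nm = "2 acosh(sqrt 2) delta",
           delta_thermal_nm = "sqrt(12 k2 / (alpha A*))",
           fwhm_thermal_nm = "2 acosh(sqrt 2) delta",
           v_thermal = "sqrt(k1 - 4 k2 / delta^2)")
    u <- c(alpha = "m^5/(kg s^2)", A_star = "kg/m^3", k1p = "", k2p = "",
           alphap = "", abs_A = "kg/m^3", delta_nm = "nm", fwhm_nm = "nm",
           delta_thermal_nm = "nm", fwhm_thermal_nm = "nm",
           v_thermal = "m/s")
    out <- tibble(case = lab, quantity = names(q), value = unname(q),
                  unit = unname(u), paper_value = unname(pv[names(q)]),
                  formula = unname(f))
    if (lab == "I") {
      d2 <- 2 * sqrt(case_I_two_point$k2 / case_I_two_point$k1) * 1e9
      out <- dplyr::bind_rows(out, tibble(
        case = lab, quantity = "delta_two_point_nm", value = d2,
        unit = "nm", paper_value = unname(pv["delta_two_point_nm"]),
        formula = "2 sqrt(k2/k1), printed two-point coefficients"))
    }
    out
  })
  dplyr::mutate(rows,
                rel_diff = (.data$value - .data$paper_value) /
                  .data$paper_value,
                .after = "paper_value")
}

#' Noise-persistence ensemble experiment
#'
#' Runs the stationary damped soliton of a case under thermal forcing for
#' an ensemble of seeds, for each damping ratio in `nu_values`, and
#' summarizes how long the analytic profile remains a good approximation:
#' the median relative L2 deviation at a reference time and the median
#' first-crossing ("persistence") time of a deviation threshold, with
#' bootstrap confidence intervals and the ratio of medians between damping
#' ratios (hydration-water damping 0.32 versus bulk 0.60).
#'
#' @param case case label for the coefficient set (default "I").
#' @param nu_values damping ratios nu'_L to compare.
#' @param n_seeds ensemble size per damping ratio.
#' @param preset `"reduced"` (dx' = 2e-2, dt' = 4e-5, window to t' = 12) or
#'   `"paper"` (dx' = 1e-2, dt' = 2.5e-5, window to t' = 4.9, the reference
#'   lattice).  Note that under the node-literal forcing the coarser
#'   lattice carries more long-wavelength noise power, so reduced-preset
#'   deviations are systematically larger; within one preset comparisons
#'   across nu'_L are consistent.
#' @param t_end end of the simulated window (dimensionless); NULL takes the
#'   preset default.
#' @param t_ref reference time for the deviation summary (default 4.9,
#'   i.e. 1 ps for case I).
#' @param threshold relative L2 threshold defining persistence
#'   (default 0.05).
#' @param seed master seed; per-run solver seeds derive from it.
#' @param n_boot bootstrap resamples for the CIs (0 disables).
#' @return object of class `persistence_experiment`: list with
#'   `deviations` (tibble: nu, seed, time, l2, collapsed), `summary` (tibble: nu,
#'   n_seeds, median_dev_at_ref, dev_ci_lo/hi, median_persistence,
#'   pers_ci_lo/hi), `ratio` (tibble comparing the first two nu values),
#'   plus the experiment parameters.
#' @export
persistence_experiment <- function(case = "I", nu_values = c(0.60, 0.32),
                                   n_seeds = 8,
                                   preset = c("reduced", "paper"),
                                   t_end = NULL, t_ref = 4.9,
                                   threshold = 0.05, seed = 1L,
                                   n_boot = 999) {
  preset <- match.arg(preset)
  p <- switch(preset,
              reduced = list(dx = 2e-2, dt = 4e-5, t_end = 12),
              paper = list(dx = 1e-2, dt = 2.5e-5, t_end = 4.9))
  t_end <- t_end %||% p$t_end
  cb <- make_case(case)
  grid <- grid_1d(120, dx = p$dx)
  save_every <- max(1L, round(0.245 / p$dt))
  n_steps <- ceiling(t_end / p$dt)
  # make the snapshot grid land on t_ref
  n_steps <- as.integer(ceiling(n_steps / save_every) * save_every)

  runs <- tidyr::expand_grid(nu = nu_values, seed_idx = seq_len(n_seeds))
  dev_list <- purrr::pmap(runs, function(nu, seed_idx) {
    dl <- cb$dimless
    dl$nuLp <- nu
    sol <- stationary_soliton(dl)
    init <- soliton_initial_state(sol, grid)
    cfg <- solver_config(dl, dt = p$dt, n_steps = n_steps,
                         save_every = save_every, noise = TRUE,
                         seed = seed * 1e5 + match(nu, nu_values) * 1e3 +
                           seed_idx,
                         dx = p$dx, on_instability = "truncate")
    traj <- withCallingHandlers(
      simulate_spde(init, grid, cfg),
      aquasoliton_warning_instability = function(w)
        invokeRestart("muffleWarning"))
    dev <- deviation_series(traj, sol)
    tibble(nu = nu, seed = seed_idx, time = dev$time, l2 = dev$l2,
           collapsed = isTRUE(traj$truncated))
  })
  deviations <- dplyr::bind_rows(dev_list)

  # a trajectory ending in nonlinear collapse has certainly left the
  # soliton: if the threshold was somehow not crossed before truncation,
  # the truncation time bounds the persistence time from above
  per_run <- deviations |>
    dplyr::group_by(.data$nu, .data$seed) |>
    dplyr::summarise(
      dev_at_ref = approx(.data$time, .data$l2, xout = t_ref, rule = 2)$y,
      persistence = {
        pt <- persistence_time(
          data.frame(time = .data$time, l2 = .data$l2), threshold)
        if (any(.data$collapsed)) min(pt, max(.data$time)) else pt
      },
      collapsed = any(.data$collapsed),
      .groups = "drop")

  boot_ci <- function(v) {
    if (n_boot < 1 || length(v) < 2) return(c(NA_real_, NA_real_))
    bm <- vapply(seq_len(n_boot), function(b)
      median(sample(v, length(v), replace = TRUE)), 1)
    unname(quantile(bm, c(0.025, 0.975), names = FALSE, type = 1))
  }
  summary <- with_seed(seed, {
    purrr::map_dfr(nu_values, function(nu) {
      d <- per_run[per_run$nu == nu, ]
      dci <- boot_ci(d$dev_at_ref)
      pci <- boot_ci(d$persistence)
      tibble(nu = nu, n_seeds = nrow(d),
             median_dev_at_ref = median(d$dev_at_ref),
             dev_ci_lo = dci[1], dev_ci_hi = dci[2],
             median_persistence = median(d$persistence),
             pers_ci_lo = pci[1], pers_ci_hi = pci[2])
    })
  })
  ratio <- NULL
  if (length(nu_values) >= 2) {
    a <- per_run[per_run$nu == nu_values[2], ]$persistence
    b <- per_run[per_run$nu == nu_values[1], ]$persistence
    # both censored at the window end gives an undefined ratio, not 1
    safe_ratio <- function(x, y)
      ifelse(is.infinite(x) & is.infinite(y), NA_real_, x / y)
    rhat <- safe_ratio(median(a), median(b))
    rci <- c(NA_real_, NA_real_)
    if (n_boot >= 1 && length(a) > 1 && length(b) > 1 && !is.na(rhat)) {
      rci <- with_seed(seed + 1, {
        rb <- vapply(seq_len(n_boot), function(i)
          safe_ratio(median(sample(a, replace = TRUE)),
                     median(sample(b, replace = TRUE))), 1)
        unname(quantile(rb, c(0.025, 0.975), names = FALSE, type = 1,
                        na.rm = TRUE))
      })
    }
    ratio <- tibble(nu_num = nu_values[2], nu_den = nu_values[1],
                    ratio_of_median_persistence = rhat,
                    ci_lo = rci[1], ci_hi = rci[2])
  }
  structure(list(deviations = deviations, per_run = per_run,
                 summary = summary, ratio = ratio, case = case,
                 preset = preset, dx = p$dx, dt = p$dt, t_end = t_end,
                 t_ref = t_ref, threshold = threshold, seed = seed),
            class = "persistence_experiment")
}

#' @export
print.persistence_experiment <- function(x, ...) {
  cat(sprintf("<persistence experiment  case %s, preset %s (dx' = %g, dt' = %g), t' to %g>\n",
              x$case, x$preset, x$dx, x$dt, x$t_end))
  print(x$summary)
  if (!is.null(x$ratio)) {
    cat(sprintf("  ratio of median persistence times (nu' = %g vs %g): %.3g",
                x$ratio$nu_num, x$ratio$nu_den,
                x$ratio$ratio_of_median_persistence))
    if (!is.na(x$ratio$ci_lo))
      cat(sprintf("  [%.3g, %.3g]", x$ratio$ci_lo, x$ratio$ci_hi))
    cat("\n")
  }
  invisible(x)
}

#' @rdname persistence_experiment
#' @param object a `persistence_experiment`.
#' @param ... unused.
#' @method autoplot persistence_experiment
#' @export
autoplot.persistence_experiment <- function(object, ...) {
  ggplot2::ggplot(object$deviations,
                  ggplot2::aes(.data$time, .data$l2,
                               group = interaction(.data$nu, .data$seed),
                               colour = factor(.data$nu))) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "t'", y = "relative L2 deviation",
                  colour = expression(nu * "'"[L]),
                  title = "Soliton persistence under thermal forcing")
}

#' @rdname persistence_experiment
#' @param x a `persistence_experiment`.
#' @method tidy persistence_experiment
#' @export
tidy.persistence_experiment <- function(x, ...) x$summary
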
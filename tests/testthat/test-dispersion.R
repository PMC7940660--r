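test_that("noiseless fits recover the generating coefficients to machine precision", {
  set.seed(11)
  for (i in 1:5) {
    # scales spanning model units to SI, with both terms contributing
    k1 <- 10^runif(1, -1, 7)
    q_max <- 10^sample(c(0, 9), 1)
    k2 <- k1 / q_max^2 * 10^runif(1, -1.5, 1.5)
    q <- seq(q_max / 3, q_max, length.out = 7)
    pts <- dispersion_points(q = q, omega0 = sqrt(k1 * q^2 + k2 * q^4))
    fit <- fit_dispersion(pts)
    expect_lt(abs(fit$coefficients$k1 - k1) / k1, 1e-10)
    expect_lt(abs(fit$coefficients$k2 - k2) / k2, 1e-10)
    expect_equal(fit$coefficients$q_max_valid, max(q))
  }
  # model-unit identity case
  q <- c(1, 2, 3)
  fit <- fit_dispersion(dispersion_points(q = q, omega0 = sqrt(q^2 + q^4)))
  expect_equal(fit$coefficients$k1, 1, tolerance = 1e-12)
  expect_equal(fit$coefficients$k2, 1, tolerance = 1e-12)
})

test_that("omega0^2-space least squares agrees with a brute-force grid search", {
  pts <- synth_dispersion(1, 1, q_min = 0.5, q_max = 3, n_points = 12,
                          relative_noise = 0.05, seed = 3)
  fit <- fit_dispersion(pts)
  k1f <- fit$coefficients$k1
  k2f <- fit$coefficients$k2
  oracle <- grid_search_fit(pts, k1f + c(-0.3, 0.3), k2f + c(-0.3, 0.3))
  sse_fit <- sum((pts$omega0^2 - k1f * pts$q^2 - k2f * pts$q^4)^2)
  expect_lte(sse_fit, oracle$sse * (1 + 1e-12))
  # the exhaustive-search optimum sits within one grid cell of the
  # analytic least-squares solution
  cell <- 0.6 / 60
  expect_lt(abs(oracle$k1 - k1f), cell * 1.01)
  expect_lt(abs(oracle$k2 - k2f), cell * 1.01)
})

test_that("two-point solve reproduces the supercooled-water coefficient chain", {
  # reference points: c = 1.3e3 m/s at q = 0.023 nm^-1, 3.5e3 m/s at 3 nm^-1
  q <- invnm_to_si(c(0.023, 3.0))
  pts <- dispersion_points(q = q, omega0 = c(1.3e3, 3.5e3) * q)
  fit <- fit_dispersion(pts, mode = "exact_two_point")
  # k2 agrees with the printed value to its two significant figures
  expect_equal(signif(fit$coefficients$k2, 2), 1.2e-12)
  expect_equal(fit$coefficients$k2, 1.1734e-12, tolerance = 1e-4)
  # the exact solve gives k1 = 1.69e6; the printed 1.8e6 is not reproduced
  # by this construction and is deliberately not forced
  expect_equal(fit$coefficients$k1, 1.690e6, tolerance = 1e-3)
  # interpolation is exact at both reference points
  expect_equal(omega0(q, fit, warn = FALSE), pts$omega0, tolerance = 1e-12)
})

test_that("two-point and least-squares modes coincide on two noiseless points", {
  pts <- synth_dispersion(3.9e6, 4.8e-13, q_min = 1e9, q_max = 3e9,
                          n_points = 2, relative_noise = 0)
  f1 <- fit_dispersion(pts, mode = "exact_two_point")
  f2 <- fit_dispersion(pts, mode = "least_squares")
  f3 <- fit_dispersion(pts, mode = "least_squares", space = "omega")
  expect_equal(f1$coefficients$k1, f2$coefficients$k1, tolerance = 1e-9)
  expect_equal(f1$coefficients$k2, f2$coefficients$k2, tolerance = 1e-9)
  expect_equal(f1$coefficients$k1, f3$coefficients$k1, tolerance = 1e-9)
})

test_that("degenerate and non-physical inputs are rejected with typed errors", {
  q <- rep(2e9, 3)
  pts <- dispersion_points(q = q, omega0 = c(1, 2, 3) * 1e12)
  expect_error(fit_dispersion(pts), class = "aquasoliton_error_degenerate")
  # omega0^2/q^2 decreasing with q forces a negative k2
  q <- c(1e9, 2e9, 3e9)
  pts <- dispersion_points(q = q, omega0 = sqrt(1e7 * q^2 - 1e-13 * q^4))
  expect_error(fit_dispersion(pts), class = "aquasoliton_error_nonphysical")
  pts3 <- dispersion_points(q = q, omega0 = 2e3 * q)
  expect_error(fit_dispersion(pts3, mode = "exact_two_point"),
               class = "aquasoliton_error_input")
  expect_error(dispersion_points(q = c(-1, 2), omega0 = c(1, 2)),
               class = "aquasoliton_error_input")
})

test_that("the dispersion law and apparent velocity behave as in the linear limit", {
  co <- dispersion_coefficients(2.5e6, 1e-13, q_max_valid = 3e9)
  expect_equal(omega0(0, co), 0)
  # k2 = 0: linear dispersion, omega0/q constant at sqrt(k1)
  lin <- dispersion_coefficients(2.5e6, 1e-300)
  q <- seq(1e8, 3e9, length.out = 5)
  expect_equal(apparent_velocity(q, lin), rep(sqrt(2.5e6), 5),
               tolerance = 1e-6)
  # positive sound dispersion: c(q) increasing, bounded below by sqrt(k1)
  cq <- apparent_velocity(q, co)
  expect_true(all(diff(cq) > 0))
  expect_true(all(cq >= sqrt(co$k1)))
  expect_warning(omega0(4e9, co), class = "aquasoliton_warning_validity")
  expect_error(apparent_velocity(0, co), class = "aquasoliton_error_domain")
})

test_that("printed crossover frequencies give the printed apparent velocities", {
  # evaluating the rounded case-I law at q* gives 4.82 ps^-1, slightly
  # below the 4.9 ps^-1 of the unrounded original fit; that is why
  # omega0(q*) is an independent input downstream
  expect_equal(omega0(invnm_to_si(2.0), case_I$coefficients),
               4.8249e12, tolerance = 1e-4)
  expect_equal(apparent_velocity(invnm_to_si(2.0),
                                 omega0_value = invps_to_si(4.9)),
               2.45e3)
  expect_equal(signif(apparent_velocity(invnm_to_si(2.5),
                                        omega0_value = invps_to_si(6.8)), 2),
               2.7e3)
})

test_that("dispersion tables round-trip through CSV in nm^-1 / ps^-1 units", {
  pts <- synth_dispersion(3.9e6, 4.8e-13, q_min = 2e8, q_max = 3e9,
                          n_points = 10, relative_noise = 0.02, seed = 5)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_dispersion_csv(pts, f)
  back <- read_dispersion_csv(f)
  expect_equal(back$q, pts$q, tolerance = 1e-12)
  expect_equal(back$omega0, pts$omega0, tolerance = 1e-12)
  expect_error(read_dispersion_csv(
    {g <- tempfile(); writeLines("a,b\n1,2", g); g}),
    class = "aquasoliton_error_input")
})

test_that("tidy and glance summarize a dispersion fit", {
  pts <- synth_dispersion(3.9e6, 4.8e-13, q_min = 2e8, q_max = 3e9,
                          n_points = 50, relative_noise = 0.02, seed = 9)
  fit <- fit_dispersion(pts)
  td <- tidy(fit)
  expect_equal(td$term, c("k1", "k2"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$nobs, 50)
  expect_lt(gl$rmse_omega0 / mean(pts$omega0), 0.05)
})

test_that("the packaged synthetic dispersion table fits back to its case-I truth", {
  f <- system.file("extdata", "synthetic_caseI_dispersion.csv",
                   package = "aquasoliton")
  pts <- read_dispersion_csv(f)
  fit <- fit_dispersion(pts)
  expect_lt(abs(fit$coefficients$k1 - 3.9e6) / 3.9e6, 0.05)
  expect_lt(abs(fit$coefficients$k2 - 4.8e-13) / 4.8e-13, 0.05)
})
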
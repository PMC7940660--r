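test_that("the flux reduces to its closed forms on simple fields", {
  dl <- case_I$dimless
  n <- 101
  # constant density, quiescent velocity: g = k1 c0 + (alpha/2) c0^2 everywhere
  c0 <- -0.7
  g <- wave_flux(list(rho = rep(c0, n), u = numeric(n)), dl, dx = 0.1)
  expect_equal(g, rep(dl$k1p * c0 + dl$alphap / 2 * c0^2, n),
               tolerance = 1e-12)
  # zero state, zero flux
  expect_equal(wave_flux(list(rho = numeric(n), u = numeric(n)), dl, 0.1),
               numeric(n))
  # linear sine mode on a periodic grid: g = (k1 + k2 q^2) sin to O(dx^2)
  dlin <- dimensionless_params(dl$k1p, dl$k2p)
  L <- 12.8; dx <- 0.01
  nn <- round(L / dx)
  x <- seq(0, by = dx, length.out = nn)
  q <- 2 * pi / L
  g <- wave_flux(list(rho = sin(q * x), u = numeric(nn)), dlin, dx,
                 periodic = TRUE)
  expect_equal(g, (dlin$k1p + dlin$k2p * q^2) * sin(q * x),
               tolerance = 1e-4)
  expect_error(wave_flux(list(rho = c(1, NaN), u = c(0, 0)), dl, 0.1),
               class = "aquasoliton_error_stability")
})

test_that("forcing realizations have the fluctuation-dissipation statistics", {
  dt <- 2.5e-5
  nu <- 0.60
  h <- make_forcing(4, 200000, nu, dt, seed = 42)
  # white in time at every node: variance nu^2/dt, mean zero
  v_target <- nu^2 / dt
  for (i in 1:4)
    expect_lt(abs(var(h[i, ]) - v_target) / v_target, 0.02)
  expect_lt(abs(mean(h)) / sqrt(v_target), 0.01)
  # nodes are independent
  cc <- cor(t(h))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.02)
  # zero damping, zero forcing
  expect_equal(make_forcing(3, 10, 0, dt), matrix(0, 3, 10))
  # bit-exact reproducibility from the seed
  expect_identical(make_forcing(5, 100, nu, dt, seed = 7),
                   make_forcing(5, 100, nu, dt, seed = 7))
  expect_false(identical(make_forcing(5, 100, nu, dt, seed = 7),
                         make_forcing(5, 100, nu, dt, seed = 8)))
  # stress-gradient reading: mean zero, variance scales like 1/dx
  h1 <- make_forcing(64, 5000, nu, dt, seed = 1, mode = "stress_gradient",
                     dx = 0.02)
  h2 <- make_forcing(64, 5000, nu, dt, seed = 2, mode = "stress_gradient",
                     dx = 0.04)
  expect_lt(abs(mean(h1)), 3 * sd(h1) / sqrt(length(h1)) + 1e-10)
  expect_gt(var(as.numeric(h1)) / var(as.numeric(h2)), 4)
})

test_that("the zero state is a fixed point and runs replay bit-exactly", {
  dl <- case_I$dimless
  g <- grid_1d(10, 0.05)
  z <- field_state(numeric(g$n_nodes), numeric(g$n_nodes))
  st <- step_maccormack(z, dl, g$dx, 1e-4)
  expect_equal(st$rho, numeric(g$n_nodes))
  expect_equal(st$u, numeric(g$n_nodes))
  cfg <- solver_config(dl, dt = 1e-4, n_steps = 200L, save_every = 100L,
                       noise = TRUE, seed = 99, dx = g$dx)
  init <- soliton_initial_state(stationary_soliton(dl), g,
                                clearance_fwhm = 1.5)
  t1 <- simulate_spde(init, g, cfg)
  t2 <- simulate_spde(init, g, cfg)
  expect_identical(t1$rho, t2$rho)
  expect_identical(t1$u, t2$u)
})

test_that("small-amplitude standing waves oscillate at the linear dispersion frequency", {
  dl <- case_I$dimless
  dlin <- dimensionless_params(dl$k1p, dl$k2p)
  dx <- 0.05
  g <- grid_1d(12.8, dx)
  P <- g$n_nodes * dx  # wrap period of the node-centred periodic lattice
  q <- 2 * pi * 2 / P
  init <- field_state(1e-6 * sin(q * g$x), numeric(g$n_nodes))
  cfg <- solver_config(dlin, dt = 2e-4, n_steps = 40000L, save_every = 50L,
                       bc = "periodic", dx = dx)
  tr <- simulate_spde(init, g, cfg)
  sig <- tr$rho[round(P / 4 / dx / 2), ]
  w_expected <- sqrt(dlin$k1p * q^2 + dlin$k2p * q^4)
  sse <- function(w) {
    X <- cbind(cos(w * tr$t), sin(w * tr$t))
    sum(lm.fit(X, sig)$residuals^2)
  }
  w_fit <- optimize(sse, w_expected * c(0.97, 1.03), tol = 1e-10)$minimum
  expect_lt(abs(w_fit - w_expected) / w_expected, 1e-3)
})

test_that("mass is conserved for compact noiseless pulses", {
  dl <- case_I$dimless
  g <- grid_1d(40, 0.02)
  init <- soliton_initial_state(stationary_soliton(dl), g)
  cfg <- solver_config(dl, dt = 5e-5, n_steps = 10000L,
                       save_every = 10000L, dx = g$dx)
  tr <- simulate_spde(init, g, cfg)
  m0 <- field_mass(init$rho, g$dx)
  m1 <- field_mass(tr$rho[, 2], g$dx)
  expect_lt(abs((m1 - m0) / m0), 1e-8)
})

test_that("damping makes the linearized wave energy non-increasing", {
  dl <- case_I$dimless
  dlin <- dimensionless_params(dl$k1p, dl$k2p, alphap = 0, nuLp = 0.60)
  dx <- 0.05
  g <- grid_1d(12.8, dx)
  P <- g$n_nodes * dx
  rho <- 1e-3 * (sin(2 * pi * 2 * g$x / P) + 0.5 * cos(2 * pi * 5 * g$x / P))
  cfg <- solver_config(dlin, dt = 2e-4, n_steps = 20000L, save_every = 500L,
                       bc = "periodic", dx = dx)
  tr <- simulate_spde(field_state(rho, numeric(g$n_nodes)), g, cfg)
  E <- vapply(seq_along(tr$t), function(j)
    wave_energy(list(rho = tr$rho[, j], u = tr$u[, j]), dlin, dx), 1)
  expect_true(all(diff(E) <= 1e-12 * E[1]))
  expect_lt(E[length(E)], 0.5 * E[1])
})

test_that("outgoing pulses leave through the absorbing boundaries", {
  dl <- dimensionless_params(case_I$dimless$k1p, case_I$dimless$k2p)
  c0 <- sqrt(dl$k1p)
  dx <- 0.02
  g <- grid_1d(40, dx)
  rho <- exp(-((g$x - 30) / 1.5)^2)
  init <- field_state(rho, c0 * rho)  # rightward linear pulse
  E0 <- wave_energy(init, dl, dx)
  ns <- as.integer(round(16 / 5e-5))
  for (bc in c("sponge", "characteristic")) {
    cfg <- solver_config(dl, dt = 5e-5, n_steps = ns, save_every = ns,
                         bc = bc, dx = dx)
    tr <- simulate_spde(init, g, cfg)
    E1 <- wave_energy(list(rho = tr$rho[, 2], u = tr$u[, 2]), dl, dx)
    frac <- E1 / E0
    if (bc == "sponge") expect_lt(frac, 0.01) else expect_lt(frac, 0.10)
  }
  # interior nodes untouched before the pulse reaches the boundary zone
  cfg <- solver_config(dl, dt = 5e-5, n_steps = 400L, save_every = 400L,
                       bc = "sponge", dx = dx)
  tr <- simulate_spde(init, g, cfg)
  mid <- abs(tr$rho[round(30 / dx), 2])
  expect_gt(mid, 0.5)  # pulse still in the interior, undamped
})

test_that("ensemble means approach the deterministic trajectory as 1/sqrt(N)", {
  dl <- case_I$dimless
  dx <- 0.05
  g <- grid_1d(12, dx)
  sol <- stationary_soliton(dl)
  init <- soliton_initial_state(sol, g, clearance_fwhm = 2)
  run <- function(seed, noise) {
    cfg <- solver_config(dl, dt = 2e-4, n_steps = 10000L,
                         save_every = 10000L, noise = noise, seed = seed,
                         dx = dx)
    simulate_spde(init, g, cfg)$rho[, 2]
  }
  det <- run(1, FALSE)
  ens <- vapply(1:32, function(s) run(s, TRUE), numeric(g$n_nodes))
  err_n <- function(n) sqrt(sum((rowMeans(ens[, 1:n]) - det)^2))
  e8 <- err_n(8)
  e32 <- err_n(32)
  # quadrupling the ensemble should roughly halve the error
  expect_lt(e32, e8)
  expect_gt(e8 / e32, 1.3)
  expect_lt(e8 / e32, 3.5)
})

test_that("violating the stability bound is warned about and detected", {
  dl <- case_I$dimless
  g <- grid_1d(10, 0.02)
  init <- soliton_initial_state(stationary_soliton(dl), g,
                                clearance_fwhm = 1.5)
  expect_warning(
    cfg <- solver_config(dl, dt = 5e-3, n_steps = 2000L, save_every = 10L,
                         dx = g$dx),
    class = "aquasoliton_warning_stability")
  expect_error(simulate_spde(init, g, cfg),
               class = "Rcpp::exception")
  # truncate mode keeps the finite prefix instead of aborting
  cfg2 <- suppressWarnings(
    solver_config(dl, dt = 5e-3, n_steps = 2000L, save_every = 10L,
                  dx = g$dx, on_instability = "truncate"))
  expect_warning(tr <- simulate_spde(init, g, cfg2),
                 class = "aquasoliton_warning_instability")
  expect_true(tr$truncated)
  expect_lt(length(tr$t), 201)
  expect_true(all(is.finite(tr$rho)))
})
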
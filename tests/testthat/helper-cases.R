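# Shared fixtures: literature case bundles and small construction helpers.

case_I <- make_case("I")
case_II <- make_case("II")

# dimensionless case-I parameter set with the damping switched off
dimless_undamped <- function(cb = case_I) {
  dl <- cb$dimless
  dl$nuLp <- 0
  dl
}

# build a trajectory object from analytic snapshots, for diagnostics tests
analytic_trajectory <- function(sol, grid, times, center = grid$length / 2,
                                direction = 1) {
  rho <- vapply(times, function(tt)
    soliton_profile(sol, grid$x, time = tt, center = center,
                    direction = direction),
    numeric(grid$n_nodes))
  structure(list(t = times, x = grid$x, rho = rho, u = 0 * rho,
                 grid = grid, config = list(noise = FALSE, bc = "none",
                                            seed = NA,
                                            dimless = NULL)),
            class = "trajectory")
}

# independent brute-force least-squares oracle: exhaustive grid search over
# (k1, k2) minimizing the omega0^2-space sum of squares
grid_search_fit <- function(points, k1_range, k2_range, n = 61) {
  k1s <- seq(k1_range[1], k1_range[2], length.out = n)
  k2s <- seq(k2_range[1], k2_range[2], length.out = n)
  y <- points$omega0^2
  q2 <- points$q^2
  q4 <- points$q^4
  best <- c(NA, NA, Inf)
  for (a in k1s) for (b in k2s) {
    sse <- sum((y - a * q2 - b * q4)^2)
    if (sse < best[3]) best <- c(a, b, sse)
  }
  list(k1 = best[1], k2 = best[2], sse = best[3])
}
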
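# aquasoliton

Soliton-like terahertz density pulses in liquid water at the viscoelastic
crossover: parameter estimation from dispersion curves, closed-form
soliton construction, and stochastic nonlinear-wave simulation.

## The problem

Inelastic X-ray/neutron scattering and molecular dynamics consistently
indicate nanometre-sized density variations in bulk and hydration water
on sub-picosecond time scales. In the wavenumber window of the
*viscoelastic crossover* (~1–3 nm⁻¹) the longitudinal acoustic-like mode
of water shows positive sound dispersion, captured at low q by

```
omega0^2(q) = k1 q^2 + k2 q^4            (valid below the crossover bound q_u)
```

When such a mode has a finite amplitude, the interplay of this dispersion
with the acoustic nonlinearity of water (`beta ≈ 3.5`, entering through
`alpha = 2 c^2 (beta - 1) / rho0`) supports sech² rarefaction solitons of
the associated Boussinesq equation

```
drho(x,t) = A sech^2((x - v t)/delta),
A = -12 k2 / (alpha delta^2),   v^2 = k1 - 4 k2 / delta^2,
```

subsonic pulses admissible for `delta^2 >= 4 k2/k1`. At the lower width
bound the pulse is stationary (`A = -3 k1/alpha`, `delta = 2 sqrt(k2/k1)`)
and is an exact steady state even of the *damped* equation — a candidate
dynamic mechanism for nanometre low-density regions in water. The package
is for researchers in water collective dynamics who want this chain as
tested, reusable code: fit dispersion data, derive the medium parameters,
build the solitons, and verify their persistence under
fluctuation–dissipation thermal forcing with a MacCormack
finite-difference integrator of the damped stochastic Boussinesq system.

## Worked example

Bulk water at ~278 K (case I: printed dispersion coefficients
`k1 = 3.9e6 m^2/s^2`, `k2 = 4.8e-13 m^4/s^2`, crossover at
`q* = 2 nm^-1`, `omega0(q*) = 4.9 ps^-1`):

```r
library(aquasoliton)
cb <- make_case("I")
cb$dimless
#> <dimensionless parameters  k1' = 0.6497, k2' = 0.3199, alpha' = 0.2164, nu'_L = 0.6>
#>   scales: q* = 2 nm^-1, omega0(q*) = 4.9 ps^-1, A* = 43.29 kg/m^3

stationary_soliton(cb$coefficients, alpha = cb$medium$alpha)
#> <sech^2 soliton (rarefaction pulse)>
#>   A = -389.8 (|A| = 389.8), delta = 7.016e-10, FWHM = 1.237e-09, v = 0
```

The stationary pulse is a rarefaction of ~390 kg/m³ (comparable to the
LDL/HDL density contrast) with width 0.70 nm, FWHM 1.2 nm. The traveling
pulse whose amplitude equals the thermal density-fluctuation magnitude
`A* ≈ 43 kg/m^3` is wider and subsonic:

```r
d <- delta_from_amplitude(cb$medium$A_star, cb$coefficients$k2,
                          cb$medium$alpha, k1 = cb$coefficients$k1)
soliton_family(d, cb$coefficients, alpha = cb$medium$alpha)
#> <sech^2 soliton (rarefaction pulse)>
#>   A = -43.29 (|A| = 43.29), delta = 2.106e-09, FWHM = 3.712e-09, v = 1862
```

i.e. `delta ≈ 2.1 nm`, FWHM ≈ 3.7 nm, speed ≈ 1.9×10³ m/s — below the
long-wavelength sound speed `sqrt(k1) ≈ 1975 m/s`. Evolving the
stationary pulse under thermal forcing (model units; `t' = 4.9` is 1 ps):

```r
dl <- cb$dimless
g <- grid_1d(120, 2e-2)
init <- soliton_initial_state(stationary_soliton(dl), g)
cfg <- solver_config(dl, dt = 5e-5, n_steps = 24500L, save_every = 4900L,
                     noise = TRUE, seed = 7, dx = g$dx)
traj <- simulate_spde(init, g, cfg)
deviation_series(traj, stationary_soliton(dl))
#> # A tibble: 6 × 3
#>    time      l2    linf
#>   <dbl>   <dbl>   <dbl>
#> 1 0     0       0
#> 2 0.245 0.00937 0.00424
#> 3 0.49  0.0145  0.00583
#> 4 0.735 0.0169  0.00724
#> 5 0.98  0.0218  0.00810
#> 6 1.23  0.0268  0.0109
```

The relative L2 deviation from the analytic profile stays at the percent
level over a quarter picosecond: the soliton survives the thermal noise.
`reproduce_estimates()` regenerates the full closed-form estimate table
for cases I/II/III next to the published values;
`persistence_experiment()` runs the seed ensembles comparing bulk
(`nu'_L = 0.60`) and DNA/protein hydration water (`nu'_L = 0.32`). See
the vignette `vignettes/soliton-modes-in-water.Rmd` for the model,
discretization and design choices.

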
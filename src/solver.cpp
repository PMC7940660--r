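// MacCormack integrator for the dimensionless damped stochastic Boussinesq
// system written as two first-order equations
//   d(rho)/dt + d(u)/dx = 0
//   d(u)/dt   + d(g)/dx = h
// with flux
//   g = k1' rho - k2' rho_xx + (alpha'/2) rho^2 + nu' d(rho)/dt
// where the mixed term nu' d(rho)/dt is evaluated as -nu' u_x through the
// continuity equation so that the scheme stays explicit and flux-local.
//
// The stochastic forcing h is white in time at every node; its per-step
// normal deviates come from an own xoshiro256++ stream (seeded from R) so
// that trajectories are bit-reproducible from (config, seed) and cheap to
// draw at ~1 normal per node per step.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// 128-layer ziggurat tables for the standard normal (Marsaglia & Tsang),
// built once at load time
struct ZigTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = static_cast<uint32_t>((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};

static const ZigTables ZIG;

struct Xoshiro {
  uint64_t s[4];

  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1), 53-bit mantissa, never exactly 0
  inline double unif() {
    return ((next() >> 11) + 0.5) * 1.1102230246251565e-16;
  }

  // standard normal via the ziggurat; rare layer-0/edge cases fall back to
  // the exact exponential tail
  inline double normal() {
    for (;;) {
      int32_t hz = static_cast<int32_t>(next() >> 32);
      uint32_t iz = static_cast<uint32_t>(hz) & 127u;
      if (static_cast<uint32_t>(hz < 0 ? -(int64_t)hz : hz) < ZIG.kn[iz])
        return hz * ZIG.wn[iz];
      // slow path
      const double r = 3.442619855899;
      double x = hz * ZIG.wn[iz];
      if (iz == 0) {
        double y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -r - x;
      }
      if (ZIG.fn[iz] + unif() * (ZIG.fn[iz - 1] - ZIG.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// flux g at every node; zero-gradient ghost cells unless periodic
inline void flux_inner(const double *r, const double *u, double *g, int n,
                       double k1, double k2dx2, double a2, double nu2dx,
                       bool periodic) {
  for (int i = 1; i < n - 1; ++i) {
    g[i] = k1 * r[i] + a2 * r[i] * r[i]
         - k2dx2 * (r[i + 1] - 2.0 * r[i] + r[i - 1])
         - nu2dx * (u[i + 1] - u[i - 1]);
  }
  if (periodic) {
    g[0] = k1 * r[0] + a2 * r[0] * r[0]
         - k2dx2 * (r[1] - 2.0 * r[0] + r[n - 1])
         - nu2dx * (u[1] - u[n - 1]);
    g[n - 1] = k1 * r[n - 1] + a2 * r[n - 1] * r[n - 1]
             - k2dx2 * (r[0] - 2.0 * r[n - 1] + r[n - 2])
             - nu2dx * (u[0] - u[n - 2]);
  } else {
    g[0] = k1 * r[0] + a2 * r[0] * r[0]
         - k2dx2 * (r[1] - r[0])
         - nu2dx * (u[1] - u[0]);
    g[n - 1] = k1 * r[n - 1] + a2 * r[n - 1] * r[n - 1]
             - k2dx2 * (r[n - 2] - r[n - 1])
             - nu2dx * (u[n - 1] - u[n - 2]);
  }
}

// forcing slice for one step: fills h (physical units of the u-equation
// source, i.e. to be applied as u += h * dt).
// mode 0: node-independent white-in-time, h_i = nu * xi_i / sqrt(dt)
// mode 1: gradient of a spatially white stress, h_i = (dS_{i+1}-dS_{i-1})/(2 dx),
//         Var(dS_i) = nu^2 / (dt * dx)
inline void draw_forcing(Xoshiro &rng, std::vector<double> &xi,
                         std::vector<double> &h, int n, double nu, double dt,
                         double dx, int mode, bool periodic) {
  if (mode == 0) {
    const double amp = nu / std::sqrt(dt);
    for (int i = 0; i < n; ++i) h[i] = amp * rng.normal();
  } else {
    const double amp = nu / std::sqrt(dt * dx);
    for (int i = 0; i < n; ++i) xi[i] = amp * rng.normal();
    const double inv2dx = 1.0 / (2.0 * dx);
    for (int i = 1; i < n - 1; ++i) h[i] = (xi[i + 1] - xi[i - 1]) * inv2dx;
    if (periodic) {
      h[0] = (xi[1] - xi[n - 1]) * inv2dx;
      h[n - 1] = (xi[0] - xi[n - 2]) * inv2dx;
    } else {
      h[0] = (xi[1] - xi[0]) * inv2dx;
      h[n - 1] = (xi[n - 1] - xi[n - 2]) * inv2dx;
    }
  }
}

struct Stepper {
  int n;
  double k1, k2dx2, a2, nu2dx, dx, dt, lam;
  bool periodic;
  std::vector<double> g, gp, rp, up;

  Stepper(int n_, double k1p, double k2p, double alphap, double nuLp,
          double dx_, double dt_, bool periodic_)
      : n(n_), k1(k1p), k2dx2(k2p / (dx_ * dx_)), a2(0.5 * alphap),
        nu2dx(nuLp / (2.0 * dx_)), dx(dx_), dt(dt_), lam(dt_ / dx_),
        periodic(periodic_), g(n_), gp(n_), rp(n_), up(n_) {}

  // one predictor/corrector step; dir = 0 forward-then-backward differences,
  // dir = 1 the reverse. h may be null (no forcing); applied with
  // Euler-Maruyama weighting, same realization in predictor and corrector.
  void step(double *r, double *u, const double *h, int dir) {
    flux_inner(r, u, g.data(), n, k1, k2dx2, a2, nu2dx, periodic);
    const double *gd = g.data();
    if (dir == 0) {
      for (int i = 0; i < n - 1; ++i) {
        rp[i] = r[i] - lam * (u[i + 1] - u[i]);
        up[i] = u[i] - lam * (gd[i + 1] - gd[i]);
      }
      if (periodic) {
        rp[n - 1] = r[n - 1] - lam * (u[0] - u[n - 1]);
        up[n - 1] = u[n - 1] - lam * (gd[0] - gd[n - 1]);
      } else {
        rp[n - 1] = r[n - 1];
        up[n - 1] = u[n - 1];
      }
    } else {
      for (int i = 1; i < n; ++i) {
        rp[i] = r[i] - lam * (u[i] - u[i - 1]);
        up[i] = u[i] - lam * (gd[i] - gd[i - 1]);
      }
      if (periodic) {
        rp[0] = r[0] - lam * (u[0] - u[n - 1]);
        up[0] = u[0] - lam * (gd[0] - gd[n - 1]);
      } else {
        rp[0] = r[0];
        up[0] = u[0];
      }
    }
    if (h) {
      for (int i = 0; i < n; ++i) up[i] += h[i] * dt;
    }
    flux_inner(rp.data(), up.data(), gp.data(), n, k1, k2dx2, a2, nu2dx,
               periodic);
    const double *gpd = gp.data();
    const double hl = 0.5 * lam;
    if (dir == 0) {
      if (periodic) {
        r[0] = 0.5 * (r[0] + rp[0]) - hl * (up[0] - up[n - 1]);
        u[0] = 0.5 * (u[0] + up[0]) - hl * (gpd[0] - gpd[n - 1]);
      } else {
        r[0] = 0.5 * (r[0] + rp[0]);
        u[0] = 0.5 * (u[0] + up[0]);
      }
      for (int i = 1; i < n; ++i) {
        r[i] = 0.5 * (r[i] + rp[i]) - hl * (up[i] - up[i - 1]);
        u[i] = 0.5 * (u[i] + up[i]) - hl * (gpd[i] - gpd[i - 1]);
      }
    } else {
      for (int i = 0; i < n - 1; ++i) {
        r[i] = 0.5 * (r[i] + rp[i]) - hl * (up[i + 1] - up[i]);
        u[i] = 0.5 * (u[i] + up[i]) - hl * (gpd[i + 1] - gpd[i]);
      }
      if (periodic) {
        r[n - 1] = 0.5 * (r[n - 1] + rp[n - 1]) - hl * (up[0] - up[n - 1]);
        u[n - 1] = 0.5 * (u[n - 1] + up[n - 1]) - hl * (gpd[0] - gpd[n - 1]);
      } else {
        r[n - 1] = 0.5 * (r[n - 1] + rp[n - 1]);
        u[n - 1] = 0.5 * (u[n - 1] + up[n - 1]);
      }
    }
    if (h) {
      for (int i = 0; i < n; ++i) u[i] += 0.5 * h[i] * dt;
    }
  }
};

// smooth quadratic-ramp absorption rate in the sponge zones
void sponge_factors(std::vector<double> &f, int n, int width, double strength,
                    double dt) {
  f.assign(n, 1.0);
  if (width <= 0) return;
  for (int j = 0; j < width; ++j) {
    double s = double(width - j) / double(width);  // 1 at wall, 0 inside
    double rate = strength * s * s;
    double fac = std::exp(-rate * dt);
    f[j] = fac;
    f[n - 1 - j] = fac;
  }
}

// first-order characteristic outflow on w+/- = u +/- c*rho at both walls
inline void characteristic_bc(double *r, double *u, int n, double c,
                              double lam) {
  const double clam = c * lam;
  // left wall: outgoing w- = u - c r advects left, incoming w+ set to 0
  double wm0 = u[0] - c * r[0], wm1 = u[1] - c * r[1];
  double wm_new = wm0 + clam * (wm1 - wm0);
  u[0] = 0.5 * wm_new;
  r[0] = -wm_new / (2.0 * c);
  // right wall: outgoing w+ = u + c r advects right, incoming w- set to 0
  double wpn = u[n - 1] + c * r[n - 1], wpm = u[n - 2] + c * r[n - 2];
  double wp_new = wpn - clam * (wpn - wpm);
  u[n - 1] = 0.5 * wp_new;
  r[n - 1] = wp_new / (2.0 * c);
}

}  // namespace

// [[Rcpp::export(name = ".flux_core")]]
NumericVector flux_core(NumericVector rho, NumericVector u, double k1p,
                        double k2p, double alphap, double nuLp, double dx,
                        bool periodic) {
  int n = rho.size();
  if (u.size() != n) stop("rho and u must have the same length");
  NumericVector g(n);
  flux_inner(rho.begin(), u.begin(), g.begin(), n, k1p, k2p / (dx * dx),
             0.5 * alphap, nuLp / (2.0 * dx), periodic);
  return g;
}

// [[Rcpp::export(name = ".forcing_core")]]
NumericMatrix forcing_core(double seed, int n_nodes, int n_steps, double nuLp,
                           double dt, int mode, double dx, bool periodic) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  NumericMatrix out(n_nodes, n_steps);
  std::vector<double> xi(n_nodes), h(n_nodes);
  for (int s = 0; s < n_steps; ++s) {
    draw_forcing(rng, xi, h, n_nodes, nuLp, dt, dx, mode, periodic);
    for (int i = 0; i < n_nodes; ++i) out(i, s) = h[i];
  }
  return out;
}

// [[Rcpp::export(name = ".step_core")]]
List step_core(NumericVector rho, NumericVector u, double k1p, double k2p,
               double alphap, double nuLp, double dx, double dt,
               Nullable<NumericVector> forcing, int dir, bool periodic) {
  int n = rho.size();
  std::vector<double> r(rho.begin(), rho.end()), v(u.begin(), u.end());
  Stepper st(n, k1p, k2p, alphap, nuLp, dx, dt, periodic);
  const double *h = nullptr;
  NumericVector hv;
  if (forcing.isNotNull()) {
    hv = forcing.get();
    if (hv.size() != n) stop("forcing must have one value per node");
    h = hv.begin();
  }
  st.step(r.data(), v.data(), h, dir);
  return List::create(_["rho"] = NumericVector(r.begin(), r.end()),
                      _["u"] = NumericVector(v.begin(), v.end()));
}

// [[Rcpp::export(name = ".simulate_core")]]
List simulate_core(NumericVector rho0, NumericVector u0, double k1p,
                   double k2p, double alphap, double nuLp, double dx,
                   double dt, int n_steps, int save_every, bool noise,
                   int noise_mode, double seed, int bc_mode, int sponge_width,
                   double sponge_strength, int on_blowup) {
  // bc_mode: 0 sponge, 1 characteristic, 2 periodic
  const int n = rho0.size();
  if (u0.size() != n) stop("rho0 and u0 must have the same length");
  const bool periodic = (bc_mode == 2);
  std::vector<double> r(rho0.begin(), rho0.end()), v(u0.begin(), u0.end());
  Stepper st(n, k1p, k2p, alphap, nuLp, dx, dt, periodic);
  Xoshiro rng(static_cast<uint64_t>(seed));
  std::vector<double> xi(n), h(n), spf;
  if (bc_mode == 0) sponge_factors(spf, n, sponge_width, sponge_strength, dt);
  const double c0 = std::sqrt(k1p);

  const int n_save = n_steps / save_every + 1;
  NumericMatrix rho_out(n, n_save), u_out(n, n_save);
  NumericVector t_out(n_save);
  int isave = 0;
  int blown_at = -1;
  for (int i = 0; i < n; ++i) {
    rho_out(i, 0) = r[i];
    u_out(i, 0) = v[i];
  }
  t_out[0] = 0.0;
  isave = 1;

  for (int step = 1; step <= n_steps; ++step) {
    const double *hp = nullptr;
    if (noise && nuLp > 0.0) {
      draw_forcing(rng, xi, h, n, nuLp, dt, dx, noise_mode, periodic);
      hp = h.data();
    }
    st.step(r.data(), v.data(), hp, (step - 1) & 1);
    if (bc_mode == 0 && sponge_width > 0) {
      for (int j = 0; j < sponge_width; ++j) {
        r[j] *= spf[j];
        v[j] *= spf[j];
        r[n - 1 - j] *= spf[n - 1 - j];
        v[n - 1 - j] *= spf[n - 1 - j];
      }
    } else if (bc_mode == 1) {
      characteristic_bc(r.data(), v.data(), n, c0, dt / dx);
    }
    if (step % save_every == 0 && isave < n_save) {
      bool ok = true;
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(r[i]) || !std::isfinite(v[i])) {
          ok = false;
          break;
        }
        rho_out(i, isave) = r[i];
        u_out(i, isave) = v[i];
      }
      if (!ok) {
        // on_blowup 1: keep the finite part of the trajectory (nonlinear
        // rarefaction collapse is a real, if rare, feature of the model)
        if (on_blowup == 1) {
          blown_at = step;
          break;
        }
        stop("numerical instability: non-finite field values at step %d",
             step);
      }
      t_out[isave] = step * dt;
      ++isave;
    }
    if ((step & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["t"] = t_out, _["rho"] = rho_out, _["u"] = u_out,
                      _["n_steps"] = n_steps, _["n_saved"] = isave,
                      _["blown_at"] = blown_at);
}
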
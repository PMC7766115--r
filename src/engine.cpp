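// Coarse-grained Langevin-dynamics engine for polymer ejection from a
// spherical cavity through a cylindrical nanopore into a semi-space.
//
// Reduced LJ units throughout: sigma = length, eps = energy, bead mass = 1,
// time in sigma*sqrt(m/eps).  Geometry convention: pore axis = +x through
// the cavity center (origin); cavity-exit ("entrance") plane at x_en = D/2;
// pore-exit plane at x_w = x_en + Lp.  A bead with x >= x_en is outside the
// cavity (half-open counting).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Pot {
  double eps, sigma, k, b0, epsw, sigw;
  double rc2_wca;   // squared WCA cutoff
  double dcut93;    // 9-3 wall cutoff (its minimum)
  double shift93;   // energy shift so U(dcut93) = 0
};

struct Geom {
  bool dinf;
  double Rc;     // nominal wall-sphere radius (finite-D only)
  double x_en;   // entrance plane (effective inner cavity surface)
  double x_w;    // pore-exit plane (effective outer surface)
  double x_pl;   // nominal outer-plane wall position
  double x_cis;  // nominal cis-plane wall position (dinf only)
  double rp;     // nominal pore (cylinder) radius
  double cyl_x0; // start of the pore tube force region (cavity vestibule)
  double cyl_x1; // end of the tube force region (exit vestibule)
};

static Pot make_pot(List pot) {
  Pot p;
  p.eps = as<double>(pot["eps"]);
  p.sigma = as<double>(pot["sigma"]);
  p.k = as<double>(pot["k_bond"]);
  p.b0 = as<double>(pot["b0"]);
  p.epsw = as<double>(pot["eps_w"]);
  p.sigw = as<double>(pot["sigma_w"]);
  double rc = std::pow(2.0, 1.0 / 6.0) * p.sigma;
  p.rc2_wca = rc * rc;
  p.dcut93 = std::pow(0.4, 1.0 / 6.0) * p.sigw;
  double s3 = std::pow(p.sigw / p.dcut93, 3.0);
  p.shift93 = -(2.0 / 15.0 * s3 * s3 * s3 - s3);  // in units of epsw
  return p;
}

static Geom make_geom(List geom) {
  Geom g;
  g.dinf = as<bool>(geom["dinf"]);
  g.x_en = as<double>(geom["x_en"]);
  g.x_w = as<double>(geom["x_w"]);
  g.rp = as<double>(geom["rp_nom"]);
  g.x_pl = as<double>(geom["x_pl"]);
  double dcut = std::pow(0.4, 1.0 / 6.0) * as<double>(geom["sigma_w"]);
  if (g.dinf) {
    g.Rc = R_PosInf;
    g.x_cis = as<double>(geom["x_cis"]);
    g.cyl_x0 = g.x_cis - dcut;
  } else {
    g.Rc = as<double>(geom["Rc"]);
    g.x_cis = 0.0;
    g.cyl_x0 = g.x_en - dcut;
  }
  // the tube extends one wall cutoff past the nominal outer plane so a
  // bead leaving the pore is past the plane's repulsion zone before it
  // gains lateral freedom
  g.cyl_x1 = g.x_pl + dcut;
  return g;
}

// LJ 9-3 wall, truncated and shifted to zero at its minimum (purely
// repulsive).  Returns energy; *fmag = -dU/dd (push away from the wall).
static inline double w93(double d, const Pot& p, double* fmag) {
  if (d >= p.dcut93) { *fmag = 0.0; return 0.0; }
  if (d <= 1e-9) d = 1e-9;
  double s3 = p.sigw * p.sigw * p.sigw / (d * d * d);
  double s9 = s3 * s3 * s3;
  *fmag = p.epsw * (9.0 * 2.0 / 15.0 * s9 - 3.0 * s3) / d;
  if (*fmag > 1e4) *fmag = 1e4;  // safety clamp for pathological overlaps
  return p.epsw * (2.0 / 15.0 * s9 - s3 + p.shift93);
}

// Confinement energy/force for one bead.
//
// The free region is the union of three primitives: the nominal wall ball
// (radius Rc, finite-D only; for dinf the cis half-space x < x_cis), the
// pore tube (radius rp, x > 0), and the outer half-space (x > x_pl).  The
// wall distance used in the 9-3 potential is the MAXIMUM of the signed
// depths into the primitives: a continuous lower bound on the true
// distance to the wall solid (exact away from the concave seams), so the
// field has no gaps or singular rims anywhere a bead can reach.
static double conf_one(const double* x, const Pot& p, const Geom& g,
                       double fcap, double* f) {
  double rho2 = x[1] * x[1] + x[2] * x[2];
  double rho = std::sqrt(rho2);
  double sd[3];
  if (!g.dinf) {
    double r = std::sqrt(x[0] * x[0] + rho2);
    sd[0] = g.Rc - r;            // depth inside the ball
  } else {
    sd[0] = g.x_cis - x[0];      // depth below the cis plane
  }
  double drho = g.rp - rho;      // radial depth inside the tube
  sd[1] = (!g.dinf && x[0] < drho) ? x[0] : drho;
  sd[2] = x[0] - g.x_pl;         // depth above the outer plane
  int k = 0;
  if (sd[1] > sd[k]) k = 1;
  if (sd[2] > sd[k]) k = 2;
  double depth = sd[k];
  if (depth >= p.dcut93) return 0.0;
  double fm;
  double U = w93(std::max(depth, 1e-9), p, &fm);
  if (fcap > 0.0 && fm > fcap) fm = fcap;
  // force along the gradient of the active depth (away from the wall)
  if (k == 2) {
    f[0] += fm;
  } else if (k == 1 && !(!g.dinf && x[0] < drho)) {
    if (rho > 1e-12) {
      f[1] -= fm * x[1] / rho;
      f[2] -= fm * x[2] / rho;
    }
  } else if (k == 1) {
    f[0] += fm;                  // tube end-cap depth (x), finite-D only
  } else if (!g.dinf) {
    double r = std::sqrt(x[0] * x[0] + rho2);
    if (r > 1e-12) {
      f[0] -= fm * x[0] / r;
      f[1] -= fm * x[1] / r;
      f[2] -= fm * x[2] / r;
    }
  } else {
    f[0] -= fm;
  }
  return U;
}

// Total conservative forces; returns potential energy.
static double forces(const std::vector<double>& x, int N, const Pot& p,
                     const Geom& g, double fcap, std::vector<double>& f) {
  std::fill(f.begin(), f.end(), 0.0);
  double U = 0.0;
  // WCA, all pairs
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < p.rc2_wca) {
        if (r2 < 1e-12) r2 = 1e-12;
        double sr2 = p.sigma * p.sigma / r2;
        double sr6 = sr2 * sr2 * sr2;
        double sr12 = sr6 * sr6;
        U += 4.0 * p.eps * (sr12 - sr6) + p.eps;
        double fr = 24.0 * p.eps * (2.0 * sr12 - sr6) / r2;  // f/r
        if (fcap > 0.0) {
          double fmagr = fr * std::sqrt(r2);
          if (fmagr > fcap) fr = fcap / std::sqrt(r2);
        }
        f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
        f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
      }
    }
  }
  // harmonic bonds
  for (int i = 0; i < N - 1; ++i) {
    double dx = x[3 * (i + 1)] - x[3 * i];
    double dy = x[3 * (i + 1) + 1] - x[3 * i + 1];
    double dz = x[3 * (i + 1) + 2] - x[3 * i + 2];
    double b = std::sqrt(dx * dx + dy * dy + dz * dz);
    U += 0.5 * p.k * (b - p.b0) * (b - p.b0);
    double c = -p.k * (b - p.b0) / std::max(b, 1e-12);
    if (fcap > 0.0) {
      double fb = std::fabs(c) * b;
      if (fb > fcap) c *= fcap / fb;
    }
    f[3 * (i + 1)] += c * dx; f[3 * (i + 1) + 1] += c * dy; f[3 * (i + 1) + 2] += c * dz;
    f[3 * i] -= c * dx; f[3 * i + 1] -= c * dy; f[3 * i + 2] -= c * dz;
  }
  // walls
  for (int i = 0; i < N; ++i) {
    U += conf_one(&x[3 * i], p, g, fcap, &f[3 * i]);
  }
  return U;
}

// [[Rcpp::export]]
List wca_ef_cpp(NumericVector r, double eps, double sigma) {
  int n = r.size();
  NumericVector U(n), F(n);
  double rc = std::pow(2.0, 1.0 / 6.0) * sigma;
  for (int i = 0; i < n; ++i) {
    if (r[i] <= 0) stop("overlap: r must be positive");
    if (r[i] > rc) { U[i] = 0; F[i] = 0; continue; }
    double sr6 = std::pow(sigma / r[i], 6.0);
    U[i] = 4.0 * eps * (sr6 * sr6 - sr6) + eps;
    F[i] = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r[i];  // -dU/dr
  }
  return List::create(_["energy"] = U, _["force"] = F);
}

// [[Rcpp::export]]
List bond_ef_cpp(NumericVector b, double k, double b0) {
  int n = b.size();
  NumericVector U(n), F(n);
  for (int i = 0; i < n; ++i) {
    U[i] = 0.5 * k * (b[i] - b0) * (b[i] - b0);
    F[i] = -k * (b[i] - b0);  // -dU/db
  }
  return List::create(_["energy"] = U, _["force"] = F);
}

// [[Rcpp::export]]
List wall93_ef_cpp(NumericVector d, double epsw, double sigw) {
  Pot p; p.epsw = epsw; p.sigw = sigw;
  p.dcut93 = std::pow(0.4, 1.0 / 6.0) * sigw;
  double s3 = std::pow(sigw / p.dcut93, 3.0);
  p.shift93 = -(2.0 / 15.0 * s3 * s3 * s3 - s3);
  int n = d.size();
  NumericVector U(n), F(n);
  for (int i = 0; i < n; ++i) {
    if (d[i] <= 0) stop("overlap: wall distance must be positive");
    double fm;
    U[i] = w93(d[i], p, &fm);
    F[i] = fm;
  }
  return List::create(_["energy"] = U, _["force"] = F);
}

// [[Rcpp::export]]
List confinement_ef_cpp(NumericMatrix pos, List geom, List pot) {
  Pot p = make_pot(pot);
  Geom g = make_geom(geom);
  int N = pos.nrow();
  NumericVector U(N);
  NumericMatrix F(N, 3);
  for (int i = 0; i < N; ++i) {
    double x[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double f[3] = {0, 0, 0};
    U[i] = conf_one(x, p, g, -1.0, f);
    F(i, 0) = f[0]; F(i, 1) = f[1]; F(i, 2) = f[2];
  }
  return List::create(_["energy"] = U, _["force"] = F);
}

// [[Rcpp::export]]
double potential_energy_cpp(NumericMatrix pos, List geom, List pot) {
  Pot p = make_pot(pot);
  Geom g = make_geom(geom);
  int N = pos.nrow();
  std::vector<double> x(3 * N), f(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  return forces(x, N, p, g, -1.0, f);
}

// BAOAB Langevin integrator with optional head-bead constraints and
// entrance-plane event recording.
// [[Rcpp::export]]
List run_md_cpp(NumericMatrix pos0, NumericMatrix vel0, double time0,
                List geom, List pot, double temp, double gamma_,
                double dt, double fcap, double nsteps_d,
                double sample_every, bool thermostat, bool hold_head,
                bool head_noreturn, bool record_events,
                bool stop_on_complete, bool confine_cavity) {
  Pot p = make_pot(pot);
  Geom g = make_geom(geom);
  const int N = pos0.nrow();
  const long nsteps = (long)nsteps_d;
  std::vector<double> x(3 * N), v(3 * N), f(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = pos0(i, d);
      v[3 * i + d] = vel0(i, d);
    }
  RNGScope rngscope;
  double c1 = 1.0, c2 = 0.0;
  if (thermostat) {
    c1 = std::exp(-gamma_ * dt);
    c2 = std::sqrt((1.0 - c1 * c1) * temp);  // bead mass = 1
  }
  std::vector<int> outside(N);
  int m = 0;
  for (int i = 0; i < N; ++i) {
    outside[i] = (x[3 * i] >= g.x_en) ? 1 : 0;
    if (!outside[i]) ++m;
  }
  bool head_past_exit = (x[0] >= g.x_w);
  double head_exit_time = head_past_exit ? time0 : NA_REAL;
  std::vector<double> ev_t; std::vector<int> ev_b; std::vector<int> ev_d;
  std::vector<double> smp_t; std::vector<int> smp_m;
  double t = time0;
  double next_sample = (sample_every > 0) ? time0 : R_PosInf;
  double max_bond = 0.0, min_bond = R_PosInf;
  double ke_sum = 0.0; long ke_n = 0;
  bool completed = false;
  double completion_time = NA_REAL;
  double last_zero_time = NA_REAL;

  forces(x, N, p, g, fcap, f);
  int hstart = hold_head ? 1 : 0;
  long step = 0;
  for (step = 0; step < nsteps; ++step) {
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
    // B: half kick
    for (int i = hstart; i < N; ++i)
      for (int d = 0; d < 3; ++d) v[3 * i + d] += 0.5 * dt * f[3 * i + d];
    // A: half drift
    for (int i = hstart; i < N; ++i)
      for (int d = 0; d < 3; ++d) x[3 * i + d] += 0.5 * dt * v[3 * i + d];
    // O: Ornstein-Uhlenbeck
    if (thermostat) {
      for (int i = hstart; i < N; ++i)
        for (int d = 0; d < 3; ++d)
          v[3 * i + d] = c1 * v[3 * i + d] + c2 * norm_rand();
    }
    // A: half drift
    for (int i = hstart; i < N; ++i)
      for (int d = 0; d < 3; ++d) x[3 * i + d] += 0.5 * dt * v[3 * i + d];
    // one-sided no-return restraint on the head bead (permanent: the
    // pore-entrance mechanism bars the head from the cavity for the whole
    // run; without it, unbiased low-phi0 runs can fall back and stall)
    if (head_noreturn && x[0] < g.x_en) {
      x[0] = 2.0 * g.x_en - x[0];
      v[0] = -v[0];
    }
    // during loading/equilibration the head blocks the pore: keep every
    // other bead on the cavity side of the entrance plane
    if (confine_cavity) {
      for (int i = 1; i < N; ++i) {
        if (x[3 * i] > g.x_en) {
          x[3 * i] = 2.0 * g.x_en - x[3 * i];
          v[3 * i] = -v[3 * i];
        }
      }
    }
    // B: half kick with new forces
    forces(x, N, p, g, fcap, f);
    for (int i = hstart; i < N; ++i)
      for (int d = 0; d < 3; ++d) {
        if (!std::isfinite(f[3 * i + d]))
          stop("non-finite force on bead %d: integration unstable", i + 1);
        v[3 * i + d] += 0.5 * dt * f[3 * i + d];
      }
    t = time0 + (step + 1) * dt;
    // entrance-plane crossings
    for (int i = 0; i < N; ++i) {
      int out_now = (x[3 * i] >= g.x_en) ? 1 : 0;
      if (out_now != outside[i]) {
        if (record_events) {
          ev_t.push_back(t);
          ev_b.push_back(i + 1);
          ev_d.push_back(out_now ? 1 : -1);  // 1 = out, -1 = back
        }
        m += out_now ? -1 : 1;
        outside[i] = out_now;
        if (m == 0) last_zero_time = t;
      }
    }
    if (!head_past_exit && x[0] >= g.x_w) {
      head_past_exit = true;
      head_exit_time = t;
    }
    // sampling
    if (t >= next_sample) {
      smp_t.push_back(t);
      smp_m.push_back(m);
      next_sample += sample_every;
    }
    // diagnostics
    if ((step & 15) == 0) {
      for (int i = 0; i < N - 1; ++i) {
        double dx = x[3 * (i + 1)] - x[3 * i];
        double dy = x[3 * (i + 1) + 1] - x[3 * i + 1];
        double dz = x[3 * (i + 1) + 2] - x[3 * i + 2];
        double b = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (b > max_bond) max_bond = b;
        if (b < min_bond) min_bond = b;
      }
      double ke = 0.0;
      for (int i = hstart; i < N; ++i)
        for (int d = 0; d < 3; ++d) ke += 0.5 * v[3 * i + d] * v[3 * i + d];
      ke_sum += ke / (N - hstart);
      ++ke_n;
    }
    if (stop_on_complete && m == 0) {
      bool all_past = true;
      for (int i = 0; i < N; ++i)
        if (x[3 * i] < g.x_w) { all_past = false; break; }
      if (all_past) {
        completed = true;
        completion_time = last_zero_time;
        break;
      }
    }
  }
  NumericMatrix pos(N, 3), vel(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) {
      pos(i, d) = x[3 * i + d];
      vel(i, d) = v[3 * i + d];
    }
  return List::create(
    _["positions"] = pos, _["velocities"] = vel, _["time"] = t,
    _["m"] = m,
    _["event_time"] = wrap(ev_t), _["event_bead"] = wrap(ev_b),
    _["event_dir"] = wrap(ev_d),
    _["sample_time"] = wrap(smp_t), _["sample_m"] = wrap(smp_m),
    _["completed"] = completed, _["completion_time"] = completion_time,
    _["head_exit_time"] = head_exit_time,
    _["steps_done"] = (double)(step < nsteps ? step + 1 : nsteps),
    _["max_bond"] = max_bond, _["min_bond"] = min_bond,
    _["mean_kinetic_temp"] = ke_n > 0 ? ke_sum / ke_n * 2.0 / 3.0 : NA_REAL);
}
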
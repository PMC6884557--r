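// Compiled core: membrane distance queries, force field (WCA + FENE +
// continuous-surface wall/pore LJ + pulling force) and the Langevin
// velocity-Verlet loops.  All lengths in sigma, energies in eps0, masses in
// m, times in t_LJ = sqrt(m sigma^2 / eps0).  Randomness comes from R's RNG
// (norm_rand under RNGScope) so set.seed() in R controls every draw.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <sstream>
using namespace Rcpp;

static const double BIG_DIST = 1e12;   // "no interaction" sentinel distance
static const double AXIS_EPS = 1e-9;   // below this radial offset the lateral
                                       // gradient of an axisymmetric distance
                                       // is taken as zero (symmetric limit)

struct Geom {
  double cis_x, trans_x, R, cy, cz;
};

struct Model {
  int n;
  double sigma, mass, kT, xi;
  double fene_k, fene_r0;
  double eps_mm;        // monomer-monomer and monomer-wall well depth
  double eps_pore;      // monomer-pore well depth
  double rc_wca, rc_pore;
  double pore_tail;     // constant added to the pore LJ inside the cutoff:
                        // +eps_pore for the literal dialect, -U_LJ(rc) for
                        // the truncated-and-shifted dialect
  double f_pull;
  Geom g;
};

static Geom geom_from_list(const List& gl) {
  Geom g;
  g.cis_x   = as<double>(gl["cis_plane_x"]);
  g.trans_x = as<double>(gl["trans_plane_x"]);
  g.R       = as<double>(gl["pore_radius"]);
  NumericVector c = gl["pore_center"];
  g.cy = c[1];
  g.cz = c[2];
  return g;
}

static Model model_from_list(const List& ml) {
  Model m;
  m.n        = as<int>(ml["n"]);
  m.sigma    = as<double>(ml["sigma"]);
  m.mass     = as<double>(ml["mass"]);
  m.kT       = as<double>(ml["kT"]);
  m.xi       = as<double>(ml["xi"]);
  m.fene_k   = as<double>(ml["fene_k"]);
  m.fene_r0  = as<double>(ml["fene_r0"]);
  m.eps_mm   = as<double>(ml["eps_mm"]);
  m.eps_pore = as<double>(ml["eps_pore"]);
  m.rc_wca   = as<double>(ml["cutoff_wca"]);
  m.rc_pore  = as<double>(ml["cutoff_pore"]);
  m.f_pull   = as<double>(ml["pull_force"]);
  m.g        = geom_from_list(ml["geom"]);
  const bool shifted = as<bool>(ml["pore_shifted"]);
  const double sr6 = std::pow(m.sigma / m.rc_pore, 6.0);
  const double u_rc = 4.0 * m.eps_pore * (sr6 * sr6 - sr6);
  m.pore_tail = shifted ? -u_rc : m.eps_pore;
  return m;
}

// ---- scalar potentials ----------------------------------------------------

// plain LJ energy (no tail) and radial force magnitude (>0 repulsive)
static inline double lj_energy_raw(double r, double eps, double sigma) {
  const double sr6 = std::pow(sigma / r, 6.0);
  return 4.0 * eps * (sr6 * sr6 - sr6);
}
static inline double lj_force_mag(double r, double eps, double sigma) {
  const double sr6 = std::pow(sigma / r, 6.0);
  return 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r;
}

// ---- axisymmetric membrane distances + gradients --------------------------

// Distance from a point to the union of the two annular wall faces (rim
// circle included); BIG_DIST inside the pore bore.  grad receives the
// distance gradient (unit where defined).
static double wall_dist_grad(double x, double y, double z, const Geom& g,
                             double grad[3]) {
  grad[0] = grad[1] = grad[2] = 0.0;
  const double dy = y - g.cy, dz = z - g.cz;
  const double rho = std::sqrt(dy * dy + dz * dz);
  const bool in_slab = (x >= g.cis_x && x <= g.trans_x);
  if (in_slab && rho < g.R) return BIG_DIST;  // inside the bore: cylinder only

  double best = BIG_DIST;
  const double planes[2] = { g.cis_x, g.trans_x };
  for (int k = 0; k < 2; ++k) {
    const double dx = x - planes[k];
    double d, gx, grho;
    if (rho >= g.R) {               // perpendicular foot lands on the annulus
      d = std::fabs(dx);
      gx = (dx >= 0.0) ? 1.0 : -1.0;
      grho = 0.0;
    } else {                        // nearest point is on the aperture rim
      const double dr = rho - g.R;  // negative here
      d = std::sqrt(dx * dx + dr * dr);
      gx = dx / d;
      grho = dr / d;
    }
    if (d < best) {
      best = d;
      grad[0] = gx;
      if (rho > AXIS_EPS) {
        grad[1] = grho * dy / rho;
        grad[2] = grho * dz / rho;
      } else {
        grad[1] = grad[2] = 0.0;
      }
    }
  }
  return best;
}

// Distance to the finite inner cylinder surface (rim circles included).
static double pore_dist_grad(double x, double y, double z, const Geom& g,
                             double grad[3]) {
  grad[0] = grad[1] = grad[2] = 0.0;
  const double dy = y - g.cy, dz = z - g.cz;
  const double rho = std::sqrt(dy * dy + dz * dz);
  double d, gx, grho;
  if (x >= g.cis_x && x <= g.trans_x) {
    const double dr = rho - g.R;
    d = std::fabs(dr);
    gx = 0.0;
    grho = (dr >= 0.0) ? 1.0 : -1.0;
  } else {
    const double xw = (x < g.cis_x) ? g.cis_x : g.trans_x;
    const double dx = x - xw;
    const double dr = rho - g.R;
    d = std::sqrt(dx * dx + dr * dr);
    gx = dx / d;
    grho = dr / d;
  }
  if (rho > AXIS_EPS) {
    grad[1] = grho * dy / rho;
    grad[2] = grho * dz / rho;
  }
  grad[0] = gx;
  return d;
}

static inline bool in_pore_region(double x, double y, double z, const Geom& g) {
  if (x < g.cis_x || x > g.trans_x) return false;
  const double dy = y - g.cy, dz = z - g.cz;
  return dy * dy + dz * dz < g.R * g.R;
}

// [[Rcpp::export]]
NumericVector cpp_wall_distance(NumericMatrix pts, List geom) {
  const Geom g = geom_from_list(geom);
  const int n = pts.nrow();
  NumericVector out(n);
  double grad[3];
  for (int i = 0; i < n; ++i)
    out[i] = wall_dist_grad(pts(i, 0), pts(i, 1), pts(i, 2), g, grad);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pore_surface_distance(NumericMatrix pts, List geom) {
  const Geom g = geom_from_list(geom);
  const int n = pts.nrow();
  NumericVector out(n);
  double grad[3];
  for (int i = 0; i < n; ++i)
    out[i] = pore_dist_grad(pts(i, 0), pts(i, 1), pts(i, 2), g, grad);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_region_of(NumericMatrix pts, List geom) {
  // 1 = cis, 2 = pore, 3 = trans
  const Geom g = geom_from_list(geom);
  const double mid = 0.5 * (g.cis_x + g.trans_x);
  const int n = pts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0);
    if (x < g.cis_x) { out[i] = 1; continue; }
    if (x > g.trans_x) { out[i] = 3; continue; }
    if (in_pore_region(x, pts(i, 1), pts(i, 2), g)) out[i] = 2;
    else out[i] = (x - mid < 0.0) ? 1 : 3;  // inside wall material: x-sign rule
  }
  return out;
}

// ---- full force evaluation -------------------------------------------------

struct Work {
  std::vector<double> fx, fy, fz;                 // total conservative force
  double energy;
  // optional component breakdown (only allocated for reports)
  bool components;
  std::vector<double> wx, wy, wz;                 // wca pair
  std::vector<double> bx, by, bz;                 // fene
  std::vector<double> lx, ly, lz;                 // wall
  std::vector<double> px, py, pz;                 // pore
  std::vector<double> ex, ey, ez;                 // external
};

static void overlap_stop(const char* what, int i, int j, double r) {
  std::ostringstream msg;
  msg << what << " between beads " << (i + 1) << " and " << (j + 1)
      << " (r = " << r << " sigma); the timestep is likely too large";
  stop(msg.str());
}

// Compute conservative forces (incl. external pulling force if use_external)
// and the total potential energy.  X, Y, Z are bead coordinates.
static void compute_forces(const std::vector<double>& X,
                           const std::vector<double>& Y,
                           const std::vector<double>& Z,
                           const Model& m, bool use_external, Work& w) {
  const int n = m.n;
  std::fill(w.fx.begin(), w.fx.end(), 0.0);
  std::fill(w.fy.begin(), w.fy.end(), 0.0);
  std::fill(w.fz.begin(), w.fz.end(), 0.0);
  if (w.components) {
    std::fill(w.wx.begin(), w.wx.end(), 0.0); std::fill(w.wy.begin(), w.wy.end(), 0.0); std::fill(w.wz.begin(), w.wz.end(), 0.0);
    std::fill(w.bx.begin(), w.bx.end(), 0.0); std::fill(w.by.begin(), w.by.end(), 0.0); std::fill(w.bz.begin(), w.bz.end(), 0.0);
    std::fill(w.lx.begin(), w.lx.end(), 0.0); std::fill(w.ly.begin(), w.ly.end(), 0.0); std::fill(w.lz.begin(), w.lz.end(), 0.0);
    std::fill(w.px.begin(), w.px.end(), 0.0); std::fill(w.py.begin(), w.py.end(), 0.0); std::fill(w.pz.begin(), w.pz.end(), 0.0);
    std::fill(w.ex.begin(), w.ex.end(), 0.0); std::fill(w.ey.begin(), w.ey.end(), 0.0); std::fill(w.ez.begin(), w.ez.end(), 0.0);
  }
  w.energy = 0.0;
  const double rc2_wca = m.rc_wca * m.rc_wca;

  // pair WCA over ALL pairs (bonded included) + FENE on adjacent pairs
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = X[i] - X[j], dy = Y[i] - Y[j], dz = Z[i] - Z[j];
      const double r2 = dx * dx + dy * dy + dz * dz;
      const bool bonded = (j == i + 1);
      if (r2 < rc2_wca || bonded) {
        const double r = std::sqrt(r2);
        if (r < 1e-9) overlap_stop("overlap", i, j, r);
        if (r2 < rc2_wca) {
          const double f = lj_force_mag(r, m.eps_mm, m.sigma);
          const double fxv = f * dx / r, fyv = f * dy / r, fzv = f * dz / r;
          w.fx[i] += fxv; w.fy[i] += fyv; w.fz[i] += fzv;
          w.fx[j] -= fxv; w.fy[j] -= fyv; w.fz[j] -= fzv;
          w.energy += lj_energy_raw(r, m.eps_mm, m.sigma) + m.eps_mm;
          if (w.components) {
            w.wx[i] += fxv; w.wy[i] += fyv; w.wz[i] += fzv;
            w.wx[j] -= fxv; w.wy[j] -= fyv; w.wz[j] -= fzv;
          }
        }
        if (bonded) {
          if (r >= m.fene_r0) overlap_stop("FENE bond overstretch", i, j, r);
          const double x2 = (r * r) / (m.fene_r0 * m.fene_r0);
          const double f = -m.fene_k * r / (1.0 - x2);  // attractive
          const double fxv = f * dx / r, fyv = f * dy / r, fzv = f * dz / r;
          w.fx[i] += fxv; w.fy[i] += fyv; w.fz[i] += fzv;
          w.fx[j] -= fxv; w.fy[j] -= fyv; w.fz[j] -= fzv;
          w.energy += -0.5 * m.fene_k * m.fene_r0 * m.fene_r0 * std::log(1.0 - x2);
          if (w.components) {
            w.bx[i] += fxv; w.by[i] += fyv; w.bz[i] += fzv;
            w.bx[j] -= fxv; w.by[j] -= fyv; w.bz[j] -= fzv;
          }
        }
      }
    }
  }

  // membrane: repulsive WCA walls + attractive pore cylinder + pulling force
  double grad[3];
  for (int i = 0; i < n; ++i) {
    const double d_wall = wall_dist_grad(X[i], Y[i], Z[i], m.g, grad);
    if (d_wall < m.rc_wca) {
      if (d_wall < 1e-9) overlap_stop("wall overlap", i, i, d_wall);
      const double f = lj_force_mag(d_wall, m.eps_mm, m.sigma);
      w.fx[i] += f * grad[0]; w.fy[i] += f * grad[1]; w.fz[i] += f * grad[2];
      w.energy += lj_energy_raw(d_wall, m.eps_mm, m.sigma) + m.eps_mm;
      if (w.components) {
        w.lx[i] += f * grad[0]; w.ly[i] += f * grad[1]; w.lz[i] += f * grad[2];
      }
    }
    if (m.eps_pore != 0.0) {
      const double d_pore = pore_dist_grad(X[i], Y[i], Z[i], m.g, grad);
      if (d_pore < m.rc_pore) {
        if (d_pore < 1e-9) overlap_stop("pore-surface overlap", i, i, d_pore);
        const double f = lj_force_mag(d_pore, m.eps_pore, m.sigma);
        w.fx[i] += f * grad[0]; w.fy[i] += f * grad[1]; w.fz[i] += f * grad[2];
        w.energy += lj_energy_raw(d_pore, m.eps_pore, m.sigma) + m.pore_tail;
        if (w.components) {
          w.px[i] += f * grad[0]; w.py[i] += f * grad[1]; w.pz[i] += f * grad[2];
        }
      }
    }
    if (use_external && in_pore_region(X[i], Y[i], Z[i], m.g)) {
      w.fx[i] += m.f_pull;
      if (w.components) w.ex[i] += m.f_pull;
    }
  }
}

static Work make_work(int n, bool components) {
  Work w;
  w.fx.assign(n, 0.0); w.fy.assign(n, 0.0); w.fz.assign(n, 0.0);
  w.components = components;
  if (components) {
    w.wx.assign(n, 0.0); w.wy.assign(n, 0.0); w.wz.assign(n, 0.0);
    w.bx.assign(n, 0.0); w.by.assign(n, 0.0); w.bz.assign(n, 0.0);
    w.lx.assign(n, 0.0); w.ly.assign(n, 0.0); w.lz.assign(n, 0.0);
    w.px.assign(n, 0.0); w.py.assign(n, 0.0); w.pz.assign(n, 0.0);
    w.ex.assign(n, 0.0); w.ey.assign(n, 0.0); w.ez.assign(n, 0.0);
  }
  w.energy = 0.0;
  return w;
}

static NumericMatrix bind3(const std::vector<double>& a,
                           const std::vector<double>& b,
                           const std::vector<double>& c) {
  const int n = (int)a.size();
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i) { m(i, 0) = a[i]; m(i, 1) = b[i]; m(i, 2) = c[i]; }
  return m;
}

// [[Rcpp::export]]
List cpp_total_forces(NumericMatrix pos, List model, bool use_external) {
  const Model m = model_from_list(model);
  const int n = m.n;
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = pos(i, 0); Y[i] = pos(i, 1); Z[i] = pos(i, 2); }
  Work w = make_work(n, true);
  compute_forces(X, Y, Z, m, use_external, w);
  return List::create(
    _["total"] = bind3(w.fx, w.fy, w.fz),
    _["wca_pair"] = bind3(w.wx, w.wy, w.wz),
    _["fene"] = bind3(w.bx, w.by, w.bz),
    _["wall"] = bind3(w.lx, w.ly, w.lz),
    _["pore"] = bind3(w.px, w.py, w.pz),
    _["external"] = bind3(w.ex, w.ey, w.ez),
    _["potential_energy"] = w.energy);
}

// ---- Langevin velocity-Verlet ---------------------------------------------
//
// One step (BBK-type, semi-implicit in the friction of the second half-kick;
// the random force is drawn once per step and held constant across it):
//   v_half = v (1 - a) + b (F + R)            a = xi dt / 2m, b = dt / 2m
//   x     += dt v_half
//   F      = F(x_new)
//   v_new  = (v_half + b (F + R)) / (1 + a)
// With xi = 0 and no noise this is exactly deterministic velocity Verlet.
// For a free particle the stationary velocity variance is exactly kT/m at
// any dt, and the per-step damping factor (1-a)/(1+a) matches exp(-xi dt/m)
// to third order.

struct Stepper {
  Model m;
  double dt, a, b, noise_sd;
  bool thermostat, use_external;
  std::vector<int> free_idx;      // indices of beads allowed to move
  std::vector<double> rx, ry, rz; // per-step random forces
  Work w;
  double time;

  void init(const Model& mm, double dt_, bool thermostat_, bool use_external_,
            const std::vector<int>& free_idx_) {
    m = mm; dt = dt_;
    thermostat = thermostat_; use_external = use_external_;
    a = m.xi * dt / (2.0 * m.mass);
    b = dt / (2.0 * m.mass);
    noise_sd = std::sqrt(2.0 * m.xi * m.kT / dt);
    free_idx = free_idx_;
    rx.assign(m.n, 0.0); ry.assign(m.n, 0.0); rz.assign(m.n, 0.0);
    w = make_work(m.n, false);
    time = 0.0;
  }

  void forces(const std::vector<double>& X, const std::vector<double>& Y,
              const std::vector<double>& Z) {
    compute_forces(X, Y, Z, m, use_external, w);
  }

  // advance one step; assumes w holds forces at the current positions
  void step(std::vector<double>& X, std::vector<double>& Y,
            std::vector<double>& Z, std::vector<double>& VX,
            std::vector<double>& VY, std::vector<double>& VZ) {
    if (thermostat) {
      for (int k : free_idx) {
        rx[k] = noise_sd * norm_rand();
        ry[k] = noise_sd * norm_rand();
        rz[k] = noise_sd * norm_rand();
      }
    }
    for (int k : free_idx) {
      VX[k] = VX[k] * (1.0 - a) + b * (w.fx[k] + rx[k]);
      VY[k] = VY[k] * (1.0 - a) + b * (w.fy[k] + ry[k]);
      VZ[k] = VZ[k] * (1.0 - a) + b * (w.fz[k] + rz[k]);
      X[k] += dt * VX[k];
      Y[k] += dt * VY[k];
      Z[k] += dt * VZ[k];
    }
    forces(X, Y, Z);
    const double inv = 1.0 / (1.0 + a);
    for (int k : free_idx) {
      VX[k] = (VX[k] + b * (w.fx[k] + rx[k])) * inv;
      VY[k] = (VY[k] + b * (w.fy[k] + ry[k])) * inv;
      VZ[k] = (VZ[k] + b * (w.fz[k] + rz[k])) * inv;
    }
    time += dt;
  }
};

static void unpack_state(const NumericMatrix& pos, const NumericMatrix& vel,
                         std::vector<double>& X, std::vector<double>& Y,
                         std::vector<double>& Z, std::vector<double>& VX,
                         std::vector<double>& VY, std::vector<double>& VZ) {
  const int n = pos.nrow();
  X.resize(n); Y.resize(n); Z.resize(n);
  VX.resize(n); VY.resize(n); VZ.resize(n);
  for (int i = 0; i < n; ++i) {
    X[i] = pos(i, 0); Y[i] = pos(i, 1); Z[i] = pos(i, 2);
    VX[i] = vel(i, 0); VY[i] = vel(i, 1); VZ[i] = vel(i, 2);
  }
}

static std::vector<int> free_indices(int n, const LogicalVector& pinned) {
  std::vector<int> idx;
  for (int i = 0; i < n; ++i)
    if (pinned.size() == 0 || !pinned[i]) idx.push_back(i);
  return idx;
}

static double kinetic_energy(const std::vector<int>& idx, double mass,
                             const std::vector<double>& VX,
                             const std::vector<double>& VY,
                             const std::vector<double>& VZ) {
  double ke = 0.0;
  for (int k : idx)
    ke += 0.5 * mass * (VX[k] * VX[k] + VY[k] * VY[k] + VZ[k] * VZ[k]);
  return ke;
}

// Plain fixed-length run.  Optionally records total energy every
// energy_every steps and accumulates per-component velocity second moments
// of the free beads after vel_burnin steps.
// [[Rcpp::export]]
List cpp_run_plain(NumericMatrix pos, NumericMatrix vel, List model,
                   double dt, int n_steps, bool thermostat, bool use_external,
                   LogicalVector pinned, int energy_every, int vel_burnin) {
  RNGScope scope;
  const Model m = model_from_list(model);
  std::vector<double> X, Y, Z, VX, VY, VZ;
  unpack_state(pos, vel, X, Y, Z, VX, VY, VZ);
  Stepper st;
  st.init(m, dt, thermostat, use_external, free_indices(m.n, pinned));
  st.forces(X, Y, Z);

  std::vector<double> e_times, e_vals;
  double sv2x = 0.0, sv2y = 0.0, sv2z = 0.0;
  long long nv = 0;
  if (energy_every > 0) {
    e_times.push_back(0.0);
    e_vals.push_back(st.w.energy + kinetic_energy(st.free_idx, m.mass, VX, VY, VZ));
  }
  for (int s = 1; s <= n_steps; ++s) {
    st.step(X, Y, Z, VX, VY, VZ);
    if (energy_every > 0 && s % energy_every == 0) {
      e_times.push_back(st.time);
      e_vals.push_back(st.w.energy + kinetic_energy(st.free_idx, m.mass, VX, VY, VZ));
    }
    if (vel_burnin >= 0 && s > vel_burnin) {
      for (int k : st.free_idx) {
        sv2x += VX[k] * VX[k]; sv2y += VY[k] * VY[k]; sv2z += VZ[k] * VZ[k];
        ++nv;
      }
    }
  }
  NumericMatrix opos(m.n, 3), ovel(m.n, 3);
  for (int i = 0; i < m.n; ++i) {
    opos(i, 0) = X[i]; opos(i, 1) = Y[i]; opos(i, 2) = Z[i];
    ovel(i, 0) = VX[i]; ovel(i, 1) = VY[i]; ovel(i, 2) = VZ[i];
  }
  return List::create(
    _["positions"] = opos, _["velocities"] = ovel,
    _["time"] = st.time,
    _["energy_times"] = wrap(e_times), _["energies"] = wrap(e_vals),
    _["v2_mean"] = nv > 0
        ? NumericVector::create(sv2x / nv, sv2y / nv, sv2z / nv)
        : NumericVector::create(NA_REAL, NA_REAL, NA_REAL),
    _["v2_n"] = (double)nv);
}

// Equilibration of the unpinned tail: no external force; every sample_every
// steps the radius of gyration of the free beads is recorded; terminates when
// the range of the last `window` samples drops below rg_tol.
// [[Rcpp::export]]
List cpp_run_equilibrate(NumericMatrix pos, NumericMatrix vel, List model,
                         double dt, int max_steps, LogicalVector pinned,
                         int sample_every, int window, double rg_tol) {
  RNGScope scope;
  const Model m = model_from_list(model);
  std::vector<double> X, Y, Z, VX, VY, VZ;
  unpack_state(pos, vel, X, Y, Z, VX, VY, VZ);
  Stepper st;
  st.init(m, dt, true, false, free_indices(m.n, pinned));
  st.forces(X, Y, Z);
  const std::vector<int>& idx = st.free_idx;
  if (idx.empty()) stop("no free beads to equilibrate");

  std::vector<double> rg_trace;
  bool converged = false;
  int steps_used = 0;
  for (int s = 1; s <= max_steps; ++s) {
    st.step(X, Y, Z, VX, VY, VZ);
    steps_used = s;
    if (s % sample_every == 0) {
      double cx = 0, cy = 0, cz = 0;
      for (int k : idx) { cx += X[k]; cy += Y[k]; cz += Z[k]; }
      const double nfree = (double)idx.size();
      cx /= nfree; cy /= nfree; cz /= nfree;
      double s2 = 0;
      for (int k : idx) {
        const double dx = X[k] - cx, dy = Y[k] - cy, dz = Z[k] - cz;
        s2 += dx * dx + dy * dy + dz * dz;
      }
      rg_trace.push_back(std::sqrt(s2 / nfree));
      const int nsamp = (int)rg_trace.size();
      if (nsamp >= window) {
        double lo = rg_trace[nsamp - window], hi = lo;
        for (int k = nsamp - window; k < nsamp; ++k) {
          lo = std::min(lo, rg_trace[k]);
          hi = std::max(hi, rg_trace[k]);
        }
        if (hi - lo < rg_tol) { converged = true; break; }
      }
    }
  }
  NumericMatrix opos(m.n, 3), ovel(m.n, 3);
  for (int i = 0; i < m.n; ++i) {
    opos(i, 0) = X[i]; opos(i, 1) = Y[i]; opos(i, 2) = Z[i];
    ovel(i, 0) = VX[i]; ovel(i, 1) = VY[i]; ovel(i, 2) = VZ[i];
  }
  return List::create(
    _["positions"] = opos, _["velocities"] = ovel,
    _["steps"] = steps_used, _["converged"] = converged,
    _["rg_trace"] = wrap(rg_trace));
}

// Translocation run: full thermostat + pulling force; records the first time
// the count of beads past the trans plane reaches each s (monotone
// first-passage watermark).  Optionally snapshots positions at each such
// instant.  Status: 0 completed, 1 retracted, 2 timed out.
// [[Rcpp::export]]
List cpp_run_translocate(NumericMatrix pos, NumericMatrix vel, List model,
                         double dt, int max_steps, bool record_snapshots) {
  RNGScope scope;
  const Model m = model_from_list(model);
  std::vector<double> X, Y, Z, VX, VY, VZ;
  unpack_state(pos, vel, X, Y, Z, VX, VY, VZ);
  Stepper st;
  st.init(m, dt, true, true, free_indices(m.n, LogicalVector(0)));
  st.forces(X, Y, Z);

  const double trans_x = m.g.trans_x, cis_x = m.g.cis_x;
  NumericVector exit_times(m.n, NA_REAL);
  List snapshots(record_snapshots ? m.n : 0);
  int watermark = 0;
  int status = 2;
  for (int s = 1; s <= max_steps; ++s) {
    st.step(X, Y, Z, VX, VY, VZ);
    int count = 0, n_cis = 0;
    for (int i = 0; i < m.n; ++i) {
      if (X[i] > trans_x) ++count;
      else if (X[i] < cis_x) ++n_cis;
    }
    while (watermark < count) {
      ++watermark;
      exit_times[watermark - 1] = st.time;
      if (record_snapshots) {
        NumericMatrix snap(m.n, 3);
        for (int i = 0; i < m.n; ++i) {
          snap(i, 0) = X[i]; snap(i, 1) = Y[i]; snap(i, 2) = Z[i];
        }
        snapshots[watermark - 1] = snap;
      }
    }
    if (watermark == m.n) { status = 0; break; }
    if (n_cis == m.n) { status = 1; break; }
    if (s % 20000 == 0) checkUserInterrupt();
  }
  NumericMatrix opos(m.n, 3), ovel(m.n, 3);
  for (int i = 0; i < m.n; ++i) {
    opos(i, 0) = X[i]; opos(i, 1) = Y[i]; opos(i, 2) = Z[i];
    ovel(i, 0) = VX[i]; ovel(i, 1) = VY[i]; ovel(i, 2) = VZ[i];
  }
  return List::create(
    _["positions"] = opos, _["velocities"] = ovel,
    _["exit_times"] = exit_times, _["status"] = status,
    _["time"] = st.time, _["snapshots"] = snapshots);
}
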
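#include "pathmeta.h"
#include "potentials.h"
#include "pathcv.h"

// ---------------------------------------------------------------------------
// BAOAB Langevin integrator. Forces in kcal/mol/A are converted to mechanical
// units (amu A ps^-2) with KCAL_TO_MECH. friction = 0 reduces to velocity
// Verlet (NVE).
// ---------------------------------------------------------------------------

struct Integrator {
  Pot pot;
  int n;
  std::vector<double> mass, x, v, f;
  double dt, gamma, kT; // kT in kcal/mol
  double c1;
  std::vector<double> c2; // per atom
  Rng rng;
  long step_count;

  Integrator(Rcpp::List spec, Rcpp::NumericMatrix x0, Rcpp::NumericVector masses,
             double temperature, double friction, double timestep,
             std::uint64_t seed)
      : pot(parse_pot(spec)), n(x0.nrow()), dt(timestep), gamma(friction),
        rng(seed), step_count(0) {
    if (n != pot.n_atoms) Rcpp::stop("coordinate/atom count mismatch");
    kT = KB_KCAL * temperature;
    mass.resize(n);
    for (int i = 0; i < n; ++i) mass[i] = masses[i % masses.size()];
    x.resize(3 * n); v.assign(3 * n, 0.0); f.assign(3 * n, 0.0);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) x[3 * i + d] = x0(i, d);
    c1 = std::exp(-gamma * dt);
    c2.resize(n);
    double kT_mech = kT * KCAL_TO_MECH;
    for (int i = 0; i < n; ++i)
      c2[i] = std::sqrt(kT_mech * (1.0 - c1 * c1) / mass[i]);
  }

  void draw_velocities() {
    double kT_mech = kT * KCAL_TO_MECH;
    for (int i = 0; i < n; ++i) {
      double s = std::sqrt(kT_mech / mass[i]);
      for (int d = 0; d < 3; ++d) v[3 * i + d] = s * rng.gauss();
    }
  }

  void set_velocities(Rcpp::NumericMatrix v0) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v[3 * i + d] = v0(i, d);
  }

  double kinetic() const { // kcal/mol
    double e = 0.0;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        e += 0.5 * mass[i] * v[3 * i + d] * v[3 * i + d];
    return e / KCAL_TO_MECH;
  }

  // Bias must ADD forces (kcal/mol/A) to f given time and positions.
  template <class BiasF> void compute_forces(double t, BiasF&& bias) {
    std::fill(f.begin(), f.end(), 0.0);
    pot_eval(pot, x.data(), f.data());
    bias(t, x.data(), f.data());
  }

  template <class BiasF> void step(double t_next, BiasF&& bias) {
    double hdt = 0.5 * dt;
    for (int i = 0; i < n; ++i) {
      double im = KCAL_TO_MECH / mass[i];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += hdt * f[3 * i + d] * im;
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += hdt * v[i];
    if (gamma > 0.0) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          v[3 * i + d] = c1 * v[3 * i + d] + c2[i] * rng.gauss();
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += hdt * v[i];
    compute_forces(t_next, bias);
    for (int i = 0; i < n; ++i) {
      double im = KCAL_TO_MECH / mass[i];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += hdt * f[3 * i + d] * im;
    }
    ++step_count;
    if (step_count % 64 == 0) {
      bool ok = true;
      for (int i = 0; i < 3 * n && ok; ++i)
        if (!std::isfinite(x[i])) ok = false;
      if (!ok)
        Rcpp::stop("non-finite coordinates at step %ld: integration aborted",
                   step_count);
      if (step_count % 200000 == 0) Rcpp::checkUserInterrupt();
    }
  }
};

static void no_bias(double, const double*, double*) {}

// [[Rcpp::export(name = ".langevin_run_cpp")]]
Rcpp::List langevin_run_cpp(Rcpp::List spec, Rcpp::NumericMatrix x0,
                            Rcpp::NumericVector masses, double temperature,
                            double friction, double timestep, int n_steps,
                            double seed, int record_stride,
                            Rcpp::Nullable<Rcpp::Function> bias,
                            Rcpp::Nullable<Rcpp::NumericMatrix> v0) {
  Integrator sim(spec, x0, masses, temperature, friction, timestep,
                 (std::uint64_t)seed);
  if (v0.isNotNull()) sim.set_velocities(Rcpp::NumericMatrix(v0));
  else sim.draw_velocities();

  bool has_bias = bias.isNotNull();
  Rcpp::Function bias_fn = has_bias ? Rcpp::Function(bias) : Rcpp::Function("identity");
  Rcpp::NumericMatrix xbuf(sim.n, 3);
  auto biasf = [&](double t, const double* x, double* f) {
    if (!has_bias) return;
    for (int i = 0; i < sim.n; ++i)
      for (int d = 0; d < 3; ++d) xbuf(i, d) = x[3 * i + d];
    Rcpp::NumericMatrix fb = bias_fn(t, xbuf);
    for (int i = 0; i < sim.n; ++i)
      for (int d = 0; d < 3; ++d) f[3 * i + d] += fb(i, d);
  };

  int n_rec = n_steps / record_stride + 1;
  std::vector<double> coords;
  coords.reserve((size_t)3 * sim.n * n_rec);
  std::vector<double> times, epot, ekin;

  sim.compute_forces(0.0, biasf);
  auto record = [&](double t) {
    for (int i = 0; i < 3 * sim.n; ++i) coords.push_back(sim.x[i]);
    times.push_back(t);
    epot.push_back(pot_eval(sim.pot, sim.x.data(), nullptr));
    ekin.push_back(sim.kinetic());
  };
  record(0.0);
  for (int s = 1; s <= n_steps; ++s) {
    double t = s * timestep;
    sim.step(t, biasf);
    if (s % record_stride == 0) record(t);
  }

  return Rcpp::List::create(
      Rcpp::Named("coords") = coords, Rcpp::Named("times") = times,
      Rcpp::Named("potential_energy") = epot, Rcpp::Named("kinetic_energy") = ekin,
      Rcpp::Named("n_atoms") = sim.n);
}

// COM-distance reaction coordinate helpers -----------------------------------
static double com_distance(const double* x, const std::vector<int>& ga,
                           const std::vector<int>& gb, double u[3]) {
  double ca[3] = {0, 0, 0}, cb[3] = {0, 0, 0};
  for (size_t i = 0; i < ga.size(); ++i)
    for (int d = 0; d < 3; ++d) ca[d] += x[3 * ga[i] + d];
  for (size_t i = 0; i < gb.size(); ++i)
    for (int d = 0; d < 3; ++d) cb[d] += x[3 * gb[i] + d];
  for (int d = 0; d < 3; ++d) {
    ca[d] /= ga.size();
    cb[d] /= gb.size();
  }
  double r = 0.0;
  for (int d = 0; d < 3; ++d) {
    u[d] = ca[d] - cb[d];
    r += u[d] * u[d];
  }
  r = std::sqrt(r);
  if (r > 1e-10)
    for (int d = 0; d < 3; ++d) u[d] /= r;
  return r;
}

// [[Rcpp::export(name = ".smd_run_cpp")]]
Rcpp::List smd_run_cpp(Rcpp::List spec, Rcpp::NumericMatrix x0,
                       Rcpp::NumericVector masses, double temperature,
                       double friction, double timestep, int n_steps,
                       double seed, int record_stride, int traj_stride,
                       Rcpp::IntegerVector group_a1, Rcpp::IntegerVector group_b1,
                       double k_spring, double speed, int equil_steps) {
  Integrator sim(spec, x0, masses, temperature, friction, timestep,
                 (std::uint64_t)seed);
  sim.draw_velocities();
  std::vector<int> ga, gb;
  for (int i = 0; i < group_a1.size(); ++i) ga.push_back(group_a1[i] - 1);
  for (int i = 0; i < group_b1.size(); ++i) gb.push_back(group_b1[i] - 1);

  double u[3];
  double xi0 = com_distance(sim.x.data(), ga, gb, u);
  if (xi0 < 1e-8)
    Rcpp::stop("reaction coordinate undefined: coincident centres of mass");

  // The restraint centre is held fixed during each dynamics step and
  // jumped between steps; the work is charged exactly at each jump as the
  // Hamiltonian difference at fixed configuration,
  //   dW = k/2 [(xi - c_next)^2 - (xi - c_cur)^2],
  // the discrete-protocol bookkeeping whose accumulated work obeys the
  // nonequilibrium work theorem without O(k v dt) discretization bias.
  double cur_center = xi0, cur_force = 0.0, work = 0.0;
  auto biasf = [&](double, const double* x, double* f) {
    double uu[3];
    double xi = com_distance(x, ga, gb, uu);
    double F = k_spring * (cur_center - xi); // applied force along +xi
    for (size_t i = 0; i < ga.size(); ++i)
      for (int d = 0; d < 3; ++d) f[3 * ga[i] + d] += F * uu[d] / ga.size();
    for (size_t i = 0; i < gb.size(); ++i)
      for (int d = 0; d < 3; ++d) f[3 * gb[i] + d] -= F * uu[d] / gb.size();
    cur_force = F;
  };

  std::vector<double> times, xi_s, center_s, force_s, work_s, coords, t_traj;
  // equilibrate under the static restraint before the centre starts moving
  sim.compute_forces(0.0, biasf);
  for (int s = 0; s < equil_steps; ++s) sim.step(0.0, biasf);
  double uu0[3];
  auto record = [&](double t) {
    double uu[3];
    times.push_back(t);
    xi_s.push_back(com_distance(sim.x.data(), ga, gb, uu));
    center_s.push_back(cur_center);
    force_s.push_back(cur_force);
    work_s.push_back(work);
  };
  record(0.0);
  if (traj_stride > 0) {
    for (int i = 0; i < 3 * sim.n; ++i) coords.push_back(sim.x[i]);
    t_traj.push_back(0.0);
  }
  for (int s = 1; s <= n_steps; ++s) {
    double t = s * timestep;
    double next_center = xi0 + speed * t;
    double xi_now = com_distance(sim.x.data(), ga, gb, uu0);
    work += 0.5 * k_spring * ((xi_now - next_center) * (xi_now - next_center) -
                              (xi_now - cur_center) * (xi_now - cur_center));
    cur_center = next_center;
    sim.step(t, biasf);
    if (s % record_stride == 0 || s == n_steps) record(t);
    if (traj_stride > 0 && (s % traj_stride == 0 || s == n_steps)) {
      for (int i = 0; i < 3 * sim.n; ++i) coords.push_back(sim.x[i]);
      t_traj.push_back(t);
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("times") = times, Rcpp::Named("xi") = xi_s,
      Rcpp::Named("restraint_center") = center_s, Rcpp::Named("force") = force_s,
      Rcpp::Named("work") = work_s, Rcpp::Named("coords") = coords,
      Rcpp::Named("t_traj") = t_traj, Rcpp::Named("n_atoms") = sim.n,
      Rcpp::Named("xi0") = xi0);
}

// ---------------------------------------------------------------------------
// Metadynamics on (S, Z). Bias forces come from gradient grids that each
// deposited hill is splatted onto (analytic node values, bilinear lookup);
// FES reconstruction from the hill log is done in R with exact sums.
// ---------------------------------------------------------------------------
struct BiasGrid {
  double s0, z0, ds, dz;
  int ns, nz;
  std::vector<double> gs, gz; // dV/dS, dV/dZ at nodes

  void init(double s_min, double s_max, double z_min, double z_max,
            double ds_, double dz_) {
    s0 = s_min; z0 = z_min; ds = ds_; dz = dz_;
    ns = (int)std::ceil((s_max - s_min) / ds) + 1;
    nz = (int)std::ceil((z_max - z_min) / dz) + 1;
    gs.assign((size_t)ns * nz, 0.0);
    gz.assign((size_t)ns * nz, 0.0);
  }

  void add_hill(double sc, double zc, double h, double ss, double sz) {
    int i0 = std::max(0, (int)std::floor((sc - 6 * ss - s0) / ds));
    int i1 = std::min(ns - 1, (int)std::ceil((sc + 6 * ss - s0) / ds));
    int j0 = std::max(0, (int)std::floor((zc - 6 * sz - z0) / dz));
    int j1 = std::min(nz - 1, (int)std::ceil((zc + 6 * sz - z0) / dz));
    if (i1 < i0 || j1 < j0) return;
    std::vector<double> es(i1 - i0 + 1), ez(j1 - j0 + 1), us(i1 - i0 + 1),
        uz(j1 - j0 + 1);
    for (int i = i0; i <= i1; ++i) {
      double u = (s0 + i * ds - sc) / ss;
      es[i - i0] = std::exp(-0.5 * u * u);
      us[i - i0] = u / ss;
    }
    for (int j = j0; j <= j1; ++j) {
      double u = (z0 + j * dz - zc) / sz;
      ez[j - j0] = std::exp(-0.5 * u * u);
      uz[j - j0] = u / sz;
    }
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j) {
        double g = h * es[i - i0] * ez[j - j0];
        gs[(size_t)i * nz + j] += -g * us[i - i0];
        gz[(size_t)i * nz + j] += -g * uz[j - j0];
      }
  }

  void gradient(double s, double z, double* dVds, double* dVdz) const {
    double fi = (s - s0) / ds, fj = (z - z0) / dz;
    int i = (int)std::floor(fi), j = (int)std::floor(fj);
    if (i < 0 || j < 0 || i >= ns - 1 || j >= nz - 1) {
      *dVds = 0.0; *dVdz = 0.0;
      return;
    }
    double a = fi - i, b = fj - j;
    size_t k00 = (size_t)i * nz + j, k10 = k00 + nz, k01 = k00 + 1, k11 = k10 + 1;
    *dVds = (1 - a) * (1 - b) * gs[k00] + a * (1 - b) * gs[k10] +
            (1 - a) * b * gs[k01] + a * b * gs[k11];
    *dVdz = (1 - a) * (1 - b) * gz[k00] + a * (1 - b) * gz[k10] +
            (1 - a) * b * gz[k01] + a * b * gz[k11];
  }
};

// [[Rcpp::export(name = ".metad_run_cpp")]]
Rcpp::List metad_run_cpp(Rcpp::List spec, Rcpp::NumericMatrix x0,
                         Rcpp::NumericVector masses, double temperature,
                         double friction, double timestep, double seed,
                         Rcpp::List fs, double hill_height, int hill_stride,
                         double sigma_s, double sigma_z, double grid_s_min,
                         double grid_s_max, double grid_z_min, double grid_z_max,
                         int max_steps, int record_stride, int traj_stride,
                         bool stop_on_recross, double start_lo, double start_hi,
                         double end_lo, double end_hi) {
  Integrator sim(spec, x0, masses, temperature, friction, timestep,
                 (std::uint64_t)seed);
  sim.draw_velocities();

  PathCV cv;
  cv.init(fs["frames_flat"], Rcpp::as<int>(fs["n_atoms"]), Rcpp::as<int>(fs["P"]),
          fs["align"], fs["displace"], Rcpp::as<double>(fs["lambda"]));
  if (cv.n_atoms != sim.n) Rcpp::stop("frameset topology does not match system");
  int nd = (int)cv.disp.size();
  std::vector<double> dsdx(3 * nd), dzdx(3 * nd);

  BiasGrid grid;
  bool biased = hill_height > 0.0;
  if (biased)
    grid.init(grid_s_min, grid_s_max, grid_z_min, grid_z_max, sigma_s / 10.0,
              sigma_z / 10.0);

  double cur_s = 0.0, cur_z = 0.0;
  auto biasf = [&](double, const double* x, double* f) {
    if (!biased) return;
    cv.eval(x, &cur_s, &cur_z, dsdx.data(), dzdx.data());
    double gS, gZ;
    grid.gradient(cur_s, cur_z, &gS, &gZ);
    for (int a = 0; a < nd; ++a) {
      int at = cv.disp[a];
      for (int d = 0; d < 3; ++d)
        f[3 * at + d] -= gS * dsdx[3 * a + d] + gZ * dzdx[3 * a + d];
    }
  };

  std::vector<double> hill_t, hill_s, hill_z;
  std::vector<double> t_rec, s_rec, z_rec, coords, t_traj;
  int phase = 0; // 0: in/awaiting start region, 1: reached end region
  double recross_time = -1.0;

  sim.compute_forces(0.0, biasf);
  auto eval_cv_now = [&]() {
    if (!biased) cv.eval(sim.x.data(), &cur_s, &cur_z, nullptr, nullptr);
  };
  eval_cv_now();
  t_rec.push_back(0.0); s_rec.push_back(cur_s); z_rec.push_back(cur_z);
  if (traj_stride > 0) {
    for (int i = 0; i < 3 * sim.n; ++i) coords.push_back(sim.x[i]);
    t_traj.push_back(0.0);
  }

  int steps_done = 0;
  for (int s = 1; s <= max_steps; ++s) {
    double t = s * timestep;
    sim.step(t, biasf);
    steps_done = s;
    bool at_record = (s % record_stride == 0);
    bool at_hill = (s % hill_stride == 0);
    if (at_record || at_hill) eval_cv_now();
    if (at_hill && biased) {
      hill_t.push_back(t);
      hill_s.push_back(cur_s);
      hill_z.push_back(cur_z);
      grid.add_hill(cur_s, cur_z, hill_height, sigma_s, sigma_z);
    }
    if (at_record) {
      t_rec.push_back(t); s_rec.push_back(cur_s); z_rec.push_back(cur_z);
      if (traj_stride > 0 && s % traj_stride == 0) {
        for (int i = 0; i < 3 * sim.n; ++i) coords.push_back(sim.x[i]);
        t_traj.push_back(t);
      }
    }
    if (stop_on_recross && (at_hill || at_record)) {
      if (phase == 0 && cur_s >= end_lo && cur_s <= end_hi) phase = 1;
      else if (phase == 1 && cur_s >= start_lo && cur_s <= start_hi) {
        recross_time = t;
        break;
      }
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("hill_time") = hill_t, Rcpp::Named("hill_s") = hill_s,
      Rcpp::Named("hill_z") = hill_z, Rcpp::Named("times") = t_rec,
      Rcpp::Named("s") = s_rec, Rcpp::Named("z") = z_rec,
      Rcpp::Named("coords") = coords, Rcpp::Named("t_traj") = t_traj,
      Rcpp::Named("n_atoms") = sim.n, Rcpp::Named("steps_done") = steps_done,
      Rcpp::Named("recross_time") = recross_time);
}

// Grid-interpolated bias gradient exactly as the metadynamics engine
// computes it (hills splatted on a sigma/10 grid, bilinear lookup) — used
// to bound the engine approximation against the analytic hill sum.
// [[Rcpp::export(name = ".bias_grid_gradient_cpp")]]
Rcpp::NumericMatrix bias_grid_gradient_cpp(Rcpp::NumericVector hs,
                                           Rcpp::NumericVector hz,
                                           Rcpp::NumericVector hh,
                                           double sigma_s, double sigma_z,
                                           double s_min, double s_max,
                                           double z_min, double z_max,
                                           Rcpp::NumericMatrix pts) {
  BiasGrid grid;
  grid.init(s_min, s_max, z_min, z_max, sigma_s / 10.0, sigma_z / 10.0);
  for (int k = 0; k < hs.size(); ++k)
    grid.add_hill(hs[k], hz[k], hh[k], sigma_s, sigma_z);
  Rcpp::NumericMatrix out(pts.nrow(), 2);
  for (int i = 0; i < pts.nrow(); ++i) {
    double gs, gz;
    grid.gradient(pts(i, 0), pts(i, 1), &gs, &gz);
    out(i, 0) = gs;
    out(i, 1) = gz;
  }
  return out;
}

// Smooth coordination count of `waters` around each of `points`:
// sum_i (1 - (r_i/r0)^n) / (1 - (r_i/r0)^m), with the r = r0 singularity
// evaluated as its limit n/m.
// [[Rcpp::export(name = ".coordination_cpp")]]
Rcpp::NumericVector coordination_cpp(Rcpp::NumericMatrix points,
                                     Rcpp::NumericMatrix waters, double r0,
                                     int n_exp, int m_exp) {
  int np = points.nrow(), nw = waters.nrow();
  Rcpp::NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double acc = 0.0;
    for (int w = 0; w < nw; ++w) {
      double dx = points(p, 0) - waters(w, 0);
      double dy = points(p, 1) - waters(w, 1);
      double dz = points(p, 2) - waters(w, 2);
      double u = std::sqrt(dx * dx + dy * dy + dz * dz) / r0;
      if (std::fabs(u - 1.0) < 1e-7) {
        double eps = u - 1.0;
        acc += ((double)n_exp / m_exp) * (1.0 + 0.5 * (n_exp - m_exp) * eps);
      } else {
        acc += (1.0 - std::pow(u, n_exp)) / (1.0 - std::pow(u, m_exp));
      }
    }
    out[p] = acc;
  }
  return out;
}
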
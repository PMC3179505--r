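#include "potentials.h"

using Rcpp::as;

Pot parse_pot(Rcpp::List spec) {
  Pot p;
  std::string ty = as<std::string>(spec["type"]);
  p.n_atoms = as<int>(spec["n_atoms"]);
  if (ty == "double_well_1d") {
    p.type = Pot::DOUBLE_WELL_1D;
    p.barrier = as<double>(spec["barrier"]);
    p.separation = as<double>(spec["separation"]);
    p.atom = as<int>(spec["atom"]) - 1;
    p.k_perp = spec.containsElementNamed("k_perp") ? as<double>(spec["k_perp"]) : 0.0;
  } else if (ty == "harmonic") {
    p.type = Pot::HARMONIC;
    p.k_harm = as<double>(spec["k"]);
    p.x0 = as<std::vector<double> >(spec["x0"]);
    if (spec.containsElementNamed("atoms")) {
      p.atoms = as<std::vector<int> >(spec["atoms"]);
      for (size_t i = 0; i < p.atoms.size(); ++i) p.atoms[i]--;
    }
  } else if (ty == "linear_1d") {
    p.type = Pot::LINEAR_1D;
    p.slope = as<double>(spec["slope"]);
    p.atom = as<int>(spec["atom"]) - 1;
    p.k_perp = spec.containsElementNamed("k_perp") ? as<double>(spec["k_perp"]) : 0.0;
  } else if (ty == "composite") {
    p.type = Pot::COMPOSITE;
    Rcpp::List comps = spec["components"];
    for (int i = 0; i < comps.size(); ++i)
      p.components.push_back(parse_pot(comps[i]));
  } else if (ty == "toy_pocket") {
    p.type = Pot::TOY_POCKET;
    p.depth = as<double>(spec["depth"]);
    p.z_half = as<double>(spec["z_half"]);
    p.delta = as<double>(spec["delta"]);
    p.lig = as<std::vector<int> >(spec["ligand"]);
    p.solv = as<std::vector<int> >(spec["solvent"]);
    p.refa = as<std::vector<int> >(spec["ref"]);
    for (size_t i = 0; i < p.lig.size(); ++i) p.lig[i]--;
    for (size_t i = 0; i < p.solv.size(); ++i) p.solv[i]--;
    for (size_t i = 0; i < p.refa.size(); ++i) p.refa[i]--;
    p.bond_i = as<std::vector<int> >(spec["bond_i"]);
    p.bond_j = as<std::vector<int> >(spec["bond_j"]);
    for (size_t i = 0; i < p.bond_i.size(); ++i) { p.bond_i[i]--; p.bond_j[i]--; }
    p.bond_r0 = as<std::vector<double> >(spec["bond_r0"]);
    p.k_int = as<double>(spec["k_int"]);
    p.ref_sites = as<std::vector<double> >(spec["ref_sites"]);
    p.k_ref = as<double>(spec["k_ref"]);
    p.sigma_wca = as<double>(spec["sigma_wca"]);
    p.eps_wca = as<double>(spec["eps_wca"]);
    p.rho_lig = as<double>(spec["rho_lig"]);
    p.z_lo_lig = as<double>(spec["z_lo_lig"]);
    p.z_hi_lig = as<double>(spec["z_hi_lig"]);
    p.rho_solv = as<double>(spec["rho_solv"]);
    p.rho_pocket = as<double>(spec["rho_pocket"]);
    p.z_lo_solv = as<double>(spec["z_lo_solv"]);
    p.z_hi_solv = as<double>(spec["z_hi_solv"]);
    p.k_wall = as<double>(spec["k_wall"]);
    p.gate_height = as<double>(spec["gate_height"]);
    p.gate_z = as<double>(spec["gate_z"]);
    p.gate_w = as<double>(spec["gate_w"]);
    p.eps_solv_pocket = as<double>(spec["eps_solv_pocket"]);
  } else {
    Rcpp::stop("unknown potential type '%s'", ty);
  }
  return p;
}

static inline double wca_pair(const double* x, int i, int j, double sigma,
                              double eps, double* f) {
  static const double CBRT2 = 1.2599210498948732;
  const double rc2 = CBRT2 * sigma * sigma; // (2^(1/6) sigma)^2
  double dx = x[3 * i] - x[3 * j];
  double dy = x[3 * i + 1] - x[3 * j + 1];
  double dz = x[3 * i + 2] - x[3 * j + 2];
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= rc2 || r2 <= 0.0) return 0.0;
  double s2 = sigma * sigma / r2;
  double s6 = s2 * s2 * s2;
  double e = 4.0 * eps * (s6 * s6 - s6) + eps;
  if (f) {
    // dV/dr2 = 4 eps (-12 s12 + 6 s6)/(2 r2); force = -dV/dr * rhat
    double fac = 24.0 * eps * (2.0 * s6 * s6 - s6) / r2; // = -2 dV/dr2
    f[3 * i] += fac * dx; f[3 * i + 1] += fac * dy; f[3 * i + 2] += fac * dz;
    f[3 * j] -= fac * dx; f[3 * j + 1] -= fac * dy; f[3 * j + 2] -= fac * dz;
  }
  return e;
}

// half-harmonic wall: V = k (q - q0)^2 beyond the wall (side = +1 above, -1 below)
static inline double wall1(double q, double q0, double k, int side, double* dVdq) {
  double ex = side > 0 ? q - q0 : q0 - q;
  if (ex <= 0.0) { if (dVdq) *dVdq = 0.0; return 0.0; }
  if (dVdq) *dVdq = 2.0 * k * ex * (side > 0 ? 1.0 : -1.0);
  return k * ex * ex;
}

double pot_eval(const Pot& p, const double* x, double* f) {
  switch (p.type) {
  case Pot::DOUBLE_WELL_1D: {
    double a = p.separation, b = p.barrier;
    double u = 2.0 * x[3 * p.atom] / a;
    double w = u * u - 1.0;
    double e = b * w * w;
    if (f) f[3 * p.atom] -= b * 2.0 * w * 2.0 * u * (2.0 / a);
    for (int d = 1; d < 3 && p.k_perp > 0.0; ++d) {
      double q = x[3 * p.atom + d];
      e += 0.5 * p.k_perp * q * q;
      if (f) f[3 * p.atom + d] -= p.k_perp * q;
    }
    return e;
  }
  case Pot::HARMONIC: {
    double e = 0.0;
    if (p.atoms.empty()) {
      for (int i = 0; i < 3 * p.n_atoms; ++i) {
        double d = x[i] - p.x0[i];
        e += 0.5 * p.k_harm * d * d;
        if (f) f[i] -= p.k_harm * d;
      }
    } else {
      for (size_t a = 0; a < p.atoms.size(); ++a) {
        int i = p.atoms[a];
        for (int d = 0; d < 3; ++d) {
          double dd = x[3 * i + d] - p.x0[3 * a + d];
          e += 0.5 * p.k_harm * dd * dd;
          if (f) f[3 * i + d] -= p.k_harm * dd;
        }
      }
    }
    return e;
  }
  case Pot::LINEAR_1D: {
    double e = p.slope * x[3 * p.atom];
    if (f) f[3 * p.atom] -= p.slope;
    for (int d = 1; d < 3 && p.k_perp > 0.0; ++d) {
      double q = x[3 * p.atom + d];
      e += 0.5 * p.k_perp * q * q;
      if (f) f[3 * p.atom + d] -= p.k_perp * q;
    }
    return e;
  }
  case Pot::COMPOSITE: {
    double e = 0.0;
    for (size_t c = 0; c < p.components.size(); ++c)
      e += pot_eval(p.components[c], x, f);
    return e;
  }
  case Pot::TOY_POCKET: {
    double e = 0.0;
    int nl = (int)p.lig.size();

    // ligand COM
    double cx = 0, cy = 0, cz = 0;
    for (int a = 0; a < nl; ++a) {
      cx += x[3 * p.lig[a]]; cy += x[3 * p.lig[a] + 1]; cz += x[3 * p.lig[a] + 2];
    }
    cx /= nl; cy /= nl; cz /= nl;

    // binding well along COM z: V = -depth * 0.5 * (1 - tanh((z - z_half)/delta))
    {
      double th = std::tanh((cz - p.z_half) / p.delta);
      e += -p.depth * 0.5 * (1.0 - th);
      double dVdz = p.depth * 0.5 * (1.0 - th * th) / p.delta;
      if (f)
        for (int a = 0; a < nl; ++a) f[3 * p.lig[a] + 2] -= dVdz / nl;
    }
    // COM tube (radial) + axial caps
    {
      double rho = std::sqrt(cx * cx + cy * cy);
      double dV;
      e += wall1(rho, p.rho_lig, p.k_wall, +1, &dV);
      if (f && dV != 0.0 && rho > 1e-12) {
        double fx = -dV * cx / rho / nl, fy = -dV * cy / rho / nl;
        for (int a = 0; a < nl; ++a) { f[3 * p.lig[a]] += fx; f[3 * p.lig[a] + 1] += fy; }
      }
      e += wall1(cz, p.z_hi_lig, p.k_wall, +1, &dV);
      if (f && dV != 0.0)
        for (int a = 0; a < nl; ++a) f[3 * p.lig[a] + 2] -= dV / nl;
      e += wall1(cz, p.z_lo_lig, p.k_wall, -1, &dV);
      if (f && dV != 0.0)
        for (int a = 0; a < nl; ++a) f[3 * p.lig[a] + 2] -= dV / nl;
    }
    // ligand internal bonds (stiff harmonic -> quasi-rigid body)
    for (size_t b = 0; b < p.bond_i.size(); ++b) {
      int i = p.bond_i[b], j = p.bond_j[b];
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - p.bond_r0[b];
      e += 0.5 * p.k_int * dr * dr;
      if (f && r > 1e-12) {
        double fac = -p.k_int * dr / r;
        f[3 * i] += fac * dx; f[3 * i + 1] += fac * dy; f[3 * i + 2] += fac * dz;
        f[3 * j] -= fac * dx; f[3 * j + 1] -= fac * dy; f[3 * j + 2] -= fac * dz;
      }
    }
    // reference cage beads: stiff site restraints
    for (size_t a = 0; a < p.refa.size(); ++a) {
      int i = p.refa[a];
      for (int d = 0; d < 3; ++d) {
        double dd = x[3 * i + d] - p.ref_sites[3 * a + d];
        e += 0.5 * p.k_ref * dd * dd;
        if (f) f[3 * i + d] -= p.k_ref * dd;
      }
    }
    // solvent: WCA with ligand and with each other; confinement; gate bump
    int ns = (int)p.solv.size();
    for (int a = 0; a < ns; ++a) {
      int i = p.solv[a];
      for (int b = a + 1; b < ns; ++b)
        e += wca_pair(x, i, p.solv[b], p.sigma_wca, p.eps_wca, f);
      for (int b = 0; b < nl; ++b)
        e += wca_pair(x, i, p.lig[b], p.sigma_wca, p.eps_wca, f);
      double sx = x[3 * i], sy = x[3 * i + 1], sz = x[3 * i + 2];
      double rho = std::sqrt(sx * sx + sy * sy);
      double dV;
      // funnel: the radial wall narrows below the gate so the pocket
      // interior is only as wide as the ligand channel
      double th = std::tanh((sz - p.gate_z) / 0.8);
      double rho_eff = p.rho_pocket + (p.rho_solv - p.rho_pocket) * 0.5 * (1.0 + th);
      e += wall1(rho, rho_eff, p.k_wall, +1, &dV);
      if (f && dV != 0.0) {
        if (rho > 1e-12) {
          f[3 * i] -= dV * sx / rho; f[3 * i + 1] -= dV * sy / rho;
        }
        double drho_dz = (p.rho_solv - p.rho_pocket) * 0.5 * (1.0 - th * th) / 0.8;
        f[3 * i + 2] += dV * drho_dz; // wall recedes with z: -dV/dz = +dV*drho_eff/dz
      }
      e += wall1(sz, p.z_hi_solv, p.k_wall, +1, &dV);
      if (f) f[3 * i + 2] -= dV;
      e += wall1(sz, p.z_lo_solv, p.k_wall, -1, &dV);
      if (f) f[3 * i + 2] -= dV;
      if (p.gate_height > 0.0) {
        double u = (sz - p.gate_z) / p.gate_w;
        double g = p.gate_height * std::exp(-0.5 * u * u);
        e += g;
        if (f) f[3 * i + 2] += g * u / p.gate_w;
      }
      if (p.eps_solv_pocket > 0.0) {
        // shallow polar-cavity attraction inside the pocket
        double tp = std::tanh((sz - p.gate_z) / 0.8);
        e += -p.eps_solv_pocket * 0.5 * (1.0 - tp);
        if (f)
          f[3 * i + 2] -= p.eps_solv_pocket * 0.5 * (1.0 - tp * tp) / 0.8;
      }
    }
    return e;
  }
  }
  Rcpp::stop("unreachable potential type");
}

// [[Rcpp::export(name = ".pot_energy_cpp")]]
double pot_energy_cpp(Rcpp::List spec, Rcpp::NumericMatrix coords) {
  Pot p = parse_pot(spec);
  if (coords.nrow() != p.n_atoms) Rcpp::stop("coordinate/atom count mismatch");
  std::vector<double> x(3 * p.n_atoms);
  for (int i = 0; i < p.n_atoms; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  return pot_eval(p, x.data(), nullptr);
}

// [[Rcpp::export(name = ".pot_gradient_cpp")]]
Rcpp::NumericMatrix pot_gradient_cpp(Rcpp::List spec, Rcpp::NumericMatrix coords) {
  Pot p = parse_pot(spec);
  if (coords.nrow() != p.n_atoms) Rcpp::stop("coordinate/atom count mismatch");
  std::vector<double> x(3 * p.n_atoms), f(3 * p.n_atoms, 0.0);
  for (int i = 0; i < p.n_atoms; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  pot_eval(p, x.data(), f.data());
  Rcpp::NumericMatrix g(p.n_atoms, 3);
  for (int i = 0; i < p.n_atoms; ++i)
    for (int d = 0; d < 3; ++d) g(i, d) = -f[3 * i + d]; // gradient = -force
  return g;
}
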
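#ifndef PATHMETA_POTENTIALS_H
#define PATHMETA_POTENTIALS_H

#include "pathmeta.h"

// Built-in analytic potentials. Coordinates are flat arrays of length 3n
// (atom-major: x1 y1 z1 x2 ...), energies kcal/mol, forces kcal/mol/A.
struct Pot {
  enum Type { DOUBLE_WELL_1D = 1, HARMONIC = 2, LINEAR_1D = 3, TOY_POCKET = 4,
              COMPOSITE = 5 };
  int type;
  int n_atoms;

  // double_well_1d / linear_1d: act on the x coordinate of one atom;
  // k_perp harmonically confines that atom's y and z (1D model embedded in 3D)
  double barrier, separation; // double well
  double slope;               // linear
  int atom;                   // 0-based internally
  double k_perp;

  // harmonic: V = 0.5 * k * sum over `atoms` (default all) of |x - x0|^2
  double k_harm;
  std::vector<double> x0;
  std::vector<int> atoms; // 0-based; empty = all

  // composite: sum of components
  std::vector<Pot> components;

  // toy pocket
  double depth, z_half, delta;       // binding well along ligand COM z
  std::vector<int> lig, solv, refa;  // 0-based atom indices
  std::vector<int> bond_i, bond_j;
  std::vector<double> bond_r0;
  double k_int;
  std::vector<double> ref_sites;     // 3 * n_ref
  double k_ref;
  double sigma_wca, eps_wca;
  double rho_lig, z_lo_lig, z_hi_lig; // ligand COM tube + caps
  double rho_solv, rho_pocket, z_lo_solv, z_hi_solv;
  double k_wall;
  double gate_height, gate_z, gate_w; // solvent gate bump at pocket mouth
  double eps_solv_pocket;             // solvent attraction inside the pocket
};

Pot parse_pot(Rcpp::List spec);

// returns energy; if f != nullptr accumulates forces (f must be zeroed or
// hold other contributions; forces are ADDED)
double pot_eval(const Pot& p, const double* x, double* f);

#endif
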
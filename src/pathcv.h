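#ifndef PATHMETA_PATHCV_H
#define PATHMETA_PATHCV_H

#include "pathmeta.h"

// Path collective variables over a frameset:
//   S = sum_j j exp(-lambda D_j) / sum_j exp(-lambda D_j),  j = 1..P
//   Z = -(1/lambda) log sum_j exp(-lambda D_j)
// with D_j the MSD (A^2) between the instantaneous configuration and frame j
// after least-squares superposition over the align selection, measured over
// the displace selection. Evaluated via log-sum-exp.
struct PathCV {
  int n_atoms, P;
  double lambda;
  std::vector<double> frames;      // P * 3n
  std::vector<int> align, disp;    // 0-based
  // scratch
  std::vector<double> wbuf, dbuf, diff, rots;

  void init(const Rcpp::NumericVector& frames_flat, int n_atoms_, int P_,
            const Rcpp::IntegerVector& align1, const Rcpp::IntegerVector& disp1,
            double lambda_);
  void eval(const double* x, double* s_out, double* z_out, double* ds_dx,
            double* dz_dx);
};

#endif
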
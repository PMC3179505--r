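#include "pathmeta.h"
#include "pathcv.h"

// Frames stored flat: frame j occupies coords[j * 3n .. ). Selections 0-based.

void PathCV::init(const Rcpp::NumericVector& frames_flat, int n_atoms_, int P_,
                  const Rcpp::IntegerVector& align1, const Rcpp::IntegerVector& disp1,
                  double lambda_) {
  n_atoms = n_atoms_;
  P = P_;
  lambda = lambda_;
  frames.assign(frames_flat.begin(), frames_flat.end());
  align.clear(); disp.clear();
  for (int i = 0; i < align1.size(); ++i) align.push_back(align1[i] - 1);
  for (int i = 0; i < disp1.size(); ++i) disp.push_back(disp1[i] - 1);
  wbuf.resize(P);
  dbuf.resize(P);
  diff.resize((size_t)P * disp.size() * 3);
  rots.resize((size_t)P * 9);
}

// Evaluate S, Z and (optionally) gradients w.r.t. the displace atoms of x.
// Alignment (rotation+translation from the align set) is held fixed for the
// gradient, which is exact when align and displace sets are disjoint.
void PathCV::eval(const double* x, double* s_out, double* z_out, double* ds_dx,
                  double* dz_dx) {
  int na = (int)align.size(), nd = (int)disp.size();
  std::vector<double> mob(3 * na), ref(3 * na);

  for (int j = 0; j < P; ++j) {
    const double* fj = &frames[(size_t)j * 3 * n_atoms];
    double rot[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
    double cm[3] = {0, 0, 0}, cr[3] = {0, 0, 0};
    if (na >= 3) {
      for (int a = 0; a < na; ++a)
        for (int d = 0; d < 3; ++d) {
          mob[3 * a + d] = x[3 * align[a] + d];
          ref[3 * a + d] = fj[3 * align[a] + d];
        }
      kearsley_fit(mob.data(), ref.data(), na, rot, cm, cr);
    }
    for (int k = 0; k < 9; ++k) rots[(size_t)j * 9 + k] = rot[k];
    double D = 0.0;
    for (int a = 0; a < nd; ++a) {
      int at = disp[a];
      double v[3], vp[3];
      for (int d = 0; d < 3; ++d) v[d] = x[3 * at + d] - cm[d];
      for (int d = 0; d < 3; ++d)
        vp[d] = rot[3 * d] * v[0] + rot[3 * d + 1] * v[1] + rot[3 * d + 2] * v[2] + cr[d];
      for (int d = 0; d < 3; ++d) {
        double dd = vp[d] - fj[3 * at + d];
        diff[((size_t)j * nd + a) * 3 + d] = dd;
        D += dd * dd;
      }
    }
    dbuf[j] = D / nd;
  }

  // log-sum-exp weights
  double m = -lambda * dbuf[0];
  for (int j = 1; j < P; ++j) m = std::max(m, -lambda * dbuf[j]);
  double sw = 0.0, sjw = 0.0;
  for (int j = 0; j < P; ++j) {
    wbuf[j] = std::exp(-lambda * dbuf[j] - m);
    sw += wbuf[j];
    sjw += (j + 1) * wbuf[j];
  }
  double S = sjw / sw;
  double Z = -(m + std::log(sw)) / lambda;
  *s_out = S;
  *z_out = Z;

  if (ds_dx && dz_dx) {
    int nd2 = nd;
    for (int a = 0; a < 3 * nd2; ++a) { ds_dx[a] = 0.0; dz_dx[a] = 0.0; }
    for (int j = 0; j < P; ++j) {
      double dS_dD = lambda * wbuf[j] * (S - (j + 1)) / sw;
      double dZ_dD = wbuf[j] / sw;
      const double* rot = &rots[(size_t)j * 9];
      for (int a = 0; a < nd2; ++a) {
        const double* dd = &diff[((size_t)j * nd2 + a) * 3];
        // dD/dx_k = (2/nd) * R^T * (x'_k - f_k)
        for (int d = 0; d < 3; ++d) {
          double g = (2.0 / nd2) *
                     (rot[d] * dd[0] + rot[3 + d] * dd[1] + rot[6 + d] * dd[2]);
          ds_dx[3 * a + d] += dS_dD * g;
          dz_dx[3 * a + d] += dZ_dD * g;
        }
      }
    }
  }
}

static PathCV make_pcv(Rcpp::List fs) {
  PathCV cv;
  cv.init(fs["frames_flat"], Rcpp::as<int>(fs["n_atoms"]), Rcpp::as<int>(fs["P"]),
          fs["align"], fs["displace"], Rcpp::as<double>(fs["lambda"]));
  return cv;
}

// [[Rcpp::export(name = ".pathcv_eval_cpp")]]
Rcpp::List pathcv_eval_cpp(Rcpp::List fs, Rcpp::NumericMatrix coords,
                           bool gradients) {
  PathCV cv = make_pcv(fs);
  if (coords.nrow() != cv.n_atoms) Rcpp::stop("coordinate/atom count mismatch");
  std::vector<double> x(3 * cv.n_atoms);
  for (int i = 0; i < cv.n_atoms; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  double s, z;
  int nd = (int)cv.disp.size();
  std::vector<double> ds(3 * nd), dz(3 * nd);
  cv.eval(x.data(), &s, &z, gradients ? ds.data() : nullptr,
          gradients ? dz.data() : nullptr);
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("s") = s, Rcpp::Named("z") = z);
  if (gradients) {
    Rcpp::NumericMatrix dsm(nd, 3), dzm(nd, 3);
    for (int a = 0; a < nd; ++a)
      for (int d = 0; d < 3; ++d) {
        dsm(a, d) = ds[3 * a + d];
        dzm(a, d) = dz[3 * a + d];
      }
    out["ds_dx"] = dsm;
    out["dz_dx"] = dzm;
  }
  return out;
}

// S, Z for every frame of a trajectory (flat coords, frame-major).
// [[Rcpp::export(name = ".pathcv_series_cpp")]]
Rcpp::List pathcv_series_cpp(Rcpp::List fs, Rcpp::NumericVector traj_flat,
                             int n_frames) {
  PathCV cv = make_pcv(fs);
  size_t stride = (size_t)3 * cv.n_atoms;
  if ((size_t)traj_flat.size() != stride * n_frames)
    Rcpp::stop("trajectory size mismatch");
  Rcpp::NumericVector s(n_frames), z(n_frames);
  for (int t = 0; t < n_frames; ++t) {
    double sv, zv;
    cv.eval(&traj_flat[stride * t], &sv, &zv, nullptr, nullptr);
    s[t] = sv;
    z[t] = zv;
  }
  return Rcpp::List::create(Rcpp::Named("s") = s, Rcpp::Named("z") = z);
}

// MSD (after optimal superposition over `align`, measured over `disp`)
// between two configurations.
// [[Rcpp::export(name = ".msd_cpp")]]
double msd_cpp(Rcpp::NumericMatrix a, Rcpp::NumericMatrix b,
               Rcpp::IntegerVector align1, Rcpp::IntegerVector disp1) {
  int n = a.nrow();
  if (b.nrow() != n) Rcpp::stop("configurations differ in atom count");
  int na = align1.size(), nd = disp1.size();
  double rot[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
  double cm[3] = {0, 0, 0}, cr[3] = {0, 0, 0};
  if (na >= 3) {
    std::vector<double> mob(3 * na), ref(3 * na);
    for (int i = 0; i < na; ++i)
      for (int d = 0; d < 3; ++d) {
        mob[3 * i + d] = a(align1[i] - 1, d);
        ref[3 * i + d] = b(align1[i] - 1, d);
      }
    kearsley_fit(mob.data(), ref.data(), na, rot, cm, cr);
  }
  double D = 0.0;
  for (int i = 0; i < nd; ++i) {
    int at = disp1[i] - 1;
    double v[3], vp[3];
    for (int d = 0; d < 3; ++d) v[d] = a(at, d) - cm[d];
    for (int d = 0; d < 3; ++d)
      vp[d] = rot[3 * d] * v[0] + rot[3 * d + 1] * v[1] + rot[3 * d + 2] * v[2] + cr[d];
    for (int d = 0; d < 3; ++d) {
      double dd = vp[d] - b(at, d);
      D += dd * dd;
    }
  }
  return D / nd;
}

// Pairwise MSD matrix over a candidate subset of trajectory frames.
// [[Rcpp::export(name = ".msd_matrix_cpp")]]
Rcpp::NumericMatrix msd_matrix_cpp(Rcpp::NumericVector traj_flat, int n_atoms,
                                   Rcpp::IntegerVector cand1,
                                   Rcpp::IntegerVector align1,
                                   Rcpp::IntegerVector disp1) {
  int C = cand1.size();
  size_t stride = (size_t)3 * n_atoms;
  int na = align1.size(), nd = disp1.size();
  Rcpp::NumericMatrix D(C, C);
  std::vector<double> mob(3 * std::max(na, 1)), ref(3 * std::max(na, 1));
  for (int ci = 0; ci < C; ++ci) {
    const double* xa = &traj_flat[stride * (cand1[ci] - 1)];
    for (int cj = ci + 1; cj < C; ++cj) {
      const double* xb = &traj_flat[stride * (cand1[cj] - 1)];
      double rot[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
      double cm[3] = {0, 0, 0}, cr[3] = {0, 0, 0};
      if (na >= 3) {
        for (int i = 0; i < na; ++i)
          for (int d = 0; d < 3; ++d) {
            mob[3 * i + d] = xa[3 * (align1[i] - 1) + d];
            ref[3 * i + d] = xb[3 * (align1[i] - 1) + d];
          }
        kearsley_fit(mob.data(), ref.data(), na, rot, cm, cr);
      }
      double dd = 0.0;
      for (int i = 0; i < nd; ++i) {
        int at = disp1[i] - 1;
        double v[3], vp[3];
        for (int d = 0; d < 3; ++d) v[d] = xa[3 * at + d] - cm[d];
        for (int d = 0; d < 3; ++d)
          vp[d] = rot[3 * d] * v[0] + rot[3 * d + 1] * v[1] + rot[3 * d + 2] * v[2] + cr[d];
        for (int d = 0; d < 3; ++d) {
          double e = vp[d] - xb[3 * at + d];
          dd += e * e;
        }
      }
      D(ci, cj) = dd / nd;
      D(cj, ci) = D(ci, cj);
    }
  }
  return D;
}

// Dynamic programme: pick P indices (first and last fixed) from C candidates
// minimizing sum over adjacent pairs of (msd - target)^2.
// [[Rcpp::export(name = ".frameset_dp_cpp")]]
Rcpp::IntegerVector frameset_dp_cpp(Rcpp::NumericMatrix D, int P, double target) {
  int C = D.nrow();
  if (P < 2 || P > C) Rcpp::stop("P out of range");
  const double INF = 1e300;
  std::vector<double> prev(C, INF), cur(C, INF);
  std::vector<std::vector<int> > back(P, std::vector<int>(C, -1));
  prev[0] = 0.0; // segment 0 ends at candidate 0 (first frame)
  for (int seg = 1; seg < P; ++seg) {
    std::fill(cur.begin(), cur.end(), INF);
    for (int j = seg; j < C; ++j) {
      double best = INF;
      int arg = -1;
      for (int i = seg - 1; i < j; ++i) {
        if (prev[i] >= INF) continue;
        double c = D(i, j) - target;
        double v = prev[i] + c * c;
        if (v < best) { best = v; arg = i; }
      }
      cur[j] = best;
      back[seg][j] = arg;
    }
    std::swap(prev, cur);
  }
  Rcpp::IntegerVector sel(P);
  int j = C - 1;
  for (int seg = P - 1; seg >= 0; --seg) {
    sel[seg] = j + 1; // 1-based candidate index
    j = (seg > 0) ? back[seg][j] : 0;
  }
  return sel;
}
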
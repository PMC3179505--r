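#include "pathmeta.h"

// Cyclic Jacobi rotations; plenty for a 4x4 symmetric matrix.
void jacobi_eigen4(double a[4][4], double eval[4], double evec[4][4]) {
  const int n = 4;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) evec[i][j] = (i == j) ? 1.0 : 0.0;

  double scale = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) scale += a[i][j] * a[i][j];
  double tol = 1e-24 * (scale + 1e-300);

  for (int sweep = 0; sweep < 100; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < n - 1; ++p)
      for (int q = p + 1; q < n; ++q) off += a[p][q] * a[p][q];
    if (off < tol) break;
    for (int p = 0; p < n - 1; ++p) {
      for (int q = p + 1; q < n; ++q) {
        if (std::fabs(a[p][q]) < 1e-300) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0);
        double s = t * c;
        for (int k = 0; k < n; ++k) {
          double akp = a[k][p], akq = a[k][q];
          a[k][p] = c * akp - s * akq;
          a[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < n; ++k) {
          double apk = a[p][k], aqk = a[q][k];
          a[p][k] = c * apk - s * aqk;
          a[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < n; ++k) {
          double vkp = evec[k][p], vkq = evec[k][q];
          evec[k][p] = c * vkp - s * vkq;
          evec[k][q] = s * vkp + c * vkq;
        }
      }
    }
  }
  for (int i = 0; i < n; ++i) eval[i] = a[i][i];
}

double kearsley_fit(const double* mob, const double* ref, int n,
                    double rot[9], double cm_mob[3], double cm_ref[3]) {
  for (int d = 0; d < 3; ++d) { cm_mob[d] = 0.0; cm_ref[d] = 0.0; }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      cm_mob[d] += mob[3 * i + d];
      cm_ref[d] += ref[3 * i + d];
    }
  for (int d = 0; d < 3; ++d) { cm_mob[d] /= n; cm_ref[d] /= n; }

  // Kearsley matrix from coordinate sums (xm, ym, zm) - (xr, yr, zr)
  double K[4][4] = {{0}};
  for (int i = 0; i < n; ++i) {
    double xm = mob[3 * i] - cm_mob[0], ym = mob[3 * i + 1] - cm_mob[1],
           zm = mob[3 * i + 2] - cm_mob[2];
    double xr = ref[3 * i] - cm_ref[0], yr = ref[3 * i + 1] - cm_ref[1],
           zr = ref[3 * i + 2] - cm_ref[2];
    double xp = xm + xr, yp = ym + yr, zp = zm + zr;
    double xd = xm - xr, yd = ym - yr, zd = zm - zr;
    K[0][0] += xd * xd + yd * yd + zd * zd;
    K[0][1] += yp * zd - yd * zp;
    K[0][2] += xd * zp - xp * zd;
    K[0][3] += xp * yd - xd * yp;
    K[1][1] += yp * yp + zp * zp + xd * xd;
    K[1][2] += xd * yd - xp * yp;
    K[1][3] += xd * zd - xp * zp;
    K[2][2] += xp * xp + zp * zp + yd * yd;
    K[2][3] += yd * zd - yp * zp;
    K[3][3] += xp * xp + yp * yp + zd * zd;
  }
  K[1][0] = K[0][1]; K[2][0] = K[0][2]; K[3][0] = K[0][3];
  K[2][1] = K[1][2]; K[3][1] = K[1][3]; K[3][2] = K[2][3];

  double eval[4], evec[4][4];
  jacobi_eigen4(K, eval, evec);
  int imin = 0;
  for (int i = 1; i < 4; ++i)
    if (eval[i] < eval[imin]) imin = i;
  double q0 = evec[0][imin], q1 = evec[1][imin], q2 = evec[2][imin],
         q3 = evec[3][imin];

  // rotation taking the centred mobile onto the centred reference,
  // row-major so that x'_d = sum_k rot[3d+k] x_k
  rot[0] = q0 * q0 + q1 * q1 - q2 * q2 - q3 * q3;
  rot[3] = 2.0 * (q1 * q2 + q0 * q3);
  rot[6] = 2.0 * (q1 * q3 - q0 * q2);
  rot[1] = 2.0 * (q1 * q2 - q0 * q3);
  rot[4] = q0 * q0 + q2 * q2 - q1 * q1 - q3 * q3;
  rot[7] = 2.0 * (q2 * q3 + q0 * q1);
  rot[2] = 2.0 * (q1 * q3 + q0 * q2);
  rot[5] = 2.0 * (q2 * q3 - q0 * q1);
  rot[8] = q0 * q0 + q3 * q3 - q1 * q1 - q2 * q2;

  double msd = eval[imin] / n;
  if (msd < 0.0) msd = 0.0;
  return std::sqrt(msd);
}

// [[Rcpp::export(name = ".kearsley_cpp")]]
Rcpp::List kearsley_cpp(Rcpp::NumericMatrix mobile, Rcpp::NumericMatrix ref) {
  int n = mobile.nrow();
  if (ref.nrow() != n) Rcpp::stop("point sets differ in size");
  std::vector<double> m(3 * n), r(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      m[3 * i + d] = mobile(i, d);
      r[3 * i + d] = ref(i, d);
    }
  double rot[9], cm[3], cr[3];
  double rmsd = kearsley_fit(m.data(), r.data(), n, rot, cm, cr);
  Rcpp::NumericMatrix R(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) R(i, j) = rot[3 * i + j];
  Rcpp::NumericVector cmv(3), crv(3);
  for (int d = 0; d < 3; ++d) { cmv[d] = cm[d]; crv[d] = cr[d]; }
  return Rcpp::List::create(Rcpp::Named("rotation") = R,
                            Rcpp::Named("cm_mobile") = cmv,
                            Rcpp::Named("cm_reference") = crv,
                            Rcpp::Named("rmsd") = rmsd);
}
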
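#ifndef PATHMETA_H
#define PATHMETA_H

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

// Units: kcal/mol, Angstrom, ps, K, amu.
// 1 kcal/mol = KCAL_TO_MECH amu A^2 ps^-2.
static const double KCAL_TO_MECH = 418.4;
static const double KB_KCAL = 1.9872041e-3; // kcal mol^-1 K^-1

// ---------------------------------------------------------------------------
// Deterministic RNG: xoshiro256++ uniforms + Marsaglia-Tsang ziggurat
// normals (self-contained so trajectories are bit-reproducible for a given
// integer seed on this toolchain).
// ---------------------------------------------------------------------------
struct ZigTables {
  std::uint32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (std::uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (std::uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};

struct Rng {
  std::uint64_t s[4]; // xoshiro256++ state

  explicit Rng(std::uint64_t seed) {
    // splitmix64 expansion of the seed
    std::uint64_t x = seed + 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      std::uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  std::uint64_t next_u64() {
    std::uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    std::uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1)
  double unif() {
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  static const ZigTables& zig() {
    static const ZigTables t;
    return t;
  }

  double gauss() {
    const ZigTables& t = zig();
    const double r = 3.442619855899;
    for (;;) {
      std::int32_t hz = (std::int32_t)(next_u64() >> 32);
      int iz = hz & 127;
      if ((std::uint32_t)((hz < 0) ? -(std::int64_t)hz : hz) < t.kn[iz])
        return hz * t.wn[iz];
      if (iz == 0) { // base-strip tail
        double x, y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      double x = hz * t.wn[iz];
      if (t.fn[iz] + unif() * (t.fn[iz - 1] - t.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// ---------------------------------------------------------------------------
// Small symmetric eigen solver (cyclic Jacobi) for the 4x4 Kearsley matrix.
// ---------------------------------------------------------------------------
void jacobi_eigen4(double a[4][4], double eval[4], double evec[4][4]);

// Optimal rigid superposition of mobile onto ref over n points (rows of
// nx3 arrays). Returns rmsd; fills rot (3x3 row-major) and centroids.
// The transform mapping mobile into the ref frame is
//   x' = rot * (x - cm_mob) + cm_ref.
double kearsley_fit(const double* mob, const double* ref, int n,
                    double rot[9], double cm_mob[3], double cm_ref[3]);

#endif
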
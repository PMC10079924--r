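#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimal deterministic xorshift32 PRNG so the relaxation sweep order is
// reproducible from a single integer drawn from R's RNG stream.
struct XorShift32 {
  uint32_t s;
  explicit XorShift32(uint32_t seed) : s(seed ? seed : 0x9E3779B9u) {}
  uint32_t next() {
    uint32_t x = s;
    x ^= x << 13; x ^= x >> 17; x ^= x << 5;
    return s = x;
  }
  double unif() { return (next() >> 8) * (1.0 / 16777216.0); }
  int below(int n) { return (int)(unif() * n) % n; }
};

static inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  return (x >= L) ? x - L : x;   // guard against floor rounding at the edge
}

// Shove relaxation: resolves overlaps of zones of influence
// (k_shov * radius) by symmetric pairwise displacement along the line of
// centres.  Periodic in x, reflecting substratum at z = 0 (cells end with
// z >= radius).  Sweeps visit cells in a randomised order (Gauss-Seidel)
// until the largest zone overlap at the start of a sweep is below tol or
// max_sweeps is reached.
// [[Rcpp::export]]
List shove_cpp(NumericVector x_, NumericVector z_, NumericVector r_,
               double k_shov, double L_y, double tol, int max_sweeps,
               int seed) {
  int n = x_.size();
  std::vector<double> x(x_.begin(), x_.end());
  std::vector<double> z(z_.begin(), z_.end());
  std::vector<double> r(r_.begin(), r_.end());
  XorShift32 rng((uint32_t)seed);

  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
  // bin size: largest interaction distance plus slack for intra-sweep motion
  double h = std::max(2.5 * k_shov * rmax, 1e-6);
  int nbx = std::max(1, (int)std::floor(L_y / h));
  double hx = L_y / nbx;

  double max_ov = 0.0;
  int sweep = 0;
  std::vector<int> order(n), head, nxt(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    // substratum reflection before pair resolution
    for (int i = 0; i < n; ++i) {
      x[i] = wrap(x[i], L_y);
      if (z[i] < r[i]) z[i] = 2.0 * r[i] - z[i];
    }
    double zmax = 0.0;
    for (int i = 0; i < n; ++i) zmax = std::max(zmax, z[i]);
    int nbz = std::max(1, (int)std::floor(zmax / h) + 1);
    head.assign((size_t)nbx * nbz, -1);
    for (int i = 0; i < n; ++i) {
      int bx = std::min(nbx - 1, (int)(x[i] / hx));
      int bz = std::min(nbz - 1, (int)(z[i] / h));
      int b = bz * nbx + bx;
      nxt[i] = head[b];
      head[b] = i;
    }
    // Fisher-Yates shuffle of visitation order
    for (int i = n - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(order[i], order[j]);
    }
    max_ov = 0.0;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      int bx = std::min(nbx - 1, (int)(wrap(x[i], L_y) / hx));
      int bz = std::min(nbz - 1, (int)(std::max(z[i], 0.0) / h));
      for (int dz = -1; dz <= 1; ++dz) {
        int cz = bz + dz;
        if (cz < 0 || cz >= nbz) continue;
        int cols[3]; int ncols = 0;
        for (int dxb = -1; dxb <= 1; ++dxb) {
          int cx = (bx + dxb + nbx) % nbx;
          bool seen = false;
          for (int q = 0; q < ncols; ++q) if (cols[q] == cx) seen = true;
          if (!seen) cols[ncols++] = cx;
        }
        for (int ci = 0; ci < ncols; ++ci) {
          int cx = cols[ci];
          for (int j = head[(size_t)cz * nbx + cx]; j != -1; j = nxt[j]) {
            if (j == i) continue;
            double dx = x[j] - x[i];
            if (dx > 0.5 * L_y) dx -= L_y;
            if (dx < -0.5 * L_y) dx += L_y;
            double dzz = z[j] - z[i];
            double d2 = dx * dx + dzz * dzz;
            double target = k_shov * (r[i] + r[j]);
            if (d2 >= target * target) continue;
            double d = std::sqrt(d2);
            double ov = target - d;
            if (ov > max_ov) max_ov = ov;
            double ux, uz;
            if (d < 1e-12) {
              double ang = rng.unif() * 2.0 * M_PI;
              ux = std::cos(ang); uz = std::sin(ang);
            } else {
              ux = dx / d; uz = dzz / d;
            }
            double push = 0.5 * ov;
            x[i] -= push * ux;  z[i] -= push * uz;
            x[j] += push * ux;  z[j] += push * uz;
            x[i] = wrap(x[i], L_y); x[j] = wrap(x[j], L_y);
            if (z[i] < r[i]) z[i] = 2.0 * r[i] - z[i];
            if (z[j] < r[j]) z[j] = 2.0 * r[j] - z[j];
          }
        }
      }
    }
    if (max_ov < tol) { ++sweep; break; }
  }
  for (int i = 0; i < n; ++i) {
    x[i] = wrap(x[i], L_y);
    if (z[i] < r[i]) z[i] = 2.0 * r[i] - z[i];
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["z"] = NumericVector(z.begin(), z.end()),
                      _["sweeps"] = sweep,
                      _["residual"] = max_ov);
}
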
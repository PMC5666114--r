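#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Weighted pair-distance histogram of one point set (pairs i<j, weight f_i*f_j).
// Bin b collects distances in [b*bin, (b+1)*bin); returns a 3-row matrix:
// row 0 the weight sum per bin, rows 1-2 the weight-times-distance and
// weight-times-distance^2 sums, so the Debye evaluation can expand about the
// per-bin mean distance to second order. Used by the binned Debye sum.
// [[Rcpp::export]]
NumericMatrix pair_hist_weighted(const NumericMatrix& X, const NumericVector& f,
                                 double bin) {
  const int n = X.nrow();
  std::vector<double> h, hd, hd2;
  for (int i = 0; i < n; ++i) {
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2), fi = f[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - X(j, 0), dy = yi - X(j, 1), dz = zi - X(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      const size_t b = (size_t)(d / bin);
      if (b >= h.size()) { h.resize(b + 1, 0.0); hd.resize(b + 1, 0.0); hd2.resize(b + 1, 0.0); }
      const double w = fi * f[j];
      h[b] += w;
      hd[b] += w * d;
      hd2[b] += w * d * d;
    }
  }
  NumericMatrix out(3, h.size());
  for (size_t b = 0; b < h.size(); ++b) {
    out(0, b) = h[b]; out(1, b) = hd[b]; out(2, b) = hd2[b];
  }
  return out;
}

// Weighted cross-distance histogram between two point sets (all pairs);
// same 3-row layout as pair_hist_weighted. Also counts pairs closer than
// `clash_cutoff` (attribute-free: returned as a List) so assembly scoring
// needs a single pass over the pair distances.
// [[Rcpp::export]]
List cross_hist_weighted(const NumericMatrix& X, const NumericVector& fx,
                         const NumericMatrix& Y, const NumericVector& fy,
                         double bin, double clash_cutoff = 0.0) {
  const int n = X.nrow(), m = Y.nrow();
  std::vector<double> h, hd, hd2;
  double nclash = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2), fi = fx[i];
    for (int j = 0; j < m; ++j) {
      const double dx = xi - Y(j, 0), dy = yi - Y(j, 1), dz = zi - Y(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < clash_cutoff) nclash += 1;
      const size_t b = (size_t)(d / bin);
      if (b >= h.size()) { h.resize(b + 1, 0.0); hd.resize(b + 1, 0.0); hd2.resize(b + 1, 0.0); }
      const double w = fi * fy[j];
      h[b] += w;
      hd[b] += w * d;
      hd2[b] += w * d * d;
    }
  }
  NumericMatrix out(3, h.size());
  for (size_t b = 0; b < h.size(); ++b) {
    out(0, b) = h[b]; out(1, b) = hd[b]; out(2, b) = hd2[b];
  }
  return List::create(_["hist"] = out, _["n_clash"] = nclash);
}

// Exact Debye double sum: I(q) = sum_i f_i^2 + 2 sum_{i<j} f_i f_j sinc(q d_ij).
// [[Rcpp::export]]
NumericVector debye_exact_cpp(const NumericMatrix& X, const NumericVector& f,
                              const NumericVector& q) {
  const int n = X.nrow(), nq = q.size();
  NumericVector I(nq);
  double s2 = 0.0;
  for (int i = 0; i < n; ++i) s2 += f[i] * f[i];
  for (int k = 0; k < nq; ++k) I[k] = s2;
  for (int i = 0; i < n; ++i) {
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2), fi = f[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - X(j, 0), dy = yi - X(j, 1), dz = zi - X(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double w = 2.0 * fi * f[j];
      for (int k = 0; k < nq; ++k) {
        const double qr = q[k] * d;
        I[k] += w * (qr < 1e-12 ? 1.0 : std::sin(qr) / qr);
      }
    }
  }
  return I;
}

// Evaluate the Debye intensity from a 3-row weighted pair-distance histogram
// (sum w, sum w*d, sum w*d^2): second-order Taylor expansion of sinc about
// each bin's weighted mean distance.
// [[Rcpp::export]]
NumericVector hist_intensity_cpp(const NumericMatrix& h, double f2_sum,
                                 const NumericVector& q) {
  const int nb = h.ncol(), nq = q.size();
  NumericVector I(nq, f2_sum);
  std::vector<double> dmean, dvar, w;
  for (int b = 0; b < nb; ++b) {
    const double wb = h(0, b);
    if (wb <= 0) continue;
    const double m = h(1, b) / wb;
    w.push_back(wb);
    dmean.push_back(m);
    dvar.push_back(std::max(0.0, h(2, b) / wb - m * m));
  }
  const int nocc = (int)w.size();
  for (int k = 0; k < nq; ++k) {
    const double qk = q[k];
    double acc = 0.0;
    for (int b = 0; b < nocc; ++b) {
      const double x = qk * dmean[b];
      double s, s2;
      if (std::fabs(x) < 1e-4) {
        s = 1.0 - x * x / 6.0;
        s2 = -1.0 / 3.0 + x * x / 10.0;
      } else {
        const double sx = std::sin(x), cx = std::cos(x);
        s = sx / x;
        s2 = -sx / x - 2.0 * cx / (x * x) + 2.0 * sx / (x * x * x);
      }
      acc += w[b] * (s + 0.5 * s2 * qk * qk * dvar[b]);
    }
    I[k] += 2.0 * acc;
  }
  return I;
}

struct CellKey {
  long long k;
  bool operator==(const CellKey& o) const { return k == o.k; }
};
struct CellHash {
  size_t operator()(const CellKey& c) const { return std::hash<long long>()(c.k); }
};

static inline long long cell_index(int cx, int cy, int cz) {
  // pack three 21-bit signed cell coordinates
  const long long off = 1 << 20;
  return (((long long)(cx + off)) << 42) | (((long long)(cy + off)) << 21) |
         ((long long)(cz + off));
}

// Count pairs (x in X, y in Y) with distance < cutoff, via a spatial cell grid
// over Y with cell edge = cutoff (checks the 27 neighboring cells).
// [[Rcpp::export]]
double count_close_pairs(const NumericMatrix& X, const NumericMatrix& Y,
                         double cutoff) {
  const int n = X.nrow(), m = Y.nrow();
  const double c2 = cutoff * cutoff, inv = 1.0 / cutoff;
  std::unordered_map<CellKey, std::vector<int>, CellHash> grid;
  grid.reserve(m * 2);
  for (int j = 0; j < m; ++j) {
    CellKey key{cell_index((int)std::floor(Y(j, 0) * inv),
                           (int)std::floor(Y(j, 1) * inv),
                           (int)std::floor(Y(j, 2) * inv))};
    grid[key].push_back(j);
  }
  double count = 0;
  for (int i = 0; i < n; ++i) {
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
    const int cx = (int)std::floor(xi * inv), cy = (int)std::floor(yi * inv),
              cz = (int)std::floor(zi * inv);
    for (int ax = cx - 1; ax <= cx + 1; ++ax)
      for (int ay = cy - 1; ay <= cy + 1; ++ay)
        for (int az = cz - 1; az <= cz + 1; ++az) {
          auto it = grid.find(CellKey{cell_index(ax, ay, az)});
          if (it == grid.end()) continue;
          for (int j : it->second) {
            const double dx = xi - Y(j, 0), dy = yi - Y(j, 1), dz = zi - Y(j, 2);
            if (dx * dx + dy * dy + dz * dz < c2) count += 1;
          }
        }
  }
  return count;
}

// Batch scorer for generator-symmetric assemblies: for each parameter row
// (ZYZ-intrinsic Euler angles in degrees, translation in Angstrom) build the
// n_units-copy assembly from the seed coordinates, accumulate the weighted
// pair-distance histogram per unit offset (counting clash pairs in the same
// pass), and evaluate the reduced chi-square against (q, Ie, s2) with the
// analytic scale factor. Returns an m x 3 matrix (chi2, scale, clashes);
// chi2 = NA for clashing models. h_intra is the precomputed intra-unit
// histogram already multiplied by n_units; f2n = n_units * sum(f^2).
// [[Rcpp::export]]
NumericMatrix score_param_batch(const NumericMatrix& U, const NumericVector& f,
                                const NumericVector& q, const NumericVector& Ie,
                                const NumericVector& s2,
                                const NumericMatrix& P, int n_units,
                                double bin, double clash_cutoff,
                                const NumericMatrix& h_intra, double f2n) {
  const int n = U.nrow(), m = P.nrow(), nq = q.size();
  const double d2r = M_PI / 180.0;
  NumericMatrix out(m, 3);
  std::vector<double> h, hd, hd2;
  std::vector<double> Uk(n * 3);
  for (int mi = 0; mi < m; ++mi) {
    const double ca = std::cos(P(mi, 0) * d2r), sa = std::sin(P(mi, 0) * d2r);
    const double cb = std::cos(P(mi, 1) * d2r), sb = std::sin(P(mi, 1) * d2r);
    const double cg = std::cos(P(mi, 2) * d2r), sg = std::sin(P(mi, 2) * d2r);
    // R = Rz(alpha) Ry(beta) Rz(gamma)
    double R[9] = {ca * cb * cg - sa * sg, -ca * cb * sg - sa * cg, ca * sb,
                   sa * cb * cg + ca * sg, -sa * cb * sg + ca * cg, sa * sb,
                   -sb * cg,                sb * sg,                 cb};
    const double tx = P(mi, 3), ty = P(mi, 4), tz = P(mi, 5);
    const size_t nb0 = h_intra.ncol();
    h.assign(nb0, 0.0); hd.assign(nb0, 0.0); hd2.assign(nb0, 0.0);
    for (size_t b = 0; b < nb0; ++b) {
      h[b] = h_intra(0, b); hd[b] = h_intra(1, b); hd2[b] = h_intra(2, b);
    }
    double Rk[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
    double tk[3] = {0, 0, 0};
    double clashes = 0;
    for (int k = 1; k < n_units; ++k) {
      // tk <- R tk + t ; Rk <- R Rk
      double t2[3] = {R[0] * tk[0] + R[1] * tk[1] + R[2] * tk[2] + tx,
                      R[3] * tk[0] + R[4] * tk[1] + R[5] * tk[2] + ty,
                      R[6] * tk[0] + R[7] * tk[1] + R[8] * tk[2] + tz};
      double R2[9];
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c)
          R2[3 * r + c] = R[3 * r] * Rk[c] + R[3 * r + 1] * Rk[3 + c] +
                          R[3 * r + 2] * Rk[6 + c];
      for (int i = 0; i < 9; ++i) Rk[i] = R2[i];
      for (int i = 0; i < 3; ++i) tk[i] = t2[i];
      for (int i = 0; i < n; ++i) {
        Uk[3 * i] = Rk[0] * U(i, 0) + Rk[1] * U(i, 1) + Rk[2] * U(i, 2) + tk[0];
        Uk[3 * i + 1] = Rk[3] * U(i, 0) + Rk[4] * U(i, 1) + Rk[5] * U(i, 2) + tk[1];
        Uk[3 * i + 2] = Rk[6] * U(i, 0) + Rk[7] * U(i, 1) + Rk[8] * U(i, 2) + tk[2];
      }
      const double mult = (double)(n_units - k);
      for (int i = 0; i < n && clashes == 0; ++i) {
        const double xi = U(i, 0), yi = U(i, 1), zi = U(i, 2), fi = f[i];
        for (int j = 0; j < n; ++j) {
          const double dx = xi - Uk[3 * j], dy = yi - Uk[3 * j + 1],
                       dz = zi - Uk[3 * j + 2];
          const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d < clash_cutoff) { clashes += 1; break; }
          const size_t b = (size_t)(d / bin);
          if (b >= h.size()) { h.resize(b + 1, 0.0); hd.resize(b + 1, 0.0); hd2.resize(b + 1, 0.0); }
          const double w = mult * fi * f[j];
          h[b] += w; hd[b] += w * d; hd2[b] += w * d * d;
        }
      }
      if (clashes > 0) break;
    }
    if (clashes > 0) {
      out(mi, 0) = NA_REAL; out(mi, 1) = NA_REAL; out(mi, 2) = 1;
      continue;
    }
    // chi2 with analytic scale on the supplied grid
    double num = 0.0, den = 0.0;
    std::vector<double> Im(nq);
    for (int kq = 0; kq < nq; ++kq) {
      const double qk = q[kq];
      double acc = f2n;
      for (size_t b = 0; b < h.size(); ++b) {
        if (h[b] <= 0) continue;
        const double dm = hd[b] / h[b];
        const double dv = std::max(0.0, hd2[b] / h[b] - dm * dm);
        const double x = qk * dm;
        double sf, s2f;
        if (std::fabs(x) < 1e-4) { sf = 1.0 - x * x / 6.0; s2f = -1.0 / 3.0 + x * x / 10.0; }
        else {
          const double sx = std::sin(x), cx = std::cos(x);
          sf = sx / x;
          s2f = -sx / x - 2.0 * cx / (x * x) + 2.0 * sx / (x * x * x);
        }
        acc += 2.0 * h[b] * (sf + 0.5 * s2f * qk * qk * dv);
      }
      Im[kq] = acc;
      num += Ie[kq] * acc / s2[kq];
      den += acc * acc / s2[kq];
    }
    const double cc = num / den;
    double chi2 = 0.0;
    for (int kq = 0; kq < nq; ++kq) {
      const double r = Ie[kq] - cc * Im[kq];
      chi2 += r * r / s2[kq];
    }
    out(mi, 0) = chi2 / (nq - 1);
    out(mi, 1) = cc;
    out(mi, 2) = 0;
  }
  return out;
}

// Shrake-Rupley solvent-accessible surface area with deterministic
// golden-spiral sphere points. Returns per-atom accessible area (A^2).
// [[Rcpp::export]]
NumericVector sasa_cpp(const NumericMatrix& X, const NumericVector& radii,
                       double probe, int n_points) {
  const int n = X.nrow();
  NumericVector area(n);
  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    const double zk = 1.0 - 2.0 * (k + 0.5) / n_points;
    const double rk = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    px[k] = std::cos(ga * k) * rk;
    py[k] = std::sin(ga * k) * rk;
    pz[k] = zk;
  }
  for (int i = 0; i < n; ++i) {
    const double Ri = radii[i] + probe;
    // neighbors that can occlude atom i
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double Rj = radii[j] + probe;
      const double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
                   dz = X(i, 2) - X(j, 2);
      if (dx * dx + dy * dy + dz * dz < (Ri + Rj) * (Ri + Rj)) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      const double sx = X(i, 0) + Ri * px[k], sy = X(i, 1) + Ri * py[k],
                   sz = X(i, 2) + Ri * pz[k];
      bool buried = false;
      for (int j : nb) {
        const double Rj = radii[j] + probe;
        const double dx = sx - X(j, 0), dy = sy - X(j, 1), dz = sz - X(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)acc / n_points;
  }
  return area;
}
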
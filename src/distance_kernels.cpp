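#include <Rcpp.h>
using namespace Rcpp;

// Coarse cross-partner pair potential over two coordinate sets (rows = points).
// d < d_clash: harmonic repulsion k_rep * (d_clash - d)^2; d_clash <= d < d_contact:
// constant reward -eps; beyond: zero. Distances in Angstrom.
// [[Rcpp::export]]
double cpp_pair_potential(const NumericMatrix& a, const NumericMatrix& b,
                          double d_clash, double d_contact,
                          double k_rep, double eps) {
  const int n = a.nrow(), m = b.nrow();
  const double c2 = d_contact * d_contact;
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= c2) continue;
      const double d = std::sqrt(d2);
      if (d < d_clash) {
        const double gap = d_clash - d;
        e += k_rep * gap * gap;
      } else {
        e -= eps;
      }
    }
  }
  return e;
}

// Minimum distance between any row of a and any row of b.
// [[Rcpp::export]]
double cpp_min_cross_dist(const NumericMatrix& a, const NumericMatrix& b) {
  const int n = a.nrow(), m = b.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// All cross pairs (i, j), 1-based, with distance <= cutoff.
// [[Rcpp::export]]
IntegerMatrix cpp_pairs_within(const NumericMatrix& a, const NumericMatrix& b,
                               double cutoff) {
  const int n = a.nrow(), m = b.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      if (dx * dx + dy * dy + dz * dz <= c2) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k];
    out(k, 1) = jj[k];
  }
  return out;
}
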
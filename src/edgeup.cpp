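// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Matched-filter selection of the minimum-SSR template for every
// neighbourhood column. Ecn holds the mean-centred, SEE-normalised
// low-resolution templates (27 x n_units); NB holds the 3x3x3
// neighbourhoods (27 x n_voxels). Minimising SSR over (K, B) per unit
// is equivalent to maximising z^2 where z = Ecn' I, so the best unit
// is the row with maximal |z|; ties resolve to the lowest unit index.
// Returns 1-based best index and the signed score z at the optimum.
// [[Rcpp::export]]
List cpp_best_fit(const arma::mat& Ecn, const arma::mat& NB) {
  const arma::uword n = Ecn.n_cols, V = NB.n_cols;
  if (Ecn.n_rows != NB.n_rows) stop("row mismatch between templates and neighbourhoods");
  arma::uvec best(V);
  arma::vec zbest(V);
  // chunk voxels so the score matrix stays ~100 MB regardless of n
  arma::uword chunk = std::max<arma::uword>(32, std::min<arma::uword>(4096, 12500000 / std::max<arma::uword>(n, 1)));
  for (arma::uword s = 0; s < V; s += chunk) {
    arma::uword e = std::min(s + chunk, V) - 1;
    arma::mat S = Ecn.t() * NB.cols(s, e); // n x m
    for (arma::uword v = 0; v < S.n_cols; ++v) {
      const double* col = S.colptr(v);
      double m = -1.0;
      arma::uword w = 0;
      for (arma::uword u = 0; u < n; ++u) {
        double a = std::abs(col[u]);
        if (a > m) { m = a; w = u; }
      }
      best(s + v) = w + 1;
      zbest(s + v) = col[w];
    }
  }
  return List::create(_["index"] = IntegerVector(best.begin(), best.end()),
                      _["z"] = NumericVector(zbest.begin(), zbest.end()));
}

// 26-connected component labelling of a 3D logical mask.
// Returns an integer array of labels (0 = background), labelled in
// first-encounter (column-major scan) order, so labelling is
// deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(const LogicalVector& mask, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i0 = 0; i0 < n; ++i0) {
    if (!mask[i0] || lab[i0]) continue;
    ++next;
    lab[i0] = next;
    stack.push_back(i0);
    while (!stack.empty()) {
      R_xlen_t i = stack.back();
      stack.pop_back();
      int x = i % nx, y = (i / nx) % ny, z = i / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
            R_xlen_t j = X + nx * (Y + (R_xlen_t)ny * Z);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
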
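#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Correlation-integral pair counts for a delay-embedded series.
// embt: m x n matrix, column i = embedded vector i (column-major R
// storage makes each vector contiguous).
// r: increasing vector of distance thresholds (Euclidean).
// theiler: pairs with |i - j| <= theiler are excluded.
// Returns counts[k] = number of pairs with distance <= r[k], plus the
// total number of admissible pairs.
// [[Rcpp::export(name = ".corr_integral_counts")]]
List corr_integral_counts(NumericMatrix embt, NumericVector r, int theiler) {
  const int m = embt.nrow(), n = embt.ncol(), nr = r.size();
  const double *x = embt.begin();
  std::vector<double> r2(nr);
  for (int k = 0; k < nr; ++k) r2[k] = r[k] * r[k];
  std::vector<double> counts(nr, 0.0);
  double npairs = 0.0;
  const double rmax2 = r2[nr - 1];
  for (int i = 0; i < n; ++i) {
    const double *xi = x + (size_t)i * m;
    for (int j = i + theiler + 1; j < n; ++j) {
      const double *xj = x + (size_t)j * m;
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        const double diff = xi[c] - xj[c];
        d2 += diff * diff;
        if (d2 > rmax2) break;
      }
      npairs += 1.0;
      if (d2 > rmax2) continue;
      int k = int(std::lower_bound(r2.begin(), r2.end(), d2) - r2.begin());
      for (; k < nr; ++k) counts[k] += 1.0;
    }
  }
  // npairs counted fully even with the early break above
  return List::create(_["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["npairs"] = npairs);
}

// Diagonal line lengths of the recurrence plot of an embedded series.
// embt: m x n matrix, column i = embedded vector i. A recurrence is
// d(v_i, v_j) < r (Euclidean, strict). Only the upper triangle beyond
// the Theiler window is scanned (j - i > theiler); each maximal diagonal
// run of recurrences with length >= lmin is recorded.
// [[Rcpp::export(name = ".recurrence_diag_lengths")]]
IntegerVector recurrence_diag_lengths(NumericMatrix embt, double r,
                                      int theiler, int lmin) {
  const int m = embt.nrow(), n = embt.ncol();
  const double *x = embt.begin();
  const double r2 = r * r;
  std::vector<int> lens;
  for (int off = theiler + 1; off < n; ++off) {
    int run = 0;
    for (int i = 0; i + off < n; ++i) {
      const double *xi = x + (size_t)i * m;
      const double *xj = x + (size_t)(i + off) * m;
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        const double diff = xi[c] - xj[c];
        d2 += diff * diff;
        if (d2 >= r2) break;
      }
      if (d2 < r2) {
        ++run;
      } else {
        if (run >= lmin) lens.push_back(run);
        run = 0;
      }
    }
    if (run >= lmin) lens.push_back(run);
  }
  return IntegerVector(lens.begin(), lens.end());
}
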
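#include <Rcpp.h>
using namespace Rcpp;

// Exact Jenks / Fisher natural-breaks optimisation.
//
// Dynamic programme over sorted values: D[i][k] = minimal total within-class
// sum of squared deviations when the first i values are split into k classes.
// Class SSD is O(1) via prefix sums. O(k n^2) time, O(k n) memory; the
// backtracked partition is a provable global optimum, not a heuristic.

static inline double ssd(const std::vector<double>& cs,
                         const std::vector<double>& cs2,
                         int j, int i) {
  // values j..i (1-based, inclusive)
  double s  = cs[i]  - cs[j - 1];
  double s2 = cs2[i] - cs2[j - 1];
  int    n  = i - j + 1;
  return s2 - s * s / n;
}

// [[Rcpp::export(name = ".jenks_dp")]]
List jenks_dp(NumericVector sorted_values, int n_classes) {
  const int n = sorted_values.size();
  if (n_classes < 1) stop("n_classes must be >= 1");
  if (n < n_classes) stop("fewer values than classes");

  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 1; i <= n; ++i) {
    double v = sorted_values[i - 1];
    cs[i]  = cs[i - 1] + v;
    cs2[i] = cs2[i - 1] + v * v;
  }

  // D[k][i], B[k][i]: cost and last-class start for first i values in k classes
  std::vector<std::vector<double> > D(n_classes + 1,
      std::vector<double>(n + 1, R_PosInf));
  std::vector<std::vector<int> > B(n_classes + 1,
      std::vector<int>(n + 1, 0));

  for (int i = 1; i <= n; ++i) {
    D[1][i] = ssd(cs, cs2, 1, i);
    B[1][i] = 1;
  }
  for (int k = 2; k <= n_classes; ++k) {
    for (int i = k; i <= n; ++i) {
      double best = R_PosInf;
      int arg = k;
      for (int j = k; j <= i; ++j) {      // last class is values j..i
        double c = D[k - 1][j - 1] + ssd(cs, cs2, j, i);
        if (c < best) { best = c; arg = j; }
      }
      D[k][i] = best;
      B[k][i] = arg;
    }
  }

  IntegerVector starts(n_classes);       // 1-based index of each class start
  int i = n;
  for (int k = n_classes; k >= 1; --k) {
    starts[k - 1] = B[k][i];
    i = B[k][i] - 1;
  }
  return List::create(_["starts"] = starts, _["ssd"] = D[n_classes][n]);
}
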
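#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Dense rectangular linear assignment by shortest augmenting paths with
// dual potentials (Hungarian / Jonker-Volgenant family).  Rows must not
// outnumber columns; the R wrapper transposes and pads as needed.
// Forbidden pairs are encoded as very large finite costs by the caller.
//
// Returns a 1-based column index for every row (0 = unassigned, which
// cannot happen when nr <= nc and costs are finite).
// [[Rcpp::export(name = ".lap_solve_cpp")]]
IntegerVector lap_solve_cpp(NumericMatrix cost) {
  const int n = cost.nrow();   // rows, n <= m
  const int m = cost.ncol();
  if (n > m) stop("internal: LAP solver requires nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();

  // row-major copy so the inner column scan is contiguous
  std::vector<double> a(static_cast<size_t>(n) * m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      a[static_cast<size_t>(i) * m + j] = cost(i, j);

  // p[j] = row matched to column j (1-based rows, 0 = free); column 0 is a
  // virtual root used by the augmenting-path search.
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0), minv(m + 1);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);

  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      const double ui0 = u[i0];
      const double *row = a.data() + static_cast<size_t>(i0 - 1) * m - 1;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = row[j] - ui0 - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      if (j1 < 0) stop("internal: LAP search exhausted (all costs infinite?)");
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    // augment along the alternating path
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }

  IntegerVector row_to_col(n, 0);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) row_to_col[p[j] - 1] = j;
  return row_to_col;
}
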
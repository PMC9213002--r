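#include <Rcpp.h>
using namespace Rcpp;

// Gabriel graph of a 3D point set: edge (u,v) iff the open ball with
// diameter uv contains no third point.  Strict test via the equivalent
// dot-product form (u-w).(v-w) < 0, so boundary (right-angle) witnesses do
// not delete an edge.  O(n^2) pairs with early-exit witness scan.
// [[Rcpp::export(name = ".gabriel_edges_cpp")]]
IntegerMatrix gabriel_edges_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  std::vector<int> ea, eb;
  for (int a = 0; a < n - 1; ++a) {
    for (int b = a + 1; b < n; ++b) {
      bool blocked = false;
      for (int w = 0; w < n && !blocked; ++w) {
        if (w == a || w == b) continue;
        double dot = 0.0;
        for (int k = 0; k < 3; ++k) {
          double aw = pts(a, k) - pts(w, k);
          double bw = pts(b, k) - pts(w, k);
          dot += aw * bw;
        }
        if (dot < 0.0) blocked = true;
      }
      if (!blocked) { ea.push_back(a + 1); eb.push_back(b + 1); }
    }
  }
  IntegerMatrix out(ea.size(), 2);
  for (size_t i = 0; i < ea.size(); ++i) { out(i, 0) = ea[i]; out(i, 1) = eb[i]; }
  return out;
}
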
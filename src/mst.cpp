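#include <Rcpp.h>
using namespace Rcpp;

// Minimum spanning tree of the complete mutual-reachability graph over 2-D
// points, by Prim's algorithm with on-the-fly distances:
// d_mreach(i, j) = max(core[i], core[j], d_euclid(i, j)).
// O(n^2) time, O(n) memory; n is the exploration subsample, not full data.
// [[Rcpp::export(name = ".mst_mutual_reachability")]]
DataFrame mst_mutual_reachability(NumericMatrix coords, NumericVector core) {
  const int n = coords.nrow();
  if (n < 2) stop("need at least 2 points");
  const double *x = &coords(0, 0);
  const double *y = &coords(0, 1);

  std::vector<double> best(n, R_PosInf);
  std::vector<int> from(n, -1);
  std::vector<bool> used(n, false);

  IntegerVector efrom(n - 1), eto(n - 1);
  NumericVector ew(n - 1);

  int cur = 0;
  used[0] = true;
  for (int it = 0; it < n - 1; ++it) {
    const double cx = x[cur], cy = y[cur], cc = core[cur];
    int nxt = -1;
    double nbest = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (used[j]) continue;
      const double dx = x[j] - cx, dy = y[j] - cy;
      double d = std::sqrt(dx * dx + dy * dy);
      if (cc > d) d = cc;
      if (core[j] > d) d = core[j];
      if (d < best[j]) { best[j] = d; from[j] = cur; }
      if (best[j] < nbest) { nbest = best[j]; nxt = j; }
    }
    efrom[it] = from[nxt] + 1;
    eto[it] = nxt + 1;
    ew[it] = best[nxt];
    used[nxt] = true;
    cur = nxt;
  }
  return DataFrame::create(_["from"] = efrom, _["to"] = eto,
                           _["weight"] = ew);
}
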
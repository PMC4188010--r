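#include <Rcpp.h>
using namespace Rcpp;

// Exact circular shortest path across the columns of a cost matrix.
// A path picks one row per column; consecutive rows (including the wrap
// from the last column back to the first) may differ by at most `step`.
// The constrained DP is run from every start row and the global minimum
// kept, so the result is exact.
// [[Rcpp::export(name = ".cspExact")]]
IntegerVector cspExact(NumericMatrix cost, int step) {
  const int R = cost.nrow(), C = cost.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  double bestTotal = INF;
  int bestStart = -1, bestEnd = -1;
  std::vector<double> prev(R), cur(R);

  for (int s = 0; s < R; ++s) {
    for (int r = 0; r < R; ++r) prev[r] = INF;
    prev[s] = cost(s, 0);
    for (int j = 1; j < C; ++j) {
      for (int r = 0; r < R; ++r) {
        double m = INF;
        int lo = std::max(0, r - step), hi = std::min(R - 1, r + step);
        for (int q = lo; q <= hi; ++q)
          if (prev[q] < m) m = prev[q];
        cur[r] = (m == INF) ? INF : m + cost(r, j);
      }
      std::swap(prev, cur);
    }
    for (int r = std::max(0, s - step); r <= std::min(R - 1, s + step); ++r)
      if (prev[r] < bestTotal) {
        bestTotal = prev[r];
        bestStart = s;
        bestEnd = r;
      }
  }

  // second pass for the winning start, keeping backpointers
  std::vector<std::vector<int>> back(C, std::vector<int>(R, -1));
  std::vector<double> d(R, INF);
  d[bestStart] = cost(bestStart, 0);
  for (int j = 1; j < C; ++j) {
    for (int r = 0; r < R; ++r) {
      double m = INF;
      int arg = -1;
      int lo = std::max(0, r - step), hi = std::min(R - 1, r + step);
      for (int q = lo; q <= hi; ++q)
        if (d[q] < m) { m = d[q]; arg = q; }
      cur[r] = (m == INF) ? INF : m + cost(r, j);
      back[j][r] = arg;
    }
    d = cur;
  }
  IntegerVector path(C);
  int r = bestEnd;
  for (int j = C - 1; j >= 1; --j) {
    path[j] = r + 1;  // 1-based for R
    r = back[j][r];
  }
  path[0] = r + 1;
  path.attr("cost") = bestTotal;
  return path;
}
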
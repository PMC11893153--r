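// Brute-force exact solver for small transportation problems, used as the
// independent oracle against the linear-programming route.
//
// Enumerates the vertices of the transportation polytope through the
// greedy-deletion construction: pick any remaining (row, column) cell,
// ship the minimum of the two residual masses, delete the exhausted side,
// repeat. Every basic feasible solution arises from some pick order, so
// an exhaustive search over pick orders covers every vertex, and the
// optimum of the LP is attained at a vertex. Branch-and-bound keeps the
// search tractable on the small supports this oracle is restricted to:
// the incumbent starts at a cheapest-cell greedy feasible plan, children
// are explored cheapest first, and a branch is cut when the partial cost
// plus a ship-everything-to-its-cheapest-destination bound cannot beat
// the incumbent.

#include <Rcpp.h>
#include <algorithm>

namespace {

constexpr double kMassTol = 1e-12;
constexpr int kMaxSupport = 16;

struct Search {
  int m, n;
  double cost[kMaxSupport][kMaxSupport];
  double best;

  double lower_bound(const double *a, const double *b, const int *rows,
                     int nr, const int *cols, int nc) const {
    double lb_rows = 0.0, lb_cols = 0.0;
    for (int r = 0; r < nr; ++r) {
      double cmin = R_PosInf;
      for (int c = 0; c < nc; ++c)
        cmin = std::min(cmin, cost[rows[r]][cols[c]]);
      lb_rows += a[rows[r]] * cmin;
    }
    for (int c = 0; c < nc; ++c) {
      double cmin = R_PosInf;
      for (int r = 0; r < nr; ++r)
        cmin = std::min(cmin, cost[rows[r]][cols[c]]);
      lb_cols += b[cols[c]] * cmin;
    }
    return std::max(lb_rows, lb_cols);
  }

  // Partial-order reduction: two consecutive picks that touch disjoint
  // rows and columns commute (same residuals either way), so any pick
  // sequence can be reordered, by adjacent commuting swaps, into one
  // where each pick either shares a row or column with its predecessor
  // or is lexicographically larger. Enumerating only such canonical
  // sequences still reaches every vertex.
  void recurse(double *a, double *b, int *rows, int nr, int *cols, int nc,
               int lastI, int lastJ, double acc) {
    if (nr == 0 || nc == 0) {
      if (acc < best) best = acc;
      return;
    }
    if (nr == 1) {  // closed form: everything ships from the single row
      double v = acc;
      for (int c = 0; c < nc; ++c) v += b[cols[c]] * cost[rows[0]][cols[c]];
      if (v < best) best = v;
      return;
    }
    if (nc == 1) {
      double v = acc;
      for (int r = 0; r < nr; ++r) v += a[rows[r]] * cost[rows[r]][cols[0]];
      if (v < best) best = v;
      return;
    }
    if (acc + lower_bound(a, b, rows, nr, cols, nc) >= best) return;

    // candidate cells respecting the canonical order, cheapest first
    std::pair<double, std::pair<int, int> > cells[kMaxSupport * kMaxSupport];
    int nk = 0;
    for (int r = 0; r < nr; ++r) {
      int i = rows[r];
      for (int c = 0; c < nc; ++c) {
        int j = cols[c];
        bool dependent = (i == lastI || j == lastJ);
        bool lex_after = (i > lastI || (i == lastI && j > lastJ));
        if (!dependent && !lex_after) continue;
        cells[nk++] = std::make_pair(cost[i][j], std::make_pair(i, j));
      }
    }
    std::sort(cells, cells + nk);

    int rows2[kMaxSupport], cols2[kMaxSupport];
    for (int t = 0; t < nk; ++t) {
      int i = cells[t].second.first;
      int j = cells[t].second.second;
      double x = std::min(a[i], b[j]);
      a[i] -= x;
      b[j] -= x;
      int nr2 = 0, nc2 = 0;
      for (int r = 0; r < nr; ++r)
        if (!(rows[r] == i && a[i] <= kMassTol)) rows2[nr2++] = rows[r];
      for (int c = 0; c < nc; ++c)
        if (!(cols[c] == j && b[j] <= kMassTol)) cols2[nc2++] = cols[c];
      recurse(a, b, rows2, nr2, cols2, nc2, i, j, acc + x * cells[t].first);
      a[i] += x;
      b[j] += x;
    }
  }

};

}  // namespace

// [[Rcpp::export]]
double w1_enumerate_cpp(Rcpp::NumericVector a, Rcpp::NumericVector b,
                        Rcpp::NumericMatrix cost) {
  int m = a.size(), n = b.size();
  if (m > kMaxSupport || n > kMaxSupport)
    Rcpp::stop("support too large for the brute-force oracle");
  if (cost.nrow() != m || cost.ncol() != n)
    Rcpp::stop("cost matrix dimensions do not match the measures");

  Search s;
  s.m = m;
  s.n = n;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) s.cost[i][j] = cost(i, j);

  // greedy feasible plan (cheapest active cell first) as initial incumbent
  {
    double a2[kMaxSupport], b2[kMaxSupport];
    bool ra[kMaxSupport], ca[kMaxSupport];
    for (int i = 0; i < m; ++i) { a2[i] = a[i]; ra[i] = true; }
    for (int j = 0; j < n; ++j) { b2[j] = b[j]; ca[j] = true; }
    double tot = 0.0;
    int nr = m, nc = n;
    while (nr > 0 && nc > 0) {
      double cmin = R_PosInf;
      int bi = -1, bj = -1;
      for (int i = 0; i < m; ++i) {
        if (!ra[i]) continue;
        for (int j = 0; j < n; ++j) {
          if (!ca[j]) continue;
          if (s.cost[i][j] < cmin) { cmin = s.cost[i][j]; bi = i; bj = j; }
        }
      }
      double x = std::min(a2[bi], b2[bj]);
      tot += x * cmin;
      a2[bi] -= x;
      b2[bj] -= x;
      if (a2[bi] <= kMassTol) { ra[bi] = false; --nr; }
      if (b2[bj] <= kMassTol) { ca[bj] = false; --nc; }
    }
    s.best = tot;
  }

  double aw[kMaxSupport], bw[kMaxSupport];
  int rows[kMaxSupport], cols[kMaxSupport];
  for (int i = 0; i < m; ++i) { aw[i] = a[i]; rows[i] = i; }
  for (int j = 0; j < n; ++j) { bw[j] = b[j]; cols[j] = j; }
  s.recurse(aw, bw, rows, m, cols, n, -1, -1, 0.0);
  return s.best;
}

// [[Rcpp::export]]
double min_permutation_cost_cpp(Rcpp::NumericMatrix cost) {
  // minimum assignment cost over all n! permutations (pruned DFS);
  // cross-check path for uniform equal-size supports
  int n = cost.nrow();
  if (cost.ncol() != n) Rcpp::stop("cost matrix must be square");
  if (n > kMaxSupport) Rcpp::stop("support too large for permutation search");
  bool used[kMaxSupport] = {false};
  double best = R_PosInf;
  struct Rec {
    int n;
    const Rcpp::NumericMatrix &cost;
    bool *used;
    double *best;
    void go(int i, double acc) {
      if (acc >= *best) return;
      if (i == n) { *best = acc; return; }
      for (int j = 0; j < n; ++j) {
        if (used[j]) continue;
        used[j] = true;
        go(i + 1, acc + cost(i, j));
        used[j] = false;
      }
    }
  } rec{n, cost, used, &best};
  rec.go(0, 0.0);
  return best;
}
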
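#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// Dynamic time warping with local cost |a_i - b_j| and the classic step set
// {diagonal, up, right}; unnormalized path sum, no endpoint relaxation.

static const double INF = std::numeric_limits<double>::infinity();

// Full DP, cost only, O(min(n,m)) memory.
static double dtw_cost_full(const std::vector<double>& a,
                            const std::vector<double>& b) {
  const size_t n = a.size(), m = b.size();
  std::vector<double> prev(m), cur(m);
  prev[0] = std::fabs(a[0] - b[0]);
  for (size_t j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::fabs(a[0] - b[j]);
  for (size_t i = 1; i < n; ++i) {
    cur[0] = prev[0] + std::fabs(a[i] - b[0]);
    for (size_t j = 1; j < m; ++j) {
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = best + std::fabs(a[i] - b[j]);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

struct PathResult {
  double cost;
  std::vector<std::pair<int, int> > path;  // (row, col), from (0,0) to (n-1,m-1)
};

// DP restricted to per-row column ranges [lo[i], hi[i]], with backtracking.
// Ranges must allow at least one monotone path; cells outside are infinite.
static PathResult dtw_windowed(const std::vector<double>& a,
                               const std::vector<double>& b,
                               const std::vector<int>& lo,
                               const std::vector<int>& hi) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<std::vector<double> > D(n);
  for (int i = 0; i < n; ++i) D[i].assign(hi[i] - lo[i] + 1, INF);
  auto get = [&](int i, int j) -> double {
    if (i < 0 || j < 0) return (i == -1 && j == -1) ? 0.0 : INF;
    if (j < lo[i] || j > hi[i]) return INF;
    return D[i][j - lo[i]];
  };
  for (int i = 0; i < n; ++i) {
    for (int j = lo[i]; j <= hi[i]; ++j) {
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else best = std::min(get(i - 1, j - 1), std::min(get(i - 1, j), get(i, j - 1)));
      if (best < INF) D[i][j - lo[i]] = best + std::fabs(a[i] - b[j]);
    }
  }
  PathResult res;
  res.cost = get(n - 1, m - 1);
  // backtrack greedily through the smaller predecessor
  int i = n - 1, j = m - 1;
  res.path.push_back(std::make_pair(i, j));
  while (i > 0 || j > 0) {
    double dd = get(i - 1, j - 1), du = get(i - 1, j), dl = get(i, j - 1);
    if (dd <= du && dd <= dl) { --i; --j; }
    else if (du <= dl) { --i; }
    else { --j; }
    res.path.push_back(std::make_pair(i, j));
  }
  std::reverse(res.path.begin(), res.path.end());
  return res;
}

static PathResult dtw_full_path(const std::vector<double>& a,
                                const std::vector<double>& b) {
  std::vector<int> lo(a.size(), 0), hi(a.size(), (int)b.size() - 1);
  return dtw_windowed(a, b, lo, hi);
}

// Halve resolution by averaging adjacent pairs; a trailing odd element drops.
static std::vector<double> reduce_by_half(const std::vector<double>& x) {
  std::vector<double> out;
  out.reserve(x.size() / 2);
  for (size_t i = 0; i + 1 < x.size(); i += 2) out.push_back((x[i] + x[i + 1]) / 2.0);
  return out;
}

// Project a coarse path (plus a square neighborhood of size `radius`) up to
// fine resolution as per-row column ranges, then repair to guarantee a
// feasible monotone corridor covering (0,0) and (n-1,m-1).
static void expand_window(const std::vector<std::pair<int, int> >& path,
                          int n, int m, int radius,
                          std::vector<int>& lo, std::vector<int>& hi) {
  lo.assign(n, m);      // sentinel: empty
  hi.assign(n, -1);
  for (size_t p = 0; p < path.size(); ++p) {
    int ci = path[p].first, cj = path[p].second;
    for (int di = -radius; di <= radius; ++di) {
      int ri = ci + di;
      if (ri < 0) continue;
      int j0 = 2 * (cj - radius), j1 = 2 * (cj + radius) + 1;
      for (int f = 0; f <= 1; ++f) {
        int i = 2 * ri + f;
        if (i >= n) continue;
        lo[i] = std::min(lo[i], std::max(0, j0));
        hi[i] = std::max(hi[i], std::min(m - 1, j1));
      }
    }
  }
  // rows past the projected corridor (odd-length leftovers): extend last range
  for (int i = 0; i < n; ++i) {
    if (hi[i] < lo[i]) {
      lo[i] = (i > 0) ? lo[i - 1] : 0;
      hi[i] = (i > 0) ? hi[i - 1] : m - 1;
    }
  }
  lo[0] = 0;
  hi[n - 1] = m - 1;
  // connectivity: a monotone path needs lo[i] <= hi[i-1] + 1 and growing ranges
  for (int i = 1; i < n; ++i) {
    if (lo[i] > hi[i - 1] + 1) lo[i] = hi[i - 1] + 1;
    if (hi[i] < hi[i - 1]) hi[i] = hi[i - 1];
    if (hi[i] < lo[i]) hi[i] = lo[i];
  }
}

static PathResult fastdtw_rec(const std::vector<double>& a,
                              const std::vector<double>& b, int radius) {
  const int min_size = radius + 2;
  if ((int)a.size() <= min_size || (int)b.size() <= min_size)
    return dtw_full_path(a, b);
  std::vector<double> sa = reduce_by_half(a), sb = reduce_by_half(b);
  PathResult low = fastdtw_rec(sa, sb, radius);
  std::vector<int> lo, hi;
  expand_window(low.path, (int)a.size(), (int)b.size(), radius, lo, hi);
  return dtw_windowed(a, b, lo, hi);
}

// [[Rcpp::export(name = ".dtw_exact_cpp")]]
double dtw_exact_cpp(NumericVector a, NumericVector b) {
  std::vector<double> va = as<std::vector<double> >(a);
  std::vector<double> vb = as<std::vector<double> >(b);
  return dtw_cost_full(va, vb);
}

// [[Rcpp::export(name = ".dtw_fast_cpp")]]
double dtw_fast_cpp(NumericVector a, NumericVector b, int radius) {
  std::vector<double> va = as<std::vector<double> >(a);
  std::vector<double> vb = as<std::vector<double> >(b);
  return fastdtw_rec(va, vb, radius).cost;
}
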
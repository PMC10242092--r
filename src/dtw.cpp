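#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Sakoe-Chiba corridor around the corner-to-corner diagonal, widened so the
// corridor is always connected under steps {(1,0),(0,1),(1,1)}.
static void band_limits(int m, int n, int r, std::vector<int>& lo,
                        std::vector<int>& hi) {
  lo.resize(m);
  hi.resize(m);
  if (m == 1) {
    lo[0] = 0;
    hi[0] = n - 1;
    return;
  }
  if (n == 1) {
    for (int i = 0; i < m; ++i) { lo[i] = 0; hi[i] = 0; }
    return;
  }
  double s = (double)(n - 1) / (double)(m - 1);
  int R = r;
  int need = (int)std::ceil(s / 2.0); // connectivity requires s <= 2R + 1
  if (need > R) R = need;
  if (R < 1) R = 1;
  for (int i = 0; i < m; ++i) {
    double li = i * s;
    int l = (int)std::floor(li) - R;
    int h = (int)std::ceil(li) + R;
    lo[i] = l < 0 ? 0 : l;
    hi[i] = h > n - 1 ? n - 1 : h;
  }
}

static inline double sq(double a, double b) {
  double d = a - b;
  return d * d;
}

// [[Rcpp::export]]
double cpp_dtw_dist(NumericVector x, NumericVector y, int r) {
  int m = x.size(), n = y.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  std::vector<int> lo, hi;
  band_limits(m, n, r, lo, hi);
  std::vector<double> prev(n, INF), cur(n, INF);
  for (int j = lo[0]; j <= hi[0]; ++j)
    prev[j] = sq(x[0], y[j]) + (j > 0 ? prev[j - 1] : 0.0);
  for (int i = 1; i < m; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    for (int j = lo[i]; j <= hi[i]; ++j) {
      double best = prev[j];                       // vertical
      if (j > 0) {
        if (prev[j - 1] < best) best = prev[j - 1]; // diagonal
        if (cur[j - 1] < best) best = cur[j - 1];   // horizontal
      }
      cur[j] = best + sq(x[i], y[j]);
    }
    std::swap(prev, cur);
  }
  return prev[n - 1];
}

// [[Rcpp::export]]
List cpp_dtw_path(NumericVector x, NumericVector y, int r) {
  int m = x.size(), n = y.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  std::vector<int> lo, hi;
  band_limits(m, n, r, lo, hi);
  std::vector<double> D((size_t)m * n, INF);
  for (int j = lo[0]; j <= hi[0]; ++j)
    D[j] = sq(x[0], y[j]) + (j > 0 ? D[j - 1] : 0.0);
  for (int i = 1; i < m; ++i) {
    for (int j = lo[i]; j <= hi[i]; ++j) {
      double best = D[(size_t)(i - 1) * n + j];
      if (j > 0) {
        double d = D[(size_t)(i - 1) * n + j - 1];
        if (d < best) best = d;
        double h = D[(size_t)i * n + j - 1];
        if (h < best) best = h;
      }
      D[(size_t)i * n + j] = best + sq(x[i], y[j]);
    }
  }
  // backtrack, preferring diagonal, then vertical, then horizontal on ties
  std::vector<int> pi, pj;
  int i = m - 1, j = n - 1;
  pi.push_back(i);
  pj.push_back(j);
  while (i > 0 || j > 0) {
    double dd = (i > 0 && j > 0) ? D[(size_t)(i - 1) * n + j - 1] : INF;
    double dv = (i > 0) ? D[(size_t)(i - 1) * n + j] : INF;
    double dh = (j > 0) ? D[(size_t)i * n + j - 1] : INF;
    if (dd <= dv && dd <= dh) {
      --i; --j;
    } else if (dv <= dh) {
      --i;
    } else {
      --j;
    }
    pi.push_back(i);
    pj.push_back(j);
  }
  int len = pi.size();
  IntegerMatrix path(len, 2);
  for (int k = 0; k < len; ++k) {
    path(k, 0) = pi[len - 1 - k] + 1; // 1-based for R
    path(k, 1) = pj[len - 1 - k] + 1;
  }
  return List::create(_["distance"] = D[(size_t)(m - 1) * n + n - 1],
                      _["path"] = path);
}

// Local minima of v whose prominence, evaluated within a window of w samples
// on each side, is at least `prominence`. The prominence of a minimum is
// min(left base, right base) - v[i], where each base is the running maximum
// encountered before a sample lower than v[i] (or the window / signal edge)
// is reached; a side with no samples contributes +Inf. Plateau minima keep
// their earliest sample. Returns 1-based indices.
// [[Rcpp::export]]
IntegerVector cpp_minima_prominence(NumericVector v, double prominence, int w) {
  int n = v.size();
  std::vector<int> keep;
  if (n < 2) return IntegerVector(0);
  for (int i = 0; i < n; ++i) {
    bool cand;
    if (i == 0)
      cand = v[0] <= v[1];
    else if (i == n - 1)
      cand = v[n - 1] < v[n - 2];
    else
      cand = (v[i - 1] > v[i]) && (v[i] <= v[i + 1]);
    if (!cand) continue;
    double lbase = -INF;
    bool scanned = false;
    int jmin = i - w < 0 ? 0 : i - w;
    for (int j = i - 1; j >= jmin; --j) {
      if (v[j] < v[i]) break;
      scanned = true;
      if (v[j] > lbase) lbase = v[j];
    }
    if (i == 0) lbase = INF;
    else if (!scanned) lbase = -INF; // immediate lower neighbour: not a min
    double rbase = -INF;
    scanned = false;
    int jmax = i + w > n - 1 ? n - 1 : i + w;
    for (int j = i + 1; j <= jmax; ++j) {
      if (v[j] < v[i]) break;
      scanned = true;
      if (v[j] > rbase) rbase = v[j];
    }
    if (i == n - 1) rbase = INF;
    else if (!scanned) rbase = -INF;
    double base = lbase < rbase ? lbase : rbase;
    if (base - v[i] >= prominence) keep.push_back(i + 1);
  }
  return wrap(keep);
}
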
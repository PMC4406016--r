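#include <Rcpp.h>
#include <vector>
#include <stack>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Best "arc" split of y[lo..hi): maximise over changepoint pairs (i, j),
// 0 <= i < j <= n, the pooled two-sample |t| between y[i..j) and its
// complement within the window. i = 0 or j = n degenerates to a single
// binary split. Every non-empty resulting child must have >= min_width
// probes. Returns false when the window admits no split.
static bool best_arc(const std::vector<double>& y, int lo, int hi,
                     int min_width, int& ibest, int& jbest, double& tbest) {
  const int n = hi - lo;
  if (n < 2 * min_width) return false;

  std::vector<double> cs(n + 1), css(n + 1);
  cs[0] = css[0] = 0.0;
  for (int k = 0; k < n; ++k) {
    const double v = y[lo + k];
    cs[k + 1] = cs[k] + v;
    css[k + 1] = css[k] + v * v;
  }
  const double S = cs[n], SS = css[n];

  ibest = -1; jbest = -1; tbest = -1.0;
  for (int i = 0; i <= n - min_width; ++i) {
    if (i != 0 && i < min_width) continue;          // left flank too small
    for (int j = i + min_width; j <= n; ++j) {
      const int nr = n - j;                          // right flank
      if (nr != 0 && nr < min_width) continue;
      const int n1 = j - i, n2 = n - n1;
      if (n2 < min_width) continue;                  // complement too small
      const double s1 = cs[j] - cs[i], ss1 = css[j] - css[i];
      const double s2 = S - s1,        ss2 = SS - ss1;
      const double m1 = s1 / n1, m2 = s2 / n2;
      double rss = (ss1 - n1 * m1 * m1) + (ss2 - n2 * m2 * m2);
      if (rss < 0.0) rss = 0.0;
      double t;
      if (n <= 2 || rss <= 0.0) {
        t = (m1 == m2) ? 0.0 : R_PosInf;  // piecewise-constant window
      } else {
        const double sp2 = rss / (n - 2);
        t = std::fabs(m1 - m2) / std::sqrt(sp2 * (1.0 / n1 + 1.0 / n2));
      }
      if (t > tbest) { tbest = t; ibest = i; jbest = j; }
    }
  }
  return ibest >= 0;
}

// [[Rcpp::export(name = ".cbs_best_split")]]
List cbs_best_split_cpp(NumericVector y, int min_width) {
  std::vector<double> v(y.begin(), y.end());
  int i, j; double t;
  if (!best_arc(v, 0, (int)v.size(), min_width, i, j, t))
    return List::create(_["i"] = NA_INTEGER, _["j"] = NA_INTEGER,
                        _["t"] = NA_REAL);
  return List::create(_["i"] = i, _["j"] = j, _["t"] = t);
}

// Permutation p-value of the observed max-|t| arc, with sequential early
// stopping: once enough exceedances have accrued that the final p-value
// must end >= alpha, the remaining permutations are skipped. Uses R's RNG
// so results are reproducible under set.seed().
static double perm_pvalue(const std::vector<double>& y, int lo, int hi,
                          int min_width, double tobs, int n_perm,
                          double alpha) {
  const int n = hi - lo;
  std::vector<double> w(y.begin() + lo, y.begin() + hi);
  const int stop_at = (int)std::ceil(alpha * (1.0 + n_perm) - 1.0);
  int exceed = 0, done = 0;
  for (int b = 0; b < n_perm; ++b) {
    for (int i = n - 1; i > 0; --i) {   // Fisher-Yates with R's RNG
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(w[i], w[j]);
    }
    int pi, pj; double t;
    best_arc(w, 0, n, min_width, pi, pj, t);
    if (t >= tobs) ++exceed;
    ++done;
    if (stop_at > 0 && exceed >= stop_at) break;
  }
  if (done < n_perm && exceed >= stop_at) return 1.0;  // early stop
  return (1.0 + exceed) / (1.0 + n_perm);
}

// Recursive (stack-based) CBS on one chromosome: accept the best arc when
// its permutation p-value is below alpha, recurse into the up-to-three
// children. Returns the 1-based end index of every segment, ascending.
// [[Rcpp::export(name = ".cbs_segment_ends")]]
IntegerVector cbs_segment_ends_cpp(NumericVector y, double alpha,
                                   int min_width, int n_perm) {
  const int n = y.size();
  std::vector<double> v(y.begin(), y.end());
  std::vector<int> ends;
  std::stack<std::pair<int, int> > todo;
  if (n > 0) todo.push(std::make_pair(0, n));
  RNGScope rng;
  while (!todo.empty()) {
    const int lo = todo.top().first, hi = todo.top().second;
    todo.pop();
    int i, j; double t;
    bool can = best_arc(v, lo, hi, min_width, i, j, t);
    if (can && t > 0.0) {
      const double p = perm_pvalue(v, lo, hi, min_width, t, n_perm, alpha);
      if (p < alpha) {
        if (j < hi - lo) todo.push(std::make_pair(lo + j, hi));
        todo.push(std::make_pair(lo + i, lo + j));
        if (i > 0) todo.push(std::make_pair(lo, lo + i));
        continue;
      }
    }
    ends.push_back(hi);
  }
  std::sort(ends.begin(), ends.end());
  return wrap(ends);
}
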
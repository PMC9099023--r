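#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Kendall S = sum over pairs of sign(xi - xj) * sign(yi - yj); tau-b uses
// the tie-corrected denominator sqrt((n0 - tx)(n0 - ty)).
static void kendall_core(const std::vector<double>& x,
                         const std::vector<double>& y,
                         double& S, double& taub) {
  const int n = x.size();
  long double s = 0;
  long long tx = 0, ty = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx == 0) ++tx;
      if (dy == 0) ++ty;
      if (dx != 0 && dy != 0) s += (dx > 0 ? 1 : -1) * (dy > 0 ? 1 : -1);
    }
  }
  const double n0 = n * (n - 1) / 2.0;
  S = (double)s;
  const double den = std::sqrt((n0 - tx) * (n0 - ty));
  taub = den > 0 ? S / den : 0.0;
}

// [[Rcpp::export]]
List cpp_kendall(NumericVector x, NumericVector y) {
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  double S, taub;
  kendall_core(xv, yv, S, taub);
  return List::create(_["S"] = S, _["tau_b"] = taub);
}

// Exact permutation null of Kendall S between a fixed reference ordering
// and every distinct rearrangement of the data values (multiset-aware via
// next_permutation). Returns the one-sided upper-tail count and the total
// number of distinct permutations.
// [[Rcpp::export]]
List cpp_kendall_exact_null(NumericVector ref, NumericVector values,
                            double S_obs) {
  std::vector<double> r(ref.begin(), ref.end());
  std::vector<double> v(values.begin(), values.end());
  std::sort(v.begin(), v.end());
  long long total = 0, ge = 0;
  double S, taub;
  do {
    kendall_core(r, v, S, taub);
    ++total;
    if (S >= S_obs - 1e-12) ++ge;
  } while (std::next_permutation(v.begin(), v.end()));
  return List::create(_["n_ge"] = (double)ge, _["n_total"] = (double)total);
}

// Seeded (via R's RNG) permutation null of Kendall S. Returns the vector
// of permuted S values.
// [[Rcpp::export]]
NumericVector cpp_kendall_perm_null(NumericVector ref, NumericVector values,
                                    int B) {
  const int n = values.size();
  std::vector<double> r(ref.begin(), ref.end());
  std::vector<double> v(values.begin(), values.end());
  NumericVector out(B);
  double S, taub;
  for (int b = 0; b < B; ++b) {
    // Fisher-Yates with R's RNG so results follow set.seed()
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(v[i], v[j]);
    }
    kendall_core(r, v, S, taub);
    out[b] = S;
  }
  return out;
}

// Two-sample Watson U^2 on a combined sorted sequence. `labels` is 1 for
// sample A, 0 for sample B, ordered by the combined sorted values;
// `block` marks tie blocks (same integer = tied values). Midrank/tie
// handling: cumulative fractions are evaluated once per tie block with
// the block size as weight.
static double watson_u2_core(const std::vector<int>& labels,
                             const std::vector<int>& block,
                             int n, int m) {
  const int N = labels.size();
  long double sum_d = 0, sum_d2 = 0;
  int cumA = 0, cumB = 0;
  int i = 0;
  while (i < N) {
    int j = i, tA = 0, tB = 0;
    while (j < N && block[j] == block[i]) {
      if (labels[j]) ++tA; else ++tB;
      ++j;
    }
    cumA += tA; cumB += tB;
    const long double d = (long double)cumA / n - (long double)cumB / m;
    const int t = j - i;
    sum_d += t * d;
    sum_d2 += t * d * d;
    i = j;
  }
  const long double nm = (long double)n * m;
  return (double)(nm / ((long double)N * N) * (sum_d2 - sum_d * sum_d / N));
}

// [[Rcpp::export]]
double cpp_watson_u2(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size(), N = n + m;
  std::vector<std::pair<double, int> > v(N);
  for (int i = 0; i < n; ++i) v[i] = std::make_pair(a[i], 1);
  for (int i = 0; i < m; ++i) v[n + i] = std::make_pair(b[i], 0);
  std::sort(v.begin(), v.end());
  std::vector<int> labels(N), block(N);
  int blk = 0;
  for (int i = 0; i < N; ++i) {
    if (i > 0 && v[i].first != v[i - 1].first) ++blk;
    labels[i] = v[i].second;
    block[i] = blk;
  }
  return watson_u2_core(labels, block, n, m);
}

// Permutation null of the two-sample Watson U^2 (labels shuffled along
// the fixed combined sorted sequence, R's RNG).
// [[Rcpp::export]]
NumericVector cpp_watson_perm_null(NumericVector a, NumericVector b, int B) {
  const int n = a.size(), m = b.size(), N = n + m;
  std::vector<std::pair<double, int> > v(N);
  for (int i = 0; i < n; ++i) v[i] = std::make_pair(a[i], 1);
  for (int i = 0; i < m; ++i) v[n + i] = std::make_pair(b[i], 0);
  std::sort(v.begin(), v.end());
  std::vector<int> labels(N), block(N);
  int blk = 0;
  for (int i = 0; i < N; ++i) {
    if (i > 0 && v[i].first != v[i - 1].first) ++blk;
    labels[i] = v[i].second;
    block[i] = blk;
  }
  NumericVector out(B);
  for (int bb = 0; bb < B; ++bb) {
    for (int i = N - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(labels[i], labels[j]);
    }
    out[bb] = watson_u2_core(labels, block, n, m);
  }
  return out;
}
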
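// Bootstrap kernel of the sliding-window local Spearman procedure.
// Kept in C++ because a default profile evaluates ~2.5e3 resamples x 11
// window sizes per spine, each needing two small rank sorts.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// average ranks (ties -> mean rank), writing into out[i] for value v[i]
void rank_average(const std::vector<double>& v, int n,
                  std::vector<int>& idx, std::vector<double>& out) {
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.begin() + n,
            [&](int a, int b) { return v[a] < v[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[idx[j + 1]] == v[idx[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) out[idx[k]] = r;
    i = j + 1;
  }
}

struct BootAcc {
  double sum_rho = 0.0, sum_p = 0.0;
  long n_used = 0, n_degenerate = 0;
};

struct Workspace {
  std::vector<int> pool, idx;
  std::vector<double> xs, ys, rx, ry;
  void reserve(int w, int m) {
    pool.resize(w);
    idx.resize(m);
    xs.resize(m); ys.resize(m); rx.resize(m); ry.resize(m);
  }
};

// one window: n_boot subsets of size m from w values
void boot_window(const double* x, const double* y, int w, int m, int n_boot,
                 bool skip_degenerate, BootAcc& acc, Workspace& ws) {
  ws.reserve(w, m);
  for (int b = 0; b < n_boot; ++b) {
    for (int i = 0; i < w; ++i) ws.pool[i] = i;
    // partial Fisher-Yates draw of m distinct indices (R's RNG stream)
    for (int i = 0; i < m; ++i) {
      int j = i + static_cast<int>(unif_rand() * (w - i));
      if (j >= w) j = w - 1;
      std::swap(ws.pool[i], ws.pool[j]);
      ws.xs[i] = x[ws.pool[i]];
      ws.ys[i] = y[ws.pool[i]];
    }
    rank_average(ws.xs, m, ws.idx, ws.rx);
    rank_average(ws.ys, m, ws.idx, ws.ry);
    double mx = 0, my = 0;
    for (int i = 0; i < m; ++i) { mx += ws.rx[i]; my += ws.ry[i]; }
    mx /= m; my /= m;
    double sxy = 0, sxx = 0, syy = 0;
    for (int i = 0; i < m; ++i) {
      const double dx = ws.rx[i] - mx, dy = ws.ry[i] - my;
      sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
    }
    if (sxx <= 0.0 || syy <= 0.0) {
      ++acc.n_degenerate;
      if (skip_degenerate) continue;
      acc.sum_rho += 0.0;
      acc.sum_p += 1.0;
      ++acc.n_used;
      continue;
    }
    double rho = sxy / std::sqrt(sxx * syy);
    if (rho > 1.0) rho = 1.0;
    if (rho < -1.0) rho = -1.0;
    // two-sided p from the t approximation on the subset size; |rho| = 1
    // is clamped so p stays positive
    double r2 = rho * rho;
    if (r2 > 1.0 - 1e-12) r2 = 1.0 - 1e-12;
    const double df = m - 2.0;
    const double t = rho * std::sqrt(df / (1.0 - r2));
    const double p = 2.0 * R::pt(-std::fabs(t), df, 1, 0);
    acc.sum_rho += rho;
    acc.sum_p += p;
    ++acc.n_used;
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_bootstrap_spearman(NumericVector x, NumericVector y,
                            int subset_size, int n_boot,
                            bool skip_degenerate) {
  const int w = x.size();
  BootAcc acc;
  Workspace ws;
  boot_window(x.begin(), y.begin(), w, subset_size, n_boot,
              skip_degenerate, acc, ws);
  return List::create(
      _["mean_rho"] = acc.n_used ? acc.sum_rho / acc.n_used : NA_REAL,
      _["mean_p"] = acc.n_used ? acc.sum_p / acc.n_used : NA_REAL,
      _["n_degenerate"] = static_cast<double>(acc.n_degenerate),
      _["n_used"] = static_cast<double>(acc.n_used));
}

// x, y must arrive sorted by the index variable (spine volume); windows are
// positional.  A window of size wsz centred on spine i is shifted inward at
// the profile edges so every spine receives every window size.
// [[Rcpp::export]]
List cpp_local_profile(NumericVector x, NumericVector y,
                       IntegerVector window_sizes, int subset_deficit,
                       int n_boot, bool skip_degenerate) {
  const int n = x.size();
  NumericVector mean_rho(n), mean_p(n), n_degenerate(n);
  IntegerVector n_windows(n);
  Workspace ws;
  for (int i = 0; i < n; ++i) {
    BootAcc acc;
    int used = 0;
    for (int k = 0; k < window_sizes.size(); ++k) {
      const int w = window_sizes[k];
      if (w > n) continue;
      int start = i - w / 2;
      if (start < 0) start = 0;
      if (start > n - w) start = n - w;
      boot_window(x.begin() + start, y.begin() + start, w,
                  w - subset_deficit, n_boot, skip_degenerate, acc, ws);
      ++used;
    }
    mean_rho[i] = acc.n_used ? acc.sum_rho / acc.n_used : NA_REAL;
    mean_p[i] = acc.n_used ? acc.sum_p / acc.n_used : NA_REAL;
    n_windows[i] = used;
    n_degenerate[i] = static_cast<double>(acc.n_degenerate);
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["mean_rho"] = mean_rho, _["mean_p"] = mean_p,
                      _["n_windows"] = n_windows,
                      _["n_degenerate"] = n_degenerate);
}
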
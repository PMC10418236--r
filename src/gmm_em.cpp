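#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 1-D Gaussian mixture fitted by EM. Deterministic quantile-based
// initialisation so results are bit-reproducible without a RNG.
// Returns the mean of the lowest-mean component (the baseline estimate
// for a fluorescence window) or NA when the fit degenerates; callers
// fall back to a percentile estimate in that case.

static double quantile_sorted(const std::vector<double>& s, double p) {
  const int n = s.size();
  if (n == 1) return s[0];
  double h = p * (n - 1);
  int lo = (int)std::floor(h);
  int hi = std::min(lo + 1, n - 1);
  return s[lo] + (h - lo) * (s[hi] - s[lo]);
}

// EM on x; returns lowest component mean, NA_REAL on degeneracy.
// For speed with large windows the sample is collapsed onto a fine grid
// (weighted EM over ~256 bins); quantization is far below the within-
// component spread and does not affect the baseline estimate.
static double em_lowest_mean(const std::vector<double>& x_raw, int n_components,
                             int max_iter, double tol) {
  std::vector<double> s(x_raw);
  std::sort(s.begin(), s.end());
  const int n_raw = s.size();
  double spread = s[n_raw - 1] - s[0];
  if (spread <= 0.0) return s[0];  // constant window: degenerate but exact

  const int K = n_components;
  std::vector<double> mu(K), sd(K), w(K, 1.0 / K);
  double sd0 = 0.0, mean0 = 0.0;
  for (int i = 0; i < n_raw; ++i) mean0 += s[i];
  mean0 /= n_raw;
  for (int i = 0; i < n_raw; ++i) sd0 += (s[i] - mean0) * (s[i] - mean0);
  sd0 = std::sqrt(sd0 / std::max(1, n_raw - 1));
  const double sd_floor = std::max(1e-8, 1e-4 * sd0);

  // collapse onto a fine grid when the window is large
  std::vector<double> x;
  std::vector<double> wt;
  if (n_raw > 512) {
    const int nb = 256;
    const double bw = spread / nb;
    std::vector<double> cnt(nb, 0.0), sum(nb, 0.0);
    for (int i = 0; i < n_raw; ++i) {
      int b = (int)((s[i] - s[0]) / bw);
      if (b >= nb) b = nb - 1;
      cnt[b] += 1.0;
      sum[b] += s[i];
    }
    for (int b = 0; b < nb; ++b) {
      if (cnt[b] > 0) {
        x.push_back(sum[b] / cnt[b]);  // occupied-bin mean
        wt.push_back(cnt[b] / n_raw);
      }
    }
  } else {
    x = x_raw;
    wt.assign(n_raw, 1.0 / n_raw);
  }
  const int n = x.size();

  // spread initial means across the quantile range
  for (int k = 0; k < K; ++k) {
    mu[k] = quantile_sorted(s, (k + 1.0) / (K + 1.0));
    sd[k] = std::max(sd0 / K, sd_floor);
  }

  std::vector<double> resp(n * K);
  std::vector<double> lw(K), inv2v(K), mu_old(K);

  for (int iter = 0; iter < max_iter; ++iter) {
    for (int k = 0; k < K; ++k) {
      lw[k] = std::log(w[k]) - std::log(sd[k]);
      inv2v[k] = 0.5 / (sd[k] * sd[k]);
      mu_old[k] = mu[k];
    }
    // E step: responsibilities via softmax over per-component log-densities
    for (int i = 0; i < n; ++i) {
      double mx = -INFINITY;
      for (int k = 0; k < K; ++k) {
        double d = x[i] - mu[k];
        double lp = lw[k] - d * d * inv2v[k];
        resp[i * K + k] = lp;
        if (lp > mx) mx = lp;
      }
      double sum = 0.0;
      for (int k = 0; k < K; ++k) {
        double e = std::exp(resp[i * K + k] - mx);
        resp[i * K + k] = e;
        sum += e;
      }
      for (int k = 0; k < K; ++k) resp[i * K + k] /= sum;
    }
    // M step (weighted)
    bool ok = true;
    for (int k = 0; k < K; ++k) {
      double nk = 0.0, mk = 0.0;
      for (int i = 0; i < n; ++i) nk += wt[i] * resp[i * K + k];
      if (nk < 1e-8) { ok = false; break; }
      for (int i = 0; i < n; ++i) mk += wt[i] * resp[i * K + k] * x[i];
      mk /= nk;
      double vk = 0.0;
      for (int i = 0; i < n; ++i)
        vk += wt[i] * resp[i * K + k] * (x[i] - mk) * (x[i] - mk);
      vk /= nk;
      mu[k] = mk;
      sd[k] = std::max(std::sqrt(vk), sd_floor);
      w[k] = nk;
    }
    if (!ok) return NA_REAL;
    // convergence on component means, relative to the data spread
    double dmax = 0.0;
    for (int k = 0; k < K; ++k)
      dmax = std::max(dmax, std::fabs(mu[k] - mu_old[k]));
    if (dmax < tol * spread) break;
  }

  // components that grabbed almost no mass are treated as degenerate
  int kmin = 0;
  for (int k = 1; k < K; ++k) if (mu[k] < mu[kmin]) kmin = k;
  if (w[kmin] < 0.02) return NA_REAL;
  return mu[kmin];
}

// [[Rcpp::export(name = ".gmm_window_baselines")]]
NumericMatrix gmm_window_baselines(NumericMatrix F, IntegerVector centers,
                                   int window_frames, int n_components,
                                   int max_iter, double tol,
                                   double fallback_quantile) {
  const int n_neurons = F.nrow();
  const int n_frames = F.ncol();
  const int n_centers = centers.size();
  const int half = window_frames / 2;
  NumericMatrix out(n_neurons, n_centers);

  for (int c = 0; c < n_centers; ++c) {
    int ctr = centers[c];  // 0-based frame index
    int lo = std::max(0, ctr - half);
    int hi = std::min(n_frames, ctr - half + window_frames);
    int m = hi - lo;
    std::vector<double> xs(m);
    for (int r = 0; r < n_neurons; ++r) {
      for (int i = 0; i < m; ++i) xs[i] = F(r, lo + i);
      double b = NA_REAL;
      if (m >= n_components)
        b = em_lowest_mean(xs, n_components, max_iter, tol);
      if (!R_finite(b)) {
        std::vector<double> srt(xs);
        std::sort(srt.begin(), srt.end());
        b = quantile_sorted(srt, fallback_quantile);
      }
      out(r, c) = b;
    }
  }
  return out;
}
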
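#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Log-likelihood of one event ordering given per-subject log densities.
//
// logE(j, i): log density of subject j's value for region i under the
// diseased (event-occurred) component; logH(j, i): under the healthy
// component. `s` is a 0-based permutation of region indices. The subject
// likelihood marginalizes a uniform prior over stages k = 0..N:
//   P(x_j | S) = 1/(N+1) * sum_k prod_{i<=k} pE(x at s(i)) prod_{i>k} pH(...)
// computed in the log domain with log-sum-exp.
static double ll_ordering(const NumericMatrix& logE, const NumericMatrix& logH,
                          const std::vector<int>& s) {
  const int J = logE.nrow();
  const int N = (int)s.size();
  std::vector<double> stage(N + 1);
  double total = 0.0;
  for (int j = 0; j < J; ++j) {
    double base = 0.0;
    for (int i = 0; i < N; ++i) base += logH(j, i);
    stage[0] = base;
    double cum = base, m = base;
    for (int k = 1; k <= N; ++k) {
      const int r = s[k - 1];
      cum += logE(j, r) - logH(j, r);
      stage[k] = cum;
      if (cum > m) m = cum;
    }
    double acc = 0.0;
    for (int k = 0; k <= N; ++k) acc += std::exp(stage[k] - m);
    total += m + std::log(acc) - std::log((double)(N + 1));
  }
  return total;
}

static std::vector<int> as_zero_based(const IntegerVector& s) {
  std::vector<int> out(s.size());
  for (int i = 0; i < s.size(); ++i) out[i] = s[i] - 1;
  return out;
}

// [[Rcpp::export]]
double ebm_loglik_cpp(const NumericMatrix& logE, const NumericMatrix& logH,
                      const IntegerVector& ordering) {
  return ll_ordering(logE, logH, as_zero_based(ordering));
}

// Best-improving pairwise-swap ascent from a start permutation.
// [[Rcpp::export]]
List ebm_greedy_cpp(const NumericMatrix& logE, const NumericMatrix& logH,
                    const IntegerVector& init) {
  std::vector<int> s = as_zero_based(init);
  const int N = (int)s.size();
  double best = ll_ordering(logE, logH, s);
  bool improved = true;
  while (improved && N > 1) {
    improved = false;
    int bi = -1, bj = -1;
    double best_cand = best;
    for (int i = 0; i < N - 1; ++i) {
      for (int j = i + 1; j < N; ++j) {
        std::swap(s[i], s[j]);
        double ll = ll_ordering(logE, logH, s);
        std::swap(s[i], s[j]);
        if (ll > best_cand) {
          best_cand = ll;
          bi = i; bj = j;
        }
      }
    }
    if (bi >= 0) {
      std::swap(s[bi], s[bj]);
      best = best_cand;
      improved = true;
    }
  }
  IntegerVector out(N);
  for (int i = 0; i < N; ++i) out[i] = s[i] + 1;
  return List::create(_["ordering"] = out, _["loglik"] = best);
}

// Metropolis chain over permutations: symmetric proposal swapping two
// distinct positions chosen uniformly; acceptance min(1, likelihood ratio)
// under a uniform prior over orderings. Uses R's RNG so set.seed() governs
// reproducibility. Returns post-burn-in samples, their log-likelihoods, the
// best ordering visited anywhere in the chain (including the start), and the
// acceptance rate.
// [[Rcpp::export]]
List ebm_mcmc_cpp(const NumericMatrix& logE, const NumericMatrix& logH,
                  const IntegerVector& init, const int n_iter,
                  const int burn_in) {
  std::vector<int> s = as_zero_based(init);
  const int N = (int)s.size();
  const int n_keep = n_iter - burn_in;
  double ll = ll_ordering(logE, logH, s);
  std::vector<int> map_s = s;
  double map_ll = ll;
  IntegerMatrix samples(n_keep, N);
  NumericVector sample_ll(n_keep);
  long accepted = 0;
  for (int t = 0; t < n_iter; ++t) {
    if (N > 1) {
      int a = (int)(unif_rand() * N); if (a >= N) a = N - 1;
      int b = a;
      while (b == a) { b = (int)(unif_rand() * N); if (b >= N) b = N - 1; }
      std::swap(s[a], s[b]);
      double ll_new = ll_ordering(logE, logH, s);
      if (ll_new >= ll || unif_rand() < std::exp(ll_new - ll)) {
        ll = ll_new;
        ++accepted;
        if (ll > map_ll) { map_ll = ll; map_s = s; }
      } else {
        std::swap(s[a], s[b]);
      }
    } else {
      ++accepted;
    }
    if (t >= burn_in) {
      const int row = t - burn_in;
      for (int i = 0; i < N; ++i) samples(row, i) = s[i] + 1;
      sample_ll[row] = ll;
    }
  }
  IntegerVector map_out(N);
  for (int i = 0; i < N; ++i) map_out[i] = map_s[i] + 1;
  return List::create(
    _["samples"] = samples,
    _["sample_loglik"] = sample_ll,
    _["map"] = map_out,
    _["map_loglik"] = map_ll,
    _["acceptance_rate"] = (double)accepted / (double)n_iter
  );
}

// Per-subject stage log-likelihoods (J x (N+1)) for a fixed ordering:
// column k+1 holds log prod_{i<=k} pE * prod_{i>k} pH for stage k.
// [[Rcpp::export]]
NumericMatrix ebm_stage_loglik_cpp(const NumericMatrix& logE,
                                   const NumericMatrix& logH,
                                   const IntegerVector& ordering) {
  std::vector<int> s = as_zero_based(ordering);
  const int J = logE.nrow();
  const int N = (int)s.size();
  NumericMatrix out(J, N + 1);
  for (int j = 0; j < J; ++j) {
    double base = 0.0;
    for (int i = 0; i < N; ++i) base += logH(j, i);
    out(j, 0) = base;
    double cum = base;
    for (int k = 1; k <= N; ++k) {
      const int r = s[k - 1];
      cum += logE(j, r) - logH(j, r);
      out(j, k) = cum;
    }
  }
  return out;
}

// Projected-EM inner loop for the two-component constrained mixture.
// The healthy component is clamped to [mu_lo, mu_hi] x [sig_lo, sig_hi]
// after every M-step (pass infinite bounds to disable), theta to
// [theta_lo, theta_hi], and sigma_d floored at sigma_d_min. Returns
// parameters, log-likelihood, iteration count and convergence flag.
// [[Rcpp::export]]
List ebm_em_cpp(const NumericVector& x,
                double mu_h, double sigma_h, double mu_d, double sigma_d,
                double theta,
                const double mu_lo, const double mu_hi,
                const double sig_lo, const double sig_hi,
                const double theta_lo, const double theta_hi,
                const double sigma_d_min,
                const double tol, const int max_iter) {
  const int n = x.size();
  const double tiny = std::numeric_limits<double>::min();
  const double log2pi_half = 0.5 * std::log(2.0 * M_PI);
  std::vector<double> r(n);
  double loglik = -std::numeric_limits<double>::infinity();
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    // E step and current log-likelihood
    double ll = 0.0;
    const double lsh = std::log(sigma_h), lsd = std::log(sigma_d);
    for (int i = 0; i < n; ++i) {
      const double zh = (x[i] - mu_h) / sigma_h;
      const double zd = (x[i] - mu_d) / sigma_d;
      const double fh = theta * std::exp(-0.5 * zh * zh - lsh - log2pi_half);
      const double fd = (1.0 - theta) * std::exp(-0.5 * zd * zd - lsd - log2pi_half);
      double denom = fh + fd;
      if (denom < tiny) denom = tiny;
      ll += std::log(denom);
      r[i] = fh / denom;
    }
    if (std::isfinite(ll) && iter > 1 && ll - loglik < tol) {
      loglik = std::max(ll, loglik);
      converged = true;
      break;
    }
    loglik = ll;
    // M step
    double wh = 0.0, sx = 0.0, sxd = 0.0;
    for (int i = 0; i < n; ++i) { wh += r[i]; sx += r[i] * x[i]; sxd += (1.0 - r[i]) * x[i]; }
    const double wd = n - wh;
    if (wh > 1e-12) {
      mu_h = sx / wh;
      double ss = 0.0;
      for (int i = 0; i < n; ++i) { const double d = x[i] - mu_h; ss += r[i] * d * d; }
      sigma_h = std::sqrt(ss / wh);
    }
    if (wd > 1e-12) {
      mu_d = sxd / wd;
      double ss = 0.0;
      for (int i = 0; i < n; ++i) { const double d = x[i] - mu_d; ss += (1.0 - r[i]) * d * d; }
      sigma_d = std::sqrt(ss / wd);
    }
    mu_h = std::min(std::max(mu_h, mu_lo), mu_hi);
    sigma_h = std::min(std::max(sigma_h, sig_lo), sig_hi);
    if (sigma_h < 1e-10) sigma_h = 1e-10;
    sigma_d = std::max(std::max(sigma_d, sigma_d_min), 1e-10);
    theta = std::min(std::max(wh / n, theta_lo), theta_hi);
  }
  if (iter > max_iter) iter = max_iter;
  return List::create(
    _["mu_h"] = mu_h, _["sigma_h"] = sigma_h,
    _["mu_d"] = mu_d, _["sigma_d"] = sigma_d,
    _["theta"] = theta, _["loglik"] = loglik,
    _["n_iter"] = iter, _["converged"] = converged
  );
}
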
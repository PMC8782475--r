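#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// scheme codes shared with R/chart-spec.R (scheme_code):
//   0 HWMA, 1 HHWMA (DHWMA = equal lambdas), 2 EWMA, 3 DEWMA, 4 CUSUM

// In-control variance multipliers of sigma_W^2 for the plotted statistic
// at t = 1..tmax. HWMA: lambda^2 then lambda^2 + (1-lambda)^2/(t-1).
// HHWMA family: (l1 l2)^2 + [A^2 + sum_{u=1}^{t-2} (A + B (H_{t-2} -
// H_{u-1}))^2] / (t-1)^2 with A = l1 + l2 - 2 l1 l2, B = (1-l1)(1-l2)
// and H_j the j-th harmonic number; the inner sum is carried
// incrementally through the running sums of H_{u-1} and H_{u-1}^2.
// EWMA: v_t = l^2 + (1-l)^2 v_{t-1}.
// DEWMA: l^4 sum_{i=0}^{t-1} (i+1)^2 (1-l)^{2i}.
// [[Rcpp::export]]
NumericVector variance_factors_cpp(int scheme, double l1, double l2,
                                   int tmax) {
  if (tmax < 1) stop("'tmax' must be >= 1");
  NumericVector f(tmax);
  if (scheme == 0) { // HWMA
    f[0] = l1 * l1;
    for (int t = 2; t <= tmax; ++t)
      f[t - 1] = l1 * l1 + (1.0 - l1) * (1.0 - l1) / (t - 1.0);
  } else if (scheme == 1) { // HHWMA / DHWMA
    const double p = l1 * l2;
    const double A = l1 + l2 - 2.0 * l1 * l2;
    const double B = (1.0 - l1) * (1.0 - l2);
    f[0] = p * p;
    if (tmax >= 2) f[1] = p * p + A * A;
    double Hharm = 0.0;      // harmonic number H_{t-2}
    double S0 = 0.0, S1 = 0.0, S2 = 0.0; // sums over H_{u-1}, u = 1..t-2
    for (int t = 3; t <= tmax; ++t) {
      Hharm += 1.0 / (t - 2.0);
      double Hu = Hharm - 1.0 / (t - 2.0); // H_{t-3}, the new u = t-2 term
      S0 += 1.0; S1 += Hu; S2 += Hu * Hu;
      double c = A + B * Hharm;
      double inner = S0 * c * c - 2.0 * c * B * S1 + B * B * S2;
      f[t - 1] = p * p + (A * A + inner) / ((t - 1.0) * (t - 1.0));
    }
  } else if (scheme == 2) { // EWMA
    double v = 0.0;
    for (int t = 1; t <= tmax; ++t) {
      v = l1 * l1 + (1.0 - l1) * (1.0 - l1) * v;
      f[t - 1] = v;
    }
  } else if (scheme == 3) { // DEWMA
    const double q = (1.0 - l1) * (1.0 - l1);
    double acc = 0.0, qi = 1.0;
    for (int t = 1; t <= tmax; ++t) {
      acc += (double)t * (double)t * qi;
      qi *= q;
      f[t - 1] = l1 * l1 * l1 * l1 * acc;
    }
  } else {
    stop("no time-varying variance factor for this scheme");
  }
  return f;
}

static inline double draw_one(int dist) {
  switch (dist) {
  case 0: return norm_rand();
  case 1: return R::rt(5.0);
  default: return R::rgamma(3.0, 1.0);
  }
}

// Zero-state run lengths for one chart configuration.
// Per replication: a fresh reference sample of size m is drawn in
// control and held fixed; test subgroups of size n (shifted by
// delta * sigma_f) stream in; W is the test rank sum against the fixed
// reference (no ties a.s. for continuous draws); the chart starts at
// mu_W and the first t with a strict limit violation is recorded.
// Returns the (possibly cap-censored) run lengths plus a censoring flag.
// [[Rcpp::export]]
List simulate_run_lengths_cpp(int scheme, double l1, double l2,
                              double limit, double k, int m, int n,
                              int dist, double delta, double sigma_f,
                              int reps, int maxrl) {
  if (m < 2 || n < 1) stop("need m >= 2 and n >= 1");
  if (reps < 1 || maxrl < 1) stop("need reps >= 1 and maxrl >= 1");
  const double mu_w = n * (m + n + 1) / 2.0;
  const double sigma_w = std::sqrt(m * (double)n * (m + n + 1) / 12.0);
  const double shift = delta * sigma_f;
  const double base = n * (n + 1) / 2.0;

  std::vector<double> hw; // half-widths per t
  double h = limit * sigma_w; // CUSUM decision interval
  if (scheme != 4) {
    NumericVector fac = variance_factors_cpp(scheme, l1, l2, maxrl);
    hw.resize(maxrl);
    for (int i = 0; i < maxrl; ++i)
      hw[i] = limit * sigma_w * std::sqrt(fac[i]);
  }

  std::vector<double> ref(m);
  std::vector<double> y(n);
  IntegerVector rl(reps);
  LogicalVector censored(reps);

  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < m; ++i) ref[i] = draw_one(dist);
    std::sort(ref.begin(), ref.end());

    double wsum = 0.0, hsum = 0.0;       // running sums of W and inner H
    double z = mu_w, z2 = mu_w;          // EWMA levels
    double cp = 0.0, cm = 0.0;           // CUSUM arms
    int out = maxrl;
    bool hit = false;

    for (int t = 1; t <= maxrl; ++t) {
      double W = base;
      for (int j = 0; j < n; ++j) {
        y[j] = draw_one(dist) + shift;
        W += std::lower_bound(ref.begin(), ref.end(), y[j]) - ref.begin();
      }
      double wbar = (t == 1) ? mu_w : wsum / (t - 1.0);
      bool sig = false;
      switch (scheme) {
      case 0: { // HWMA
        double stat = l1 * W + (1.0 - l1) * wbar;
        sig = std::fabs(stat - mu_w) > hw[t - 1];
        break;
      }
      case 1: { // HHWMA / DHWMA (l2 inner, l1 outer)
        double Ht = l2 * W + (1.0 - l2) * wbar;
        double hbar = (t == 1) ? mu_w : hsum / (t - 1.0);
        double stat = l1 * Ht + (1.0 - l1) * hbar;
        hsum += Ht;
        sig = std::fabs(stat - mu_w) > hw[t - 1];
        break;
      }
      case 2: { // EWMA
        z = l1 * W + (1.0 - l1) * z;
        sig = std::fabs(z - mu_w) > hw[t - 1];
        break;
      }
      case 3: { // DEWMA
        z = l1 * W + (1.0 - l1) * z;
        z2 = l1 * z + (1.0 - l1) * z2;
        sig = std::fabs(z2 - mu_w) > hw[t - 1];
        break;
      }
      default: { // CUSUM
        double d = W - mu_w;
        cp = std::max(0.0, cp + d - k);
        cm = std::max(0.0, cm - d - k);
        sig = (cp > h) || (cm > h);
        break;
      }
      }
      wsum += W;
      if (sig) { out = t; hit = true; break; }
    }
    rl[r] = out;
    censored[r] = !hit;
    if ((r & 0x3ff) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["rl"] = rl, _["censored"] = censored);
}
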
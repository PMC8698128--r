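// Hot loops of the von Mises kernel density machinery: leave-one-out
// cross-validation over a concentration grid and kernel-sum evaluation.
// Bessel-I0 normalizing constants are computed in R and passed in as logs.

#include <Rcpp.h>
using namespace Rcpp;

// Leave-one-out CV log-likelihood of the kernel density for each kappa.
// log_i0: log I0(kappa) for each candidate, from R's besselI.
// [[Rcpp::export]]
NumericVector loo_cv_loglik_cpp(NumericVector x, NumericVector kappas,
                                NumericVector log_i0) {
  const int n = x.size(), m = kappas.size();
  if (n < 2) stop("need at least 2 observations");
  // s[k][i] = sum_{j != i} exp(kappa_k * (cos(x_i - x_j) - 1))
  std::vector< std::vector<double> > s(m, std::vector<double>(n, 0.0));
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double cd = std::cos(x[i] - x[j]) - 1.0;  // in [-2, 0]
      for (int k = 0; k < m; ++k) {
        const double e = std::exp(kappas[k] * cd);
        s[k][i] += e;
        s[k][j] += e;
      }
    }
  }
  NumericVector out(m);
  const double l2pi = std::log(2.0 * M_PI);
  for (int k = 0; k < m; ++k) {
    double ll = 0.0;
    bool ok = true;
    for (int i = 0; i < n; ++i) {
      if (s[k][i] <= 0.0) { ok = false; break; }
      ll += std::log(s[k][i]) + kappas[k] - std::log((double)(n - 1)) -
            l2pi - log_i0[k];
    }
    out[k] = ok ? ll : R_NegInf;
  }
  return out;
}

// Kernel density evaluated at arbitrary angles: equal-weight von Mises
// mixture centred at the sample points.
// [[Rcpp::export]]
NumericVector kde_eval_cpp(NumericVector x, double kappa, double log_i0,
                           NumericVector at) {
  const int n = x.size(), m = at.size();
  const double lc = -std::log(2.0 * M_PI) - log_i0;
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      s += std::exp(kappa * (std::cos(at[j] - x[i]) - 1.0));
    }
    out[j] = s * std::exp(lc + kappa) / n;
  }
  return out;
}
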
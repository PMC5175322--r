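#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// log rising factorial d_(j) = d (d+1) ... (d+j-1), via lgamma differences
static inline double log_rf(double d, int j) {
  if (j == 0) return 0.0;
  return std::lgamma(d + j) - std::lgamma(d);
}

// log of Kummer's confluent hypergeometric function 1F1(a; b; z).
// For z < 0 the Kummer transformation F(a;b;z) = e^z F(b-a;b;-z) is applied
// first, so the series is summed over non-negative terms only. In this
// model's parameterisation a < b always holds after the transformation,
// hence every term is bounded by z^j / j! and the linear-space accumulation
// cannot overflow for |z| well below 700.
static double log_hyp1f1_scalar(double a, double b, double z) {
  if (b <= 0.0) stop("hyp1f1: second parameter must be positive");
  double shift = 0.0;
  if (z < 0.0) {
    shift = z;
    a = b - a;
    z = -z;
  }
  if (z == 0.0) return shift;
  double term = 1.0, sum = 1.0;
  const int cap = 100000;
  int j = 0;
  for (; j < cap; ++j) {
    term *= (a + j) * z / ((b + j) * (j + 1.0));
    sum += term;
    if (j > z && std::fabs(term) < 1e-16 * sum) break;
  }
  if (j >= cap)
    stop("hyp1f1: series did not converge after %d terms (a=%g, b=%g, z=%g)",
         cap, a, b, z);
  return shift + std::log(sum);
}

// [[Rcpp::export(name = ".log_hyp1f1_cpp")]]
NumericVector log_hyp1f1_cpp(NumericVector a, NumericVector b, NumericVector z) {
  R_xlen_t m = std::max(a.size(), std::max(b.size(), z.size()));
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i)
    out[i] = log_hyp1f1_scalar(a[i % a.size()], b[i % b.size()], z[i % z.size()]);
  return out;
}

// log p_{n,b} for b = 0..n under the stationary reversible-epimutation
// sampling distribution with genic selection:
//   p_{n,b} = C(n,b) F(beta+b; alpha+beta+n; 2*sigma) beta_(b) alpha_(n-b)
//             / [ F(beta; alpha+beta; 2*sigma) (alpha+beta)_(n) ]
static void log_p_vec(double alpha, double beta, double sigma, int n,
                      std::vector<double> &logp) {
  const double z = 2.0 * sigma;
  const double denom = log_hyp1f1_scalar(beta, alpha + beta, z)
    + log_rf(alpha + beta, n);
  for (int b = 0; b <= n; ++b) {
    double lf = (z == 0.0) ? 0.0
      : log_hyp1f1_scalar(beta + b, alpha + beta + n, z);
    logp[b] = ::Rf_lchoose((double) n, (double) b) + lf
      + log_rf(beta, b) + log_rf(alpha, n - b) - denom;
  }
}

// [[Rcpp::export(name = ".log_sampling_prob_cpp")]]
NumericVector log_sampling_prob_cpp(double alpha, double beta, double sigma,
                                    int n) {
  if (alpha <= 0.0 || beta <= 0.0) stop("alpha and beta must be positive");
  if (n < 1) stop("n must be >= 1");
  std::vector<double> logp(n + 1);
  log_p_vec(alpha, beta, sigma, n, logp);
  return NumericVector(logp.begin(), logp.end());
}

static inline double logsumexp(const std::vector<double> &x, int from, int to) {
  double m = R_NegInf;
  for (int i = from; i <= to; ++i) if (x[i] > m) m = x[i];
  if (!R_FINITE(m)) return m;
  double s = 0.0;
  for (int i = from; i <= to; ++i) s += std::exp(x[i] - m);
  return m + std::log(s);
}

// Multinomial log-likelihood of segregating-class counts d_{n,b}
// (b = 1..n-1) over a full grid of (alpha, r, sigma) values.
// Returns a vector indexed [ia + na*(ir + nr*is)].
// Classes with d = 0 contribute 0 even when q underflows; a class with
// d > 0 and q = 0 yields -Inf.
// [[Rcpp::export(name = ".grid_loglik_cpp")]]
NumericVector grid_loglik_cpp(NumericVector alpha, NumericVector r,
                              NumericVector sigma, NumericVector counts,
                              int n) {
  if (counts.size() != n - 1) stop("counts must have length n - 1");
  const R_xlen_t na = alpha.size(), nr = r.size(), ns = sigma.size();
  NumericVector out(na * nr * ns);
  std::vector<double> logp(n + 1);
  for (R_xlen_t is = 0; is < ns; ++is) {
    for (R_xlen_t ir = 0; ir < nr; ++ir) {
      for (R_xlen_t ia = 0; ia < na; ++ia) {
        const double a = alpha[ia], b = r[ir] * alpha[ia];
        log_p_vec(a, b, sigma[is], n, logp);
        const double log_pseg = logsumexp(logp, 1, n - 1);
        double ll = 0.0;
        if (!R_FINITE(log_pseg)) {
          ll = R_NegInf;
        } else {
          for (int k = 1; k <= n - 1; ++k) {
            if (counts[k - 1] > 0.0) {
              const double logq = logp[k] - log_pseg;
              if (!R_FINITE(logq)) { ll = R_NegInf; break; }
              ll += counts[k - 1] * logq;
            }
          }
        }
        out[ia + na * (ir + nr * is)] = ll;
      }
    }
  }
  return out;
}
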
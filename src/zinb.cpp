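// Fused evaluation of the mean ZINB/NB negative log-likelihood and its
// gradients wrt (mu, theta, pi). theta is per-feature; its lgamma/digamma
// terms are hoisted out of the cell loop. This is the innermost kernel of
// every training step.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List zinb_loss_grads_cpp(const NumericMatrix& x, const NumericMatrix& mu,
                         const NumericVector& theta,
                         Nullable<NumericMatrix> pi_) {
  const int n = x.nrow(), p = x.ncol();
  const bool has_pi = pi_.isNotNull();
  NumericMatrix pi = has_pi ? NumericMatrix(pi_) : NumericMatrix(0, 0);

  NumericMatrix dmu(n, p), dth(n, p);
  NumericMatrix dpi = has_pi ? NumericMatrix(n, p) : NumericMatrix(0, 0);
  double ll_sum = 0.0;

  for (int j = 0; j < p; ++j) {
    const double t = theta[j];
    const double lt = std::log(t);
    const double lgt = R::lgammafn(t);
    const double dgt = R::digamma(t);
    for (int i = 0; i < n; ++i) {
      const double xx = x(i, j);
      const double m = mu(i, j);
      const double tm = t + m;
      const double ltr = lt - std::log(tm);
      if (xx > 0.0) {
        double ll = R::lgammafn(xx + t) - lgt - R::lgammafn(xx + 1.0) +
                    t * ltr + xx * (std::log(m) - std::log(tm));
        dmu(i, j) = (xx + t) / tm - xx / m;
        dth(i, j) = -(R::digamma(xx + t) - dgt + ltr + 1.0 - (xx + t) / tm);
        if (has_pi) {
          const double q = 1.0 - pi(i, j);
          ll += std::log1p(-pi(i, j));
          dpi(i, j) = 1.0 / std::max(q, 1e-10);
        }
        ll_sum += ll;
      } else {
        const double nb0 = std::exp(t * ltr);
        const double p0 = has_pi ? pi(i, j) : 0.0;
        const double L0 = std::max(p0 + (1.0 - p0) * nb0, 1e-12);
        ll_sum += std::log(L0);
        const double dnb0 = -(1.0 - p0) / L0;
        dmu(i, j) = dnb0 * nb0 * (-t / tm);
        dth(i, j) = dnb0 * nb0 * (ltr + 1.0 - t / tm);
        if (has_pi) dpi(i, j) = -(1.0 - nb0) / L0;
      }
    }
  }
  const double sc = 1.0 / (double(n) * double(p));
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) {
      dmu(i, j) *= sc;
      dth(i, j) *= sc;
      if (has_pi) dpi(i, j) *= sc;
    }
  List out = List::create(_["loss"] = -ll_sum * sc,
                          _["dmu"] = dmu, _["dtheta"] = dth);
  if (has_pi) out["dpi"] = dpi;
  return out;
}
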
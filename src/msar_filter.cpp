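// Hamilton forward filter for the univariate (K = 1) two-state MSAR(1),
// with a hand-derived reverse-mode gradient through the recursion.
//
// Forward pass, per individual, t = 2..T:
//   m1 = gamma * z_t                       (state 1: A1 = B1 = 0)
//   m2 = A2 + B2 * y_{t-1} + gamma * z_t
//   f_s = N(y_t; m_s, sigma)               (scaled by max log-density)
//   p11 = logistic(eta_tilde_{it}),  p21 fixed
//   a_1 = xi1 * p11 + xi2 * p21,  a_2 = xi1 * (1 - p11) + xi2 * (1 - p21)
//   c_t = a_1 f_1 + a_2 f_2;  loglik += log c_t;  xi_s <- a_s f_s / c_t
//
// Backward pass: with adjoints bxi_s = d loglik_future / d xi_{s,t} and
// D = sum_s bxi_s xi_{s,t},
//   bar a_s     = (f_s / c_t) (1 + bxi_s - D)
//   bar log f_s = xi_{s,t}    (1 + bxi_s - D)
//   bar p11     = xi_{1,t-1} (bar a_1 - bar a_2)
//   bxi_{s',t-1} = sum_s P_{s's} bar a_s
// and bar log f_s feeds the density-parameter gradients analytically.
//
// When eta_tilde has a single column the predictor is treated as constant
// over time (time-invariant transitions): the stay probability is computed
// once per individual and the eta-gradient is returned as one value per
// individual.

#include <Rcpp.h>
using namespace Rcpp;

static inline double logistic_stable(double x) {
  double p;
  if (x >= 0.0) {
    p = 1.0 / (1.0 + std::exp(-x));
  } else {
    double e = std::exp(x);
    p = e / (1.0 + e);
  }
  // keep both transition branches alive so the mixture never degenerates
  const double eps = 1e-12;
  if (p < eps) p = eps;
  if (p > 1.0 - eps) p = 1.0 - eps;
  return p;
}

static inline double exp_cut(double dq) {
  // cut off below double precision to avoid denormal slowdowns
  return dq < -745.0 ? 0.0 : std::exp(dq);
}

// [[Rcpp::export]]
List msar_filter_cpp(NumericMatrix y, NumericMatrix z, NumericMatrix eta_tilde,
                     double A2, double B2, double gamma, double sigma,
                     double p21, bool want_grad, bool want_xi) {
  const int N = y.nrow(), T = y.ncol();
  const bool tinv = eta_tilde.ncol() == 1;  // time-invariant predictor
  const double s2 = sigma * sigma;
  const double inv2s2 = 0.5 / s2;
  const double inv_s2 = 1.0 / s2, inv_s = 1.0 / sigma;
  const double lconst = -0.5 * std::log(2.0 * M_PI) - std::log(sigma);

  double loglik = 0.0;
  double dA2 = 0.0, dB2 = 0.0, dgamma = 0.0, dsigma = 0.0;
  NumericMatrix d_eta;
  NumericMatrix xi_out;
  if (want_grad) d_eta = NumericMatrix(N, tinv ? 1 : T);
  if (want_xi) xi_out = NumericMatrix(N, T);

  std::vector<double> xi1(T), p11v(T), fr1(T), fr2(T);

  for (int i = 0; i < N; ++i) {
    xi1[0] = 1.0;
    double p11_const = tinv ? logistic_stable(eta_tilde(i, 0)) : 0.0;
    for (int t = 1; t < T; ++t) {
      const double yl = y(i, t - 1), yt = y(i, t), zt = z(i, t);
      const double m1 = gamma * zt;
      const double m2 = A2 + B2 * yl + gamma * zt;
      const double r1 = yt - m1, r2 = yt - m2;
      const double q1 = -r1 * r1 * inv2s2;  // log f_s = lconst + q_s
      const double q2 = -r2 * r2 * inv2s2;
      const double mx = (q1 > q2 ? q1 : q2) + lconst;
      double f1, f2;
      if (q1 >= q2) { f1 = 1.0; f2 = exp_cut(q2 - q1); }
      else          { f2 = 1.0; f1 = exp_cut(q1 - q2); }
      const double p11 = tinv ? p11_const : logistic_stable(eta_tilde(i, t));
      const double x1 = xi1[t - 1], x2 = 1.0 - x1;
      const double a1 = x1 * p11 + x2 * p21;
      const double a2 = x1 * (1.0 - p11) + x2 * (1.0 - p21);
      const double c = a1 * f1 + a2 * f2;
      if (!(c > 0.0) || !R_finite(std::log(c) + mx)) {
        // reject the parameter point (e.g. a divergent trajectory reached
        // sigma = Inf); the sampler treats -Inf as an ordinary rejection
        List bad = List::create(_["loglik"] = R_NegInf,
                                _["bad_i"] = i + 1, _["bad_t"] = t + 1);
        return bad;
      }
      loglik += std::log(c) + mx;
      xi1[t] = a1 * f1 / c;
      p11v[t] = p11;
      fr1[t] = f1 / c;
      fr2[t] = f2 / c;
      if (want_xi) xi_out(i, t) = xi1[t];
    }
    if (want_xi) xi_out(i, 0) = 1.0;

    if (want_grad) {
      double bx1 = 0.0, bx2 = 0.0;  // adjoints of (xi1, xi2) at time t
      double deta_i = 0.0;
      for (int t = T - 1; t >= 1; --t) {
        const double x1t = xi1[t], x2t = 1.0 - x1t;
        const double D = bx1 * x1t + bx2 * x2t;
        const double g1 = 1.0 + bx1 - D, g2 = 1.0 + bx2 - D;
        const double ba1 = fr1[t] * g1, ba2 = fr2[t] * g2;
        const double blf1 = x1t * g1, blf2 = x2t * g2;

        const double yl = y(i, t - 1), yt = y(i, t), zt = z(i, t);
        const double r1 = yt - gamma * zt;
        const double r2 = yt - (A2 + B2 * yl + gamma * zt);
        dA2    += blf2 * r2 * inv_s2;
        dB2    += blf2 * r2 * yl * inv_s2;
        dgamma += (blf1 * r1 + blf2 * r2) * zt * inv_s2;
        dsigma += blf1 * (r1 * r1 * inv_s2 - 1.0) * inv_s
                + blf2 * (r2 * r2 * inv_s2 - 1.0) * inv_s;

        const double p11 = p11v[t];
        const double x1p = xi1[t - 1];
        const double bp = x1p * (ba1 - ba2) * p11 * (1.0 - p11);
        if (tinv) deta_i += bp; else d_eta(i, t) = bp;
        const double nb1 = p11 * ba1 + (1.0 - p11) * ba2;
        const double nb2 = p21 * ba1 + (1.0 - p21) * ba2;
        bx1 = nb1; bx2 = nb2;
      }
      if (tinv) d_eta(i, 0) = deta_i;
    }
  }

  List out = List::create(_["loglik"] = loglik);
  if (want_grad) {
    out["dA2"] = dA2; out["dB2"] = dB2; out["dgamma"] = dgamma;
    out["dsigma"] = dsigma; out["d_eta"] = d_eta;
  }
  if (want_xi) out["xi1"] = xi_out;
  return out;
}
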
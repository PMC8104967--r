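#include <Rcpp.h>
using namespace Rcpp;

// Per-gene EM for the two-component gamma-normal dropout mixture.
// X: modeled genes x cells (cp10k_log values); initial parameter vectors
// per gene. Zeros are evaluated at eps (half the smallest positive value).
// Updates mirror the documented M-steps: posterior-weighted normal moments
// and a 3-step Newton solve of the gamma shape score equation.

// [[Rcpp::export(name = ".mix_em_cpp")]]
List mix_em_cpp(NumericMatrix X, NumericVector lambda0, NumericVector shape0,
                NumericVector rate0, NumericVector mu0, NumericVector sigma0,
                int max_iter, double tol, double eps) {
  const int G = X.nrow(), C = X.ncol();
  NumericVector lambda = clone(lambda0), shape = clone(shape0),
                rate = clone(rate0), mu = clone(mu0), sigma = clone(sigma0);
  LogicalVector converged(G);
  const double SQRT2PI = 2.5066282746310002;

  std::vector<double> xc(C), lx(C), gam(C);
  for (int g = 0; g < G; ++g) {
    for (int c = 0; c < C; ++c) {
      double x = X(g, c);
      xc[c] = x < eps ? eps : x;
      lx[c] = std::log(xc[c]);
    }
    double lam = lambda[g], a = shape[g], b = rate[g], m = mu[g], s = sigma[g];
    double ll_old = R_NegInf;
    bool conv = false;
    for (int it = 0; it < max_iter; ++it) {
      double cg = a * std::log(b) - R::lgammafn(a);
      double ll = 0.0, sum_g = 0.0, sum_gx = 0.0, sum_glx = 0.0;
      double sum_w = 0.0, sum_wx = 0.0;
      for (int c = 0; c < C; ++c) {
        double x = X(g, c);
        double lfg = (a - 1.0) * lx[c] - b * xc[c] + cg;
        double fg = std::exp(lfg);
        double z = (x - m) / s;
        double fn = std::exp(-0.5 * z * z) / (s * SQRT2PI);
        double num = lam * fg;
        double den = num + (1.0 - lam) * fn;
        if (den < 1e-300) den = 1e-300;
        double gm = num / den;
        gam[c] = gm;
        ll += std::log(den);
        sum_g += gm;
        sum_gx += gm * xc[c];
        sum_glx += gm * lx[c];
        sum_w += 1.0 - gm;
        sum_wx += (1.0 - gm) * x;
      }
      // M-step: mixing weight, normal moments
      lam = sum_g / C;
      if (lam < 1e-6) lam = 1e-6;
      if (lam > 1.0 - 1e-6) lam = 1.0 - 1e-6;
      double sw = sum_w < 1e-8 ? 1e-8 : sum_w;
      double m_new = sum_wx / sw;
      double ss = 0.0;
      for (int c = 0; c < C; ++c) {
        double d = X(g, c) - m_new;
        ss += (1.0 - gam[c]) * d * d;
      }
      m = m_new;
      s = std::sqrt(ss / sw);
      if (s < 1e-3) s = 1e-3;
      // gamma component via Newton on log a - digamma(a) = s_stat
      double T1 = sum_g < 1e-8 ? 1e-8 : sum_g;
      double T2 = sum_gx < 1e-12 ? 1e-12 : sum_gx;
      double s_stat = std::log(T2 / T1) - sum_glx / T1;
      if (s_stat < 1e-8) s_stat = 1e-8;
      for (int nw = 0; nw < 3; ++nw) {
        a -= (std::log(a) - R::digamma(a) - s_stat) /
             (1.0 / a - R::trigamma(a));
        if (a < 1e-3) a = 1e-3;
        if (a > 1e4) a = 1e4;
      }
      b = a * T1 / T2;
      if (b < 1e-6) b = 1e-6;
      if (b > 1e8) b = 1e8;

      if (R_finite(ll_old) && (ll - ll_old) < tol) { conv = true; break; }
      ll_old = ll;
    }
    lambda[g] = lam; shape[g] = a; rate[g] = b; mu[g] = m; sigma[g] = s;
    converged[g] = conv;
  }
  return List::create(_["lambda"] = lambda, _["shape"] = shape,
                      _["rate"] = rate, _["mu"] = mu, _["sigma"] = sigma,
                      _["converged"] = converged);
}
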
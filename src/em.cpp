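#include <Rcpp.h>
using namespace Rcpp;

// Solve log(a) - digamma(a) = s for the gamma shape by safeguarded Newton
// iterations. `init` (> 0) warm-starts the iteration; otherwise the
// Minka moment-style starting value is used.
static double solve_shape(double s, double init) {
  double a;
  if (init > 0.0 && R_finite(init)) {
    a = init;
  } else {
    a = (3.0 - s + std::sqrt((s - 3.0) * (s - 3.0) + 24.0 * s)) / (12.0 * s);
  }
  for (int i = 0; i < 100; ++i) {
    double f = std::log(a) - R::digamma(a) - s;
    double fp = 1.0 / a - R::trigamma(a);
    double step = f / fp;
    double anew = a - step;
    while (anew <= 0.0) { step *= 0.5; anew = a - step; }
    if (std::fabs(anew - a) < 1e-12 * a) { a = anew; break; }
    a = anew;
  }
  return a;
}

// [[Rcpp::export]]
double gamma_shape_mle(double s, double init) {
  return solve_shape(s, init);
}

// EM for a two-component gamma mixture on strictly positive data.
// Responsibilities are computed in log space; the M-step solves each
// component's weighted gamma ML with warm-started Newton iterations.
// Returns the parameter estimates, the per-iteration observed-data
// log-likelihood trace, and a collapse flag when one component's
// responsibility mass drops below `minMass` effective observations.
// [[Rcpp::export]]
List em_gamma_mix(NumericVector x, double lam, double a1, double b1,
                  double a2, double b2, double tol, int maxit,
                  double minMass) {
  int n = x.size();
  std::vector<double> lx(n);
  for (int i = 0; i < n; ++i) lx[i] = std::log(x[i]);
  NumericVector trace(maxit);
  double ll = R_NegInf;
  int it = 0;
  bool converged = false;
  for (it = 0; it < maxit; ++it) {
    double l1c = std::log(lam) - R::lgammafn(a1) - a1 * std::log(b1);
    double l2c = std::log1p(-lam) - R::lgammafn(a2) - a2 * std::log(b2);
    double llnew = 0.0;
    double sr = 0.0, s1x = 0.0, s1l = 0.0, s2x = 0.0, s2l = 0.0;
    for (int i = 0; i < n; ++i) {
      double ld1 = l1c + (a1 - 1.0) * lx[i] - x[i] / b1;
      double ld2 = l2c + (a2 - 1.0) * lx[i] - x[i] / b2;
      double m = ld1 > ld2 ? ld1 : ld2;
      double e1 = std::exp(ld1 - m), e2 = std::exp(ld2 - m);
      double tot = e1 + e2;
      llnew += m + std::log(tot);
      double r = e1 / tot;
      sr += r;
      s1x += r * x[i]; s1l += r * lx[i];
      s2x += (1.0 - r) * x[i]; s2l += (1.0 - r) * lx[i];
    }
    trace[it] = llnew;
    if (R_finite(ll) && std::fabs(llnew - ll) < tol * std::fabs(ll)) {
      ll = llnew; converged = true; ++it; break;
    }
    ll = llnew;
    double sr2 = (double)n - sr;
    if (sr < minMass || sr2 < minMass) {
      return List::create(_["collapsed"] = true,
                          _["which"] = sr < minMass ? 1 : 2,
                          _["iters"] = it + 1);
    }
    lam = sr / (double)n;
    double wm1 = s1x / sr, wl1 = s1l / sr;
    double wm2 = s2x / sr2, wl2 = s2l / sr2;
    a1 = solve_shape(std::log(wm1) - wl1, a1);
    b1 = wm1 / a1;
    a2 = solve_shape(std::log(wm2) - wl2, a2);
    b2 = wm2 / a2;
  }
  return List::create(_["collapsed"] = false, _["lam"] = lam,
                      _["a1"] = a1, _["b1"] = b1,
                      _["a2"] = a2, _["b2"] = b2,
                      _["loglik"] = ll, _["iters"] = it,
                      _["converged"] = converged,
                      _["trace"] = trace[Rcpp::Range(0, it - 1)]);
}

// Observed-data log-likelihood of the two-component gamma mixture and its
// gradient with respect to (lam, a1, b1, a2, b2), used by the quasi-Newton
// refinement after EM.
// [[Rcpp::export]]
List mix_loglik_grad(NumericVector x, double lam, double a1, double b1,
                     double a2, double b2) {
  int n = x.size();
  double l1c = std::log(lam) - R::lgammafn(a1) - a1 * std::log(b1);
  double l2c = std::log1p(-lam) - R::lgammafn(a2) - a2 * std::log(b2);
  double ll = 0.0, sr = 0.0, s1x = 0.0, s1l = 0.0, s2x = 0.0, s2l = 0.0;
  double lb1 = std::log(b1), lb2 = std::log(b2);
  for (int i = 0; i < n; ++i) {
    double lxi = std::log(x[i]);
    double ld1 = l1c + (a1 - 1.0) * lxi - x[i] / b1;
    double ld2 = l2c + (a2 - 1.0) * lxi - x[i] / b2;
    double m = ld1 > ld2 ? ld1 : ld2;
    double e1 = std::exp(ld1 - m), e2 = std::exp(ld2 - m);
    double tot = e1 + e2;
    ll += m + std::log(tot);
    double r = e1 / tot;
    sr += r;
    s1x += r * x[i]; s1l += r * lxi;
    s2x += (1.0 - r) * x[i]; s2l += (1.0 - r) * lxi;
  }
  double sr2 = (double)n - sr;
  double dlam = sr / lam - sr2 / (1.0 - lam);
  double da1 = s1l - sr * (lb1 + R::digamma(a1));
  double db1 = s1x / (b1 * b1) - sr * a1 / b1;
  double da2 = s2l - sr2 * (lb2 + R::digamma(a2));
  double db2 = s2x / (b2 * b2) - sr2 * a2 / b2;
  return List::create(_["loglik"] = ll,
                      _["grad"] = NumericVector::create(dlam, da1, db1,
                                                        da2, db2));
}
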
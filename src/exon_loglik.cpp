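#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Integrated per-exon log-likelihood for the measurement-error
// proportional-hazards model.  For patient k with inclusion/skipping
// junction counts (ic_k, sc_k), follow-up (t_k, delta_k) and a fixed
// cumulative baseline hazard, the marginal likelihood integrates the
// proportional-hazards density against the binomial read model and the
// prior on the latent inclusion level psi:
//
//   L_k(beta) = int [ lam0(t_k)^delta exp(delta * beta * (psi - c))
//                     * exp(-Lam0(t_k) e^{beta (psi - c)}) ]
//               * Binom(ic_k | n_k, f(psi)) * pi(psi) dpsi
//
// evaluated by fixed Gauss-Legendre quadrature on [0, 1], entirely in
// log space.  The centring constant c (a cohort-level summary of the
// point PSI estimates) only rescales the baseline and leaves the null
// model (beta = 0) unchanged.

static double row_lse(const std::vector<double>& v) {
  double mx = R_NegInf;
  for (double x : v) if (x > mx) mx = x;
  if (!R_finite(mx)) return mx;
  double s = 0.0;
  for (double x : v) s += std::exp(x - mx);
  return mx + std::log(s);
}

// constant (beta-independent) part of the integrand matrix:
// logWPrior_i + lchoose(n_k, ic_k) + ic_k log f_i + sc_k log(1 - f_i)
//   + delta_k * logHaz_k
static void build_const(const NumericVector& ic, const NumericVector& sc,
                        const NumericVector& delta, const NumericVector& logHaz,
                        const NumericVector& logf, const NumericVector& log1mf,
                        const NumericVector& logWPrior,
                        std::vector<double>& C) {
  const int n = ic.size(), m = logf.size();
  C.resize((size_t)n * m);
  for (int k = 0; k < n; ++k) {
    const double lch = Rf_lchoose(ic[k] + sc[k], ic[k]);
    const double ev = delta[k] > 0.5 ? logHaz[k] : 0.0;
    const double base = lch + ev;
    double* row = &C[(size_t)k * m];
    for (int i = 0; i < m; ++i)
      row[i] = base + logWPrior[i] + ic[k] * logf[i] + sc[k] * log1mf[i];
  }
}

static double loglik_at(double beta, const std::vector<double>& C,
                        const NumericVector& delta, const NumericVector& cumHaz,
                        const NumericVector& psiCov) {
  const int n = delta.size(), m = psiCov.size();
  std::vector<double> bp(m), ebp(m), v(m);
  for (int i = 0; i < m; ++i) {
    bp[i] = beta * psiCov[i];
    ebp[i] = std::exp(bp[i]);
  }
  double ll = 0.0;
  for (int k = 0; k < n; ++k) {
    const double* row = &C[(size_t)k * m];
    const bool ev = delta[k] > 0.5;
    const double ch = cumHaz[k];
    for (int i = 0; i < m; ++i) {
      double x = row[i] - ch * ebp[i];
      if (ev) x += bp[i];
      v[i] = x;
    }
    ll += row_lse(v);
  }
  return ll;
}

// [[Rcpp::export(name = ".cppExonLoglik")]]
double cpp_exon_loglik(double beta, NumericVector ic, NumericVector sc,
                       NumericVector delta, NumericVector logHaz,
                       NumericVector cumHaz, NumericVector psiCov,
                       NumericVector logf, NumericVector log1mf,
                       NumericVector logWPrior) {
  std::vector<double> C;
  build_const(ic, sc, delta, logHaz, logf, log1mf, logWPrior, C);
  return loglik_at(beta, C, delta, cumHaz, psiCov);
}

// Brent's method (golden section + parabolic interpolation) minimising
// the negated log-likelihood over a bounded interval.
template <class F>
static double brent_min(F g, double a, double b, double tol, int maxit,
                        double& fmin, bool& converged) {
  const double gold = 0.3819660112501051;
  double x, w, v, fx, fw, fv, d = 0.0, e = 0.0;
  x = w = v = a + gold * (b - a);
  fx = fw = fv = g(x);
  converged = false;
  for (int iter = 0; iter < maxit; ++iter) {
    const double xm = 0.5 * (a + b);
    const double tol1 = tol * std::fabs(x) + 1e-10;
    const double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) { converged = true; break; }
    bool golden = true;
    if (std::fabs(e) > tol1) {
      const double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      const double etemp = e;
      e = d;
      if (!(std::fabs(p) >= std::fabs(0.5 * q * etemp) ||
            p <= q * (a - x) || p >= q * (b - x))) {
        d = p / q;
        const double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x ? tol1 : -tol1);
        golden = false;
      }
    }
    if (golden) {
      e = (x >= xm ? a - x : b - x);
      d = gold * e;
    }
    const double u = (std::fabs(d) >= tol1) ? x + d
                                            : x + (d > 0.0 ? tol1 : -tol1);
    const double fu = g(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  fmin = fx;
  return x;
}

// Full-likelihood fit with the baseline hazard profiled out.
// Patients must be supplied sorted by increasing follow-up time.
// Given risk weights w_k (posterior expectations of exp(beta*psi_k)),
// the profile (Breslow) baseline has increment d_g / sum_{risk set} w_k
// at each distinct event time; at beta = 0 the weights are 1 and the
// profile baseline is exactly the Nelson-Aalen estimator, so the null
// model coincides with the plug-in null.  The alternative alternates
// Brent maximization over beta (baseline fixed) with an EM baseline
// update, a monotone-ascent scheme for the joint maximum.
struct Baseline {
  std::vector<double> cumHaz, logHaz;  // per patient (sorted order)
};

static Baseline breslow(const std::vector<double>& w,
                        const NumericVector& time,
                        const NumericVector& delta) {
  const int n = time.size();
  Baseline b;
  b.cumHaz.assign(n, 0.0);
  b.logHaz.assign(n, 0.0);
  std::vector<double> suffix(n + 1, 0.0);
  for (int k = n - 1; k >= 0; --k) suffix[k] = suffix[k + 1] + w[k];
  double ch = 0.0;
  int g = 0;
  while (g < n) {
    int h = g;
    int d = 0;
    while (h < n && time[h] == time[g]) { d += (delta[h] > 0.5); ++h; }
    double jump = 0.0;
    if (d > 0) jump = d / suffix[g];
    ch += jump;
    const double lj = (d > 0) ? std::log(jump) : R_NegInf;
    for (int k = g; k < h; ++k) {
      b.cumHaz[k] = ch;
      b.logHaz[k] = lj;
    }
    g = h;
  }
  return b;
}

// loglik with per-patient event-term offset delta_k * logHaz_k kept
// outside the C matrix (it changes when the baseline is re-profiled).
// Nodes whose constant part lies far enough below the per-patient
// maximum that they cannot come within exp(-45) of the integral -- even
// after the largest possible swing of the beta-dependent terms across
// nodes -- are skipped.
static double loglik_prof(double beta, const std::vector<double>& C,
                          const std::vector<double>& Cmax,
                          const NumericVector& delta,
                          const Baseline& b, const NumericVector& psi,
                          std::vector<double>* postW = nullptr) {
  const int n = delta.size(), m = psi.size();
  std::vector<double> bp(m), ebp(m), v(m);
  double ebpMin = R_PosInf, ebpMax = R_NegInf;
  for (int i = 0; i < m; ++i) {
    bp[i] = beta * psi[i];
    ebp[i] = std::exp(bp[i]);
    if (ebp[i] < ebpMin) ebpMin = ebp[i];
    if (ebp[i] > ebpMax) ebpMax = ebp[i];
  }
  const double bpSpan = std::fabs(beta) * std::fabs(psi[m - 1] - psi[0]);
  if (postW) postW->assign(n, 1.0);
  std::vector<double> ve(m);
  double ll = 0.0;
  for (int k = 0; k < n; ++k) {
    const double* row = &C[(size_t)k * m];
    const bool ev = delta[k] > 0.5;
    const double ch = b.cumHaz[k];
    const double swing = bpSpan + ch * (ebpMax - ebpMin);
    const double thr = Cmax[k] - 45.0 - swing;
    int used = 0;
    double mx = R_NegInf;
    for (int i = 0; i < m; ++i) {
      if (row[i] < thr) continue;
      double x = row[i] - ch * ebp[i];
      if (ev) x += bp[i];
      v[used] = x;
      ve[used] = ebp[i];
      if (x > mx) mx = x;
      ++used;
    }
    double s = 0.0, sw = 0.0;
    for (int i = 0; i < used; ++i) {
      const double e = std::exp(v[i] - mx);
      s += e;
      sw += e * ve[i];
    }
    ll += mx + std::log(s);
    if (ev) ll += b.logHaz[k];
    if (postW) (*postW)[k] = sw / s;
  }
  return ll;
}

// [[Rcpp::export(name = ".cppFitExonProfile")]]
List cpp_fit_exon_profile(NumericVector ic, NumericVector sc,
                          NumericVector delta, NumericVector time,
                          NumericVector psi, NumericVector logf,
                          NumericVector log1mf, NumericVector logWPrior,
                          double lower, double upper, double tol,
                          int maxIter, int maxInner) {
  const int n = ic.size();
  const int m = psi.size();
  std::vector<double> C;
  {  // constant part without the event-term offset
    NumericVector zeroHaz(n, 0.0), noEv(n, 0.0);
    build_const(ic, sc, noEv, zeroHaz, logf, log1mf, logWPrior, C);
  }
  std::vector<double> Cmax(n, R_NegInf);
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < m; ++i)
      if (C[(size_t)k * m + i] > Cmax[k]) Cmax[k] = C[(size_t)k * m + i];
  std::vector<double> ones(n, 1.0);
  const Baseline bNull = breslow(ones, time, delta);  // Nelson-Aalen
  const double llNull = loglik_prof(0.0, C, Cmax, delta, bNull, psi);

  // profile log-likelihood: for fixed beta, iterate the EM baseline
  // self-consistency (Breslow increments with posterior-expected
  // relative hazards) to convergence.  Warm-started across Brent
  // evaluations; monotone ascent in the inner loop; iteration stops as
  // soon as the refreshed baseline is numerically unchanged.
  Baseline bCur = bNull;
  std::vector<double> postW;
  auto baseClose = [&](const Baseline& a, const Baseline& b2) {
    for (size_t k = 0; k < a.cumHaz.size(); ++k)
      if (std::fabs(a.cumHaz[k] - b2.cumHaz[k]) >
          1e-10 * (1.0 + std::fabs(a.cumHaz[k]))) return false;
    return true;
  };
  auto profile_ll = [&](double beta) {
    Baseline b = bCur;
    double ll = loglik_prof(beta, C, Cmax, delta, b, psi, &postW);
    for (int it = 0; it < maxInner; ++it) {
      Baseline bNew = breslow(postW, time, delta);
      if (baseClose(b, bNew)) break;
      const double llNew = loglik_prof(beta, C, Cmax, delta, bNew, psi,
                                       &postW);
      b = bNew;
      const bool done =
        std::fabs(llNew - ll) < 1e-9 * (1.0 + std::fabs(ll));
      ll = llNew;
      if (done) break;
    }
    bCur = b;
    return ll;
  };

  double fmin;
  bool conv;
  auto g = [&](double x) { return -profile_ll(x); };
  double beta = brent_min(g, lower, upper, tol, maxIter, fmin, conv);
  double llAlt = -fmin;
  std::string flag = "ok";
  if (!R_finite(llAlt)) flag = "nonfinite";
  else if (!conv) flag = "noconv";
  else if (beta - lower < 1e-3 * (upper - lower) ||
           upper - beta < 1e-3 * (upper - lower)) flag = "boundary";
  if (llAlt < llNull) { beta = 0.0; llAlt = llNull; }
  return List::create(_["beta"] = beta, _["logLikAlt"] = llAlt,
                      _["logLikNull"] = llNull, _["flag"] = flag);
}

// [[Rcpp::export(name = ".cppFitExon")]]
List cpp_fit_exon(NumericVector ic, NumericVector sc, NumericVector delta,
                  NumericVector logHaz, NumericVector cumHaz,
                  NumericVector psiCov, NumericVector logf,
                  NumericVector log1mf, NumericVector logWPrior,
                  double lower, double upper, double tol, int maxIter) {
  std::vector<double> C;
  build_const(ic, sc, delta, logHaz, logf, log1mf, logWPrior, C);
  const double llNull = loglik_at(0.0, C, delta, cumHaz, psiCov);
  double beta = 0.0, llAlt = llNull;
  std::string flag = "ok";
  if (upper > lower) {
    double fmin;
    bool conv;
    auto g = [&](double b) { return -loglik_at(b, C, delta, cumHaz, psiCov); };
    beta = brent_min(g, lower, upper, tol, maxIter, fmin, conv);
    llAlt = -fmin;
    if (!R_finite(llAlt)) flag = "nonfinite";
    else if (!conv) flag = "noconv";
    else if (beta - lower < 1e-3 * (upper - lower) ||
             upper - beta < 1e-3 * (upper - lower)) flag = "boundary";
    if (llAlt < llNull) { beta = 0.0; llAlt = llNull; }
  }
  return List::create(_["beta"] = beta, _["logLikAlt"] = llAlt,
                      _["logLikNull"] = llNull, _["flag"] = flag);
}
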
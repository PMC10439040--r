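#include <Rcpp.h>
#include "wdm.h"
#include "hull.h"
#include "internal.h"
#include <cmath>
#include <cfloat>

using namespace Rcpp;

namespace diffsamp {

void make_nodes(double mu_nu, double s_nu, double mu_w, double s_w, bool upper,
                const std::vector<double> &ghx, const std::vector<double> &ghw,
                const std::vector<double> &glx01, const std::vector<double> &glw01,
                std::vector<double> &nu, std::vector<double> &nuW,
                std::vector<double> &ww, std::vector<double> &wW) {
  const double SQRT2 = 1.4142135623730951, SQRTPI = 1.7724538509055159;
  nu.clear(); nuW.clear(); ww.clear(); wW.clear();
  if (s_nu > 0.0) {
    for (size_t i = 0; i < ghx.size(); ++i) {
      nu.push_back(mu_nu + SQRT2 * s_nu * ghx[i]);
      nuW.push_back(ghw[i] / SQRTPI);
    }
  } else { nu.push_back(mu_nu); nuW.push_back(1.0); }
  if (s_w > 0.0) {
    for (size_t j = 0; j < glx01.size(); ++j) {
      ww.push_back((mu_w - s_w / 2.0) + s_w * glx01[j]);
      wW.push_back(glw01[j]);
    }
  } else { ww.push_back(mu_w); wW.push_back(1.0); }
  if (upper) {  // reflection: upper-boundary quantities at (-v, 1-w)
    for (size_t i = 0; i < nu.size(); ++i) nu[i] = -nu[i];
    for (size_t j = 0; j < ww.size(); ++j) ww[j] = 1.0 - ww[j];
  }
}

double mixed_cdf_nodes(double t, double a, const std::vector<double> &nu,
                       const std::vector<double> &nuW,
                       const std::vector<double> &ww,
                       const std::vector<double> &wW, double eps) {
  if (!(t > 0.0)) return 0.0;
  double acc = 0.0;
  for (size_t i = 0; i < nu.size(); ++i)
    for (size_t j = 0; j < ww.size(); ++j)
      acc += nuW[i] * wW[j] * wdm::cdf(t, a, nu[i], ww[j], eps);
  return acc;
}

double mixed_mass_nodes(double bound, double a, const std::vector<double> &nu,
                        const std::vector<double> &nuW,
                        const std::vector<double> &ww,
                        const std::vector<double> &wW, double eps) {
  if (R_finite(bound)) return mixed_cdf_nodes(bound, a, nu, nuW, ww, wW, eps);
  double acc = 0.0;
  for (size_t i = 0; i < nu.size(); ++i)
    for (size_t j = 0; j < ww.size(); ++j)
      acc += nuW[i] * wW[j] * wdm::prob_lower(a, nu[i], ww[j]);
  return acc;
}

double mixed_density_nodes(double t, double a, const std::vector<double> &nu,
                           const std::vector<double> &nuW,
                           const std::vector<double> &ww,
                           const std::vector<double> &wW, double eps) {
  double acc = 0.0;
  for (size_t i = 0; i < nu.size(); ++i)
    for (size_t j = 0; j < ww.size(); ++j)
      acc += nuW[i] * wW[j] * wdm::density(t, a, nu[i], ww[j], eps);
  return acc;
}

// -------------------------------------------------------------------------
// inverse transform sampling: bisection on the defective CDF (lower-boundary
// parametrization; caller reflects).  utarget in (0, F(bound)).
// -------------------------------------------------------------------------
double its_bisect(double utarget, double a, double v, double w, double bound,
                  double eps) {
  double hi;
  if (R_finite(bound)) hi = bound;
  else {
    hi = a * a / (1.0 + std::fabs(v));
    int g = 0;
    while (wdm::cdf(hi, a, v, w, eps) < utarget) {
      hi *= 2.0;
      if (++g > 200) Rcpp::stop("ITS bracket search failed");
    }
  }
  double lo = 0.0;
  for (int it = 0; it < 200 && (hi - lo) > 1e-10; ++it) {
    double mid = 0.5 * (lo + hi);
    if (wdm::cdf(mid, a, v, w, eps) < utarget) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// -------------------------------------------------------------------------
// rejection sampling, symmetric core (w = 1/2).
// Normalized diffusion time u = t / a_sub^2 has density prop. to
// exp(-lam*u) * f0(u), lam = (v*a_sub)^2/2, where f0 is the drift-free
// both-boundary density at unit separation:
//   f0(u) = (2 pi u^3)^{-1/2} sum_j (-1)^j (2j+1) exp(-(2j+1)^2/(8u))
//         = 2 pi       sum_j (-1)^j (2j+1) exp(-(2j+1)^2 pi^2 u / 2)
// Proposals: truncated inverse Gaussian / scaled-inverse-chi-square below
// ubar, shifted exponential above; alternating-series accept tests.
// -------------------------------------------------------------------------

static const double RS_UBAR = 0.64;

// one-sided standard normal tail draw y >= c0 (Robert's method for large c0)
static double rnorm_tail(double c0) {
  if (c0 < 1.0) {
    for (int g = 0; g < 100000; ++g) {
      double y = std::fabs(norm_rand());
      if (y >= c0) return y;
    }
  }
  double alpha = 0.5 * (c0 + std::sqrt(c0 * c0 + 4.0));
  for (int g = 0; g < 100000; ++g) {
    double y = c0 + exp_rand() / alpha;
    double rho = std::exp(-0.5 * (y - alpha) * (y - alpha));
    if (unif_rand() <= rho) return y;
  }
  Rcpp::stop("truncated-normal tail sampler failed");
}

// inverse Gaussian(mean m, shape lam_ig) draw (Michael-Schucany-Haas)
static double rinvgauss(double m, double lam_ig) {
  double y = norm_rand(); y *= y;
  double x = m + m * m * y / (2.0 * lam_ig)
           - (m / (2.0 * lam_ig))
             * std::sqrt(4.0 * m * lam_ig * y + m * m * y * y);
  if (x <= 0.0) x = DBL_MIN;
  return (unif_rand() <= m / (m + x)) ? x : m * m / x;
}

// alternating-series acceptance, short-time representation:
// accept z <= sum_j (-1)^j (2j+1) exp(-j(j+1)/(2u))
static bool accept_short(double z, double u) {
  double S = 1.0;                   // j = 0 partial sum: upper bound
  if (z > S) return false;
  for (int j = 1; j <= 1000; ++j) {
    double term = (2.0 * j + 1.0) * std::exp(-j * (j + 1.0) / (2.0 * u));
    if (j % 2 == 1) { S -= term; if (z <= S) return true; }
    else            { S += term; if (z >  S) return false; }
    if (term < 1e-17) return z <= S;
  }
  return z <= S;
}

// long-time representation: accept z <= sum_j (-1)^j (2j+1) exp(-2j(j+1)pi^2 u)
static bool accept_long(double z, double u) {
  double S = 1.0;
  if (z > S) return false;
  const double PISQ = M_PI * M_PI;
  for (int j = 1; j <= 1000; ++j) {
    double term = (2.0 * j + 1.0) * std::exp(-2.0 * j * (j + 1.0) * PISQ * u);
    if (j % 2 == 1) { S -= term; if (z <= S) return true; }
    else            { S += term; if (z >  S) return false; }
    if (term < 1e-17) return z <= S;
  }
  return z <= S;
}

// log of Phi-based mass of the truncated-IG short proposal (level 1/2, drift mu)
static double short_mass_ig(double mu) {
  double su = std::sqrt(RS_UBAR);
  double l1 = R::pnorm((mu * RS_UBAR - 0.5) / su, 0.0, 1.0, 1, 1);
  double l2 = mu + R::pnorm(-(mu * RS_UBAR + 0.5) / su, 0.0, 1.0, 1, 1);
  double mx = std::max(l1, l2);
  return std::log(2.0) - mu / 2.0 + mx
       + std::log(std::exp(l1 - mx) + std::exp(l2 - mx));
}

// normalized symmetric-core draw of u; caller converts t = a_sub^2 * u
double rs_sample_u(double lam) {
  double mu = std::sqrt(2.0 * lam);         // |v| * a_sub
  bool use_ig = (mu >= 0.4);
  double logMs, Ml;
  if (use_ig) logMs = short_mass_ig(mu);
  else logMs = std::log(4.0 * R::pnorm(-0.5 / std::sqrt(RS_UBAR), 0, 1, 1, 0));
  double rate = M_PI * M_PI / 2.0 + lam;
  Ml = 2.0 * M_PI * std::exp(-rate * RS_UBAR) / rate;
  double Ms = std::exp(logMs);
  double pshort = Ms / (Ms + Ml);
  for (long g = 0; g < 1000000L; ++g) {
    double u;
    if (unif_rand() < pshort) {
      if (use_ig) {
        int tries = 0;
        do {
          u = rinvgauss(1.0 / (2.0 * mu), 0.25);
          if (++tries > 100000) Rcpp::stop("RS short-proposal truncation failed");
        } while (u > RS_UBAR);
        if (!accept_short(unif_rand(), u)) continue;
      } else {
        double y = rnorm_tail(0.5 / std::sqrt(RS_UBAR));
        u = 1.0 / (4.0 * y * y);
        double z = unif_rand() * std::exp(lam * u);  // fold exp(-lam u) weight
        if (!accept_short(z, u)) continue;
      }
    } else {
      u = RS_UBAR + exp_rand() / rate;
      if (!accept_long(unif_rand(), u)) continue;
    }
    return u;
  }
  Rcpp::stop("rejection sampler exceeded iteration guard");
}

// full RS draw for arbitrary w via nested symmetric exits (strong Markov):
// from position x the process first leaves [x-d, x+d], d = min(x, a-x);
// that exit is a symmetric two-boundary problem with separation 2d.
void rs_draw(double a, double v, double w, double &t, bool &upper) {
  double x = a * w;
  t = 0.0;
  for (int stage = 0; stage < 10000; ++stage) {
    double d = std::min(x, a - x);
    double asub = 2.0 * d;
    double lam = (v * asub) * (v * asub) / 2.0;
    double u = rs_sample_u(lam);
    t += asub * asub * u;
    double pup = 1.0 / (1.0 + std::exp(-v * asub));
    bool up = (unif_rand() < pup);
    if (x <= a - x) {            // lower exit lands exactly on 0
      if (!up) { upper = false; return; }
      x = 2.0 * x;
      if (x >= a) { upper = true; return; }
    } else {                     // upper exit lands exactly on a
      if (up) { upper = true; return; }
      x = 2.0 * x - a;
      if (x <= 0.0) { upper = false; return; }
    }
  }
  Rcpp::stop("RS stage recursion failed to terminate");
}

// boundary-conditional, truncated RS with ITS escape for tight bounds
double rs_conditional(double a, double v, double w, bool upper, double bound,
                      double eps) {
  double va = upper ? -v : v;
  double wa = upper ? 1.0 - w : w;
  if (R_finite(bound)) {
    double pb = wdm::prob_lower(a, va, wa);
    double fb = wdm::cdf(bound, a, va, wa, eps);
    if (pb <= 0.0 || fb / std::max(pb, 1e-300) < 0.01) {
      double u = unif_rand() * fb;
      return its_bisect(u, a, va, wa, bound, eps);
    }
  }
  for (long g = 0; g < 1000000L; ++g) {
    double t; bool up;
    rs_draw(a, v, w, t, up);
    if (up == upper && (!R_finite(bound) || t <= bound)) return t;
  }
  Rcpp::stop("RS conditional resampling exceeded iteration guard");
}

double start_alpha(double a, double v, double w, bool upper, double bound) {
  double wt = upper ? 1.0 - w : w;
  double tg = (a * wt) * (a * wt) / 3.0 + 1e-3;
  if (R_finite(bound)) tg = std::min(tg, 0.5 * bound);
  return std::log(std::max(tg, 1e-4));
}

} // namespace diffsamp

using namespace diffsamp;

// ===========================================================================
// Exported kernel evaluators (vectorized over t)
// ===========================================================================

static inline void reflect(double &v, double &w, bool upper) {
  if (upper) { v = -v; w = 1.0 - w; }
}

// [[Rcpp::export]]
NumericVector cpp_fpt_density(NumericVector t, double a, double v, double w,
                              bool upper, double eps) {
  reflect(v, w, upper);
  NumericVector out(t.size());
  for (R_xlen_t i = 0; i < t.size(); ++i)
    out[i] = wdm::density(t[i], a, v, w, eps);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fpt_logdensity(NumericVector t, double a, double v, double w,
                                 bool upper, double eps) {
  reflect(v, w, upper);
  NumericVector out(t.size());
  for (R_xlen_t i = 0; i < t.size(); ++i)
    out[i] = wdm::log_density(t[i], a, v, w, eps);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fpt_tderiv(NumericVector t, double a, double v, double w,
                             bool upper, double eps) {
  reflect(v, w, upper);
  NumericVector out(t.size());
  for (R_xlen_t i = 0; i < t.size(); ++i)
    out[i] = wdm::density_tderiv(t[i], a, v, w, eps);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fpt_ratio(NumericVector t, double a, double v, double w,
                            bool upper, double eps) {
  reflect(v, w, upper);
  NumericVector out(t.size());
  for (R_xlen_t i = 0; i < t.size(); ++i)
    out[i] = wdm::density_ratio(t[i], a, v, w, eps);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fpt_cdf(NumericVector t, double a, double v, double w,
                          bool upper, double eps) {
  reflect(v, w, upper);
  NumericVector out(t.size());
  for (R_xlen_t i = 0; i < t.size(); ++i)
    out[i] = wdm::cdf(t[i], a, v, w, eps);
  return out;
}

// [[Rcpp::export]]
double cpp_prob_upper(double a, double v, double w) {
  return wdm::prob_upper(a, v, w);
}

// ===========================================================================
// Mixed (marginal) quantities given quadrature nodes
// ===========================================================================

static void nodes_from_r(double mu_nu, double s_nu, double mu_w, double s_w,
                         bool upper, NumericVector ghx, NumericVector ghw,
                         NumericVector glx01, NumericVector glw01,
                         std::vector<double> &nu, std::vector<double> &nuW,
                         std::vector<double> &ww, std::vector<double> &wW) {
  std::vector<double> gx(ghx.begin(), ghx.end()), gw(ghw.begin(), ghw.end());
  std::vector<double> lx(glx01.begin(), glx01.end()), lw(glw01.begin(), glw01.end());
  make_nodes(mu_nu, s_nu, mu_w, s_w, upper, gx, gw, lx, lw, nu, nuW, ww, wW);
}

// [[Rcpp::export]]
NumericVector cpp_mixed_density(NumericVector t, double a, double mu_nu,
                                double s_nu, double mu_w, double s_w,
                                bool upper, double eps, NumericVector ghx,
                                NumericVector ghw, NumericVector glx01,
                                NumericVector glw01) {
  std::vector<double> nu, nuW, ww, wW;
  nodes_from_r(mu_nu, s_nu, mu_w, s_w, upper, ghx, ghw, glx01, glw01,
               nu, nuW, ww, wW);
  NumericVector out(t.size());
  for (R_xlen_t i = 0; i < t.size(); ++i)
    out[i] = mixed_density_nodes(t[i], a, nu, nuW, ww, wW, eps);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_mixed_cdf(NumericVector t, double a, double mu_nu,
                            double s_nu, double mu_w, double s_w, bool upper,
                            double eps, NumericVector ghx, NumericVector ghw,
                            NumericVector glx01, NumericVector glw01) {
  std::vector<double> nu, nuW, ww, wW;
  nodes_from_r(mu_nu, s_nu, mu_w, s_w, upper, ghx, ghw, glx01, glw01,
               nu, nuW, ww, wW);
  NumericVector out(t.size());
  for (R_xlen_t i = 0; i < t.size(); ++i)
    out[i] = mixed_cdf_nodes(t[i], a, nu, nuW, ww, wW, eps);
  return out;
}

// [[Rcpp::export]]
double cpp_mixed_mass(double bound, double a, double mu_nu, double s_nu,
                      double mu_w, double s_w, bool upper, double eps,
                      NumericVector ghx, NumericVector ghw,
                      NumericVector glx01, NumericVector glw01) {
  std::vector<double> nu, nuW, ww, wW;
  nodes_from_r(mu_nu, s_nu, mu_w, s_w, upper, ghx, ghw, glx01, glw01,
               nu, nuW, ww, wW);
  return mixed_mass_nodes(bound, a, nu, nuW, ww, wW, eps);
}

// mixed transformed log-density and its alpha-derivative (for the
// log-concavity scan and the transform-module surface)
// [[Rcpp::export]]
NumericMatrix cpp_mixed_alpha_h(NumericVector alpha, double a, double mu_nu,
                                double s_nu, double mu_w, double s_w,
                                bool upper, double eps, double s_alpha,
                                double alpha0, NumericVector ghx,
                                NumericVector ghw, NumericVector glx01,
                                NumericVector glw01) {
  MixedAlphaTarget tg;
  tg.a = a; tg.eps = eps; tg.s_alpha = s_alpha; tg.alpha0 = alpha0;
  nodes_from_r(mu_nu, s_nu, mu_w, s_w, upper, ghx, ghw, glx01, glw01,
               tg.nu, tg.nuW, tg.ww, tg.wW);
  NumericMatrix out(alpha.size(), 2);
  for (R_xlen_t i = 0; i < alpha.size(); ++i) {
    double h, dh;
    tg.eval(alpha[i], h, dh);
    out(i, 0) = h; out(i, 1) = dh;
  }
  return out;
}

// ===========================================================================
// Hull (R-facing granular operations share the C++ Hull class)
// ===========================================================================

static List hull_to_list(const ars::Hull &H) {
  return List::create(
    _["xs"] = NumericVector(H.x.begin(), H.x.end()),
    _["hs"] = NumericVector(H.h.begin(), H.h.end()),
    _["dhs"] = NumericVector(H.dh.begin(), H.dh.end()),
    _["zs"] = NumericVector(H.z.begin(), H.z.end()),
    _["logJs"] = NumericVector(H.logJ.begin(), H.logJ.end()),
    _["domain"] = NumericVector::create(H.lo, H.hi));
}

static ars::Hull hull_from_list(List st) {
  NumericVector xs = st["xs"], hs = st["hs"], dhs = st["dhs"],
                dom = st["domain"];
  ars::Hull H;
  H.build(std::vector<double>(xs.begin(), xs.end()),
          std::vector<double>(hs.begin(), hs.end()),
          std::vector<double>(dhs.begin(), dhs.end()), dom[0], dom[1]);
  return H;
}

// [[Rcpp::export]]
List cpp_hull_build(NumericVector xs, NumericVector hs, NumericVector dhs,
                    double lo, double hi) {
  ars::Hull H;
  H.build(std::vector<double>(xs.begin(), xs.end()),
          std::vector<double>(hs.begin(), hs.end()),
          std::vector<double>(dhs.begin(), dhs.end()), lo, hi);
  return hull_to_list(H);
}

// [[Rcpp::export]]
List cpp_hull_insert(List state, double x, double h, double dh) {
  ars::Hull H = hull_from_list(state);
  H.insert(x, h, dh);
  return hull_to_list(H);
}

// [[Rcpp::export]]
double cpp_hull_total_logmass(List state) {
  ars::Hull H = hull_from_list(state);
  return H.total_logJ();
}

// [[Rcpp::export]]
NumericVector cpp_hull_sample(List state, NumericVector uprop) {
  ars::Hull H = hull_from_list(state);
  NumericVector out(uprop.size());
  for (R_xlen_t i = 0; i < uprop.size(); ++i) out[i] = H.sample(uprop[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_hull_sample_n(List state, int n) {
  ars::Hull H = hull_from_list(state);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = H.sample(unif_rand());
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_hull_eval(List state, NumericVector x) {
  ars::Hull H = hull_from_list(state);
  NumericMatrix out(x.size(), 2);
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out(i, 0) = H.upper_at(x[i]);
    out(i, 1) = H.lower_at(x[i]);
  }
  return out;
}

// envelope bin probabilities over `breaks` (for goodness-of-fit checks)
// [[Rcpp::export]]
NumericVector cpp_hull_bin_probs(List state, NumericVector breaks) {
  ars::Hull H = hull_from_list(state);
  int nb = breaks.size() - 1;
  NumericVector lp(nb);
  for (int b = 0; b < nb; ++b) {
    double A = breaks[b], B = breaks[b + 1];
    double acc = R_NegInf;
    for (int i = 0; i < H.k(); ++i) {
      double lo2 = std::max(A, H.z[i]), hi2 = std::min(B, H.z[i + 1]);
      if (hi2 <= lo2) continue;
      // mass of tangent-i exponential over [lo2, hi2]
      double s = H.dh[i], hh = H.h[i], xx = H.x[i];
      double m;
      if (std::fabs(s) < 1e-10)
        m = hh + s * (lo2 - xx) + std::log(hi2 - lo2);
      else {
        double sd = s * (hi2 - lo2);
        if (sd > 700.0)
          m = hh + s * (hi2 - xx) - std::log(s);
        else
          m = hh + s * (lo2 - xx) + std::log(std::expm1(sd) / s);
      }
      acc = (acc == R_NegInf) ? m
            : std::max(acc, m) + std::log1p(std::exp(-std::fabs(acc - m)));
    }
    lp[b] = acc;
  }
  double tot = cpp_hull_total_logmass(state);
  NumericVector out(nb);
  for (int b = 0; b < nb; ++b)
    out[b] = (lp[b] == R_NegInf) ? 0.0 : std::exp(lp[b] - tot);
  return out;
}

// generic ARS with an R-function target: f(x) -> c(h, dh)
struct RFunTarget : ars::Target {
  Function f;
  RFunTarget(Function f_) : f(f_) {}
  void eval(double x, double &h, double &dh) {
    NumericVector r = f(x);
    h = r[0]; dh = r[1];
  }
};

// [[Rcpp::export]]
List cpp_ars_generic(Function target, int n, double lo, double hi,
                     double start, bool keep_hull, int k0) {
  RFunTarget tg(target);
  ars::Hull H;
  H.init(tg, lo, hi, start, k0);
  ars::ArsDiag diag;
  std::vector<double> out;
  std::vector<int> flags;
  ars::ars_sample_loop(tg, H, n, keep_hull, lo, hi, start, out, diag, &flags);
  return List::create(
    _["x"] = NumericVector(out.begin(), out.end()),
    _["squeeze"] = IntegerVector(flags.begin(), flags.end()),
    _["hull"] = hull_to_list(H),
    _["diag"] = List::create(_["proposals"] = (double)diag.proposals,
                             _["squeeze_accepts"] = (double)diag.squeeze_accepts,
                             _["full_accepts"] = (double)diag.full_accepts,
                             _["rejects"] = (double)diag.rejects,
                             _["target_evals"] = (double)diag.target_evals));
}

// [[Rcpp::export]]
List cpp_init_hull_generic(Function target, double lo, double hi, double start,
                           int k0) {
  RFunTarget tg(target);
  ars::Hull H;
  H.init(tg, lo, hi, start, k0);
  return hull_to_list(H);
}

// ===========================================================================
// FPT samplers at fixed parameters (decision time, boundary-conditional)
// ===========================================================================

// [[Rcpp::export]]
List cpp_ars_fpt(int n, double a, double v, double w, bool upper, double bound,
                 double eps, bool keep_hull, Nullable<List> hull_in,
                 bool want_flags) {
  CoreAlphaTarget tg(a, upper ? -v : v, upper ? 1.0 - w : w, eps);
  double hi = R_finite(bound) ? std::log(bound) : R_PosInf;
  ars::Hull H;
  if (hull_in.isNotNull()) H = hull_from_list(List(hull_in));
  ars::ArsDiag diag;
  std::vector<double> alpha;
  std::vector<int> flags;
  ars::ars_sample_loop(tg, H, n, keep_hull, R_NegInf, hi,
                       start_alpha(a, v, w, upper, bound), alpha, diag,
                       want_flags ? &flags : 0);
  NumericVector t(n);
  for (int i = 0; i < n; ++i) t[i] = std::exp(alpha[i]);
  List out = List::create(
    _["t"] = t, _["hull"] = hull_to_list(H),
    _["squeeze"] = IntegerVector(flags.begin(), flags.end()),
    _["diag"] = List::create(_["proposals"] = (double)diag.proposals,
                             _["squeeze_accepts"] = (double)diag.squeeze_accepts,
                             _["full_accepts"] = (double)diag.full_accepts,
                             _["rejects"] = (double)diag.rejects,
                             _["target_evals"] = (double)diag.target_evals));
  return out;
}

// [[Rcpp::export]]
List cpp_ars_fpt_mixed(int n, double a, double mu_nu, double s_nu, double mu_w,
                       double s_w, bool upper, double bound, double eps,
                       bool keep_hull, Nullable<List> hull_in, bool want_flags,
                       NumericVector ghx, NumericVector ghw,
                       NumericVector glx01, NumericVector glw01) {
  MixedAlphaTarget tg;
  tg.a = a; tg.eps = eps; tg.s_alpha = 1.0; tg.alpha0 = 0.0;
  nodes_from_r(mu_nu, s_nu, mu_w, s_w, upper, ghx, ghw, glx01, glw01,
               tg.nu, tg.nuW, tg.ww, tg.wW);
  double hi = R_finite(bound) ? std::log(bound) : R_PosInf;
  ars::Hull H;
  if (hull_in.isNotNull()) H = hull_from_list(List(hull_in));
  ars::ArsDiag diag;
  std::vector<double> alpha;
  std::vector<int> flags;
  ars::ars_sample_loop(tg, H, n, keep_hull, R_NegInf, hi,
                       start_alpha(a, mu_nu, mu_w, upper, bound), alpha, diag,
                       want_flags ? &flags : 0);
  NumericVector t(n);
  for (int i = 0; i < n; ++i) t[i] = std::exp(alpha[i]);
  return List::create(
    _["t"] = t, _["hull"] = hull_to_list(H),
    _["squeeze"] = IntegerVector(flags.begin(), flags.end()),
    _["diag"] = List::create(_["proposals"] = (double)diag.proposals,
                             _["squeeze_accepts"] = (double)diag.squeeze_accepts,
                             _["full_accepts"] = (double)diag.full_accepts,
                             _["rejects"] = (double)diag.rejects,
                             _["target_evals"] = (double)diag.target_evals));
}

// [[Rcpp::export]]
NumericVector cpp_its_fpt(int n, double a, double v, double w, bool upper,
                          double bound, double eps) {
  double va = upper ? -v : v, wa = upper ? 1.0 - w : w;
  double fb = R_finite(bound) ? wdm::cdf(bound, a, va, wa, eps)
                              : wdm::prob_lower(a, va, wa);
  if (fb <= 0.0) Rcpp::stop("no probability mass below the truncation bound");
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = its_bisect(unif_rand() * fb, a, va, wa, bound, eps);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_its_quantile(NumericVector p, double a, double v, double w,
                               bool upper, double bound, double eps) {
  double va = upper ? -v : v, wa = upper ? 1.0 - w : w;
  double fb = R_finite(bound) ? wdm::cdf(bound, a, va, wa, eps)
                              : wdm::prob_lower(a, va, wa);
  NumericVector out(p.size());
  for (R_xlen_t i = 0; i < p.size(); ++i)
    out[i] = its_bisect(p[i] * fb, a, va, wa, bound, eps);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rs_fpt(int n, double a, double v, double w, bool upper,
                         double bound, double eps) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = rs_conditional(a, v, w, upper, bound, eps);
  return out;
}

// unconditional RS draws: joint (time, boundary)
// [[Rcpp::export]]
List cpp_rs_fpt_both(int n, double a, double v, double w, double bound,
                     double eps) {
  NumericVector t(n);
  IntegerVector up(n);
  for (int i = 0; i < n; ++i) {
    for (long g = 0;; ++g) {
      if (g > 1000000L) Rcpp::stop("RS truncation resampling guard exceeded");
      double tt; bool uu;
      rs_draw(a, v, w, tt, uu);
      if (!R_finite(bound) || tt <= bound) { t[i] = tt; up[i] = uu; break; }
    }
  }
  return List::create(_["t"] = t, _["upper"] = up);
}
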
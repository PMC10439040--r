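#include "wdm.h"
#include <cmath>
#include <cfloat>
#include <algorithm>
#include <R.h>
#include <Rmath.h>

namespace wdm {

static const double LOG_2PI = 1.837877066409345483560659472811;
static const double PISQ = M_PI * M_PI;

bool valid_core(double a, double v, double w) {
  return R_finite(a) && R_finite(v) && R_finite(w) &&
         a > 0.0 && w > 0.0 && w < 1.0;
}

// ---------------------------------------------------------------------------
// f1(u; w): defective density (unit separation, zero drift, diffusion time
// u = t/a^2) of first passage at 0 starting from w.  Two representations:
//   small u:  (2 pi u^3)^{-1/2} sum_k (w+2k) exp(-(w+2k)^2 / (2u))
//   large u:  pi sum_{k>=1} k exp(-k^2 pi^2 u / 2) sin(k pi w)
// Both are evaluated with the dominant exponential factored out, so only
// well-scaled sums remain.  The same sums give the u-derivative ratio.
// ---------------------------------------------------------------------------

struct F1 {
  double logf;   // log f1(u; w)
  double ratio;  // f1'(u)/f1(u)  (derivative w.r.t. u)
};

static F1 f1_small(double u, double w, double eps) {
  // factored: f1 = (2 pi u^3)^{-1/2} e^{-w^2/(2u)} * S0
  // S0 = sum_k c_k exp(-(c_k^2 - w^2)/(2u)),  c_k = w + 2k
  // f1' = (2 pi u^3)^{-1/2} e^{-w^2/(2u)} * S1' with per-term factor
  //       (c_k^2/(2u^2) - 3/(2u))
  double S0 = w, S1 = w * (w * w / (2.0 * u * u) - 1.5 / u);
  double tol = std::max(eps * 1e-2, 1e-17);
  int quiet = 0;
  for (int k = 1; k <= 400; ++k) {
    double mx = 0.0;
    for (int s = -1; s <= 1; s += 2) {
      double c = w + 2.0 * s * k;
      double e = std::exp(-(c * c - w * w) / (2.0 * u));
      double t0 = c * e;
      S0 += t0;
      S1 += t0 * (c * c / (2.0 * u * u) - 1.5 / u);
      mx = std::max(mx, std::fabs(t0));
    }
    if (mx < tol * std::max(1.0, std::fabs(S0))) {
      if (++quiet >= 2) break;
    } else quiet = 0;
  }
  F1 out;
  if (S0 <= 0.0) { // cannot happen in the small-u regime; signal underflow
    out.logf = R_NegInf; out.ratio = 0.0; return out;
  }
  out.logf = -0.5 * (LOG_2PI + 3.0 * std::log(u)) - w * w / (2.0 * u)
             + std::log(S0);
  out.ratio = S1 / S0;
  return out;
}

static F1 f1_large(double u, double w, double eps) {
  // factored: f1 = pi e^{-pi^2 u/2} * S0,
  //   S0 = sum_k k sin(k pi w) exp(-(k^2-1) pi^2 u/2)
  // f1'/f1 = -(pi^2/2) * S3/S0,  S3 = sum_k k^3 sin(...) exp(...)
  double S0 = 0.0, S3 = 0.0;
  double tol = std::max(eps * 1e-2, 1e-17);
  int quiet = 0;
  for (int k = 1; k <= 1000; ++k) {
    double e = std::exp(-((double)k * k - 1.0) * PISQ * u / 2.0);
    double sk = std::sin(k * M_PI * w);
    S0 += k * e * sk;
    S3 += (double)k * k * k * e * sk;
    double bound = (double)k * k * k * e;  // dominates both term magnitudes
    if (bound < tol) {
      if (++quiet >= 2) break;
    } else quiet = 0;
  }
  F1 out;
  if (S0 <= 0.0) { out.logf = R_NegInf; out.ratio = 0.0; return out; }
  out.logf = std::log(M_PI) - PISQ * u / 2.0 + std::log(S0);
  out.ratio = -(PISQ / 2.0) * (S3 / S0);
  return out;
}

// representation switch: pick the series needing fewer terms (conservative
// Navarro-Fuss-style counts); adaptive stopping above does the fine control.
static bool use_small(double u, double eps) {
  if (u <= 0.03) return true;
  if (u >= 0.75) return false;
  double el = std::max(eps, 1e-15);
  double arg_s = -2.0 * u * std::log(2.0 * el * std::sqrt(2.0 * M_PI * u));
  double ks = (arg_s > 0.0) ? 2.0 + std::sqrt(arg_s) : 2.0;
  double arg_l = -2.0 * std::log(M_PI * u * el) / (PISQ * u);
  double kl = (arg_l > 0.0) ? std::sqrt(arg_l) : 1.0;
  return ks < kl;
}

static F1 f1_eval(double u, double w, double eps) {
  F1 r = use_small(u, eps) ? f1_small(u, w, eps) : f1_large(u, w, eps);
  if (!R_finite(r.logf) && r.logf > 0) r.logf = R_NegInf;
  return r;
}

// ---------------------------------------------------------------------------

double log_density(double t, double a, double v, double w, double eps) {
  if (!(t > 0.0)) return R_NegInf;
  double u = t / (a * a);
  F1 f = f1_eval(u, w, eps);
  if (!R_finite(f.logf)) return R_NegInf;
  return -2.0 * std::log(a) - v * a * w - v * v * t / 2.0 + f.logf;
}

double density(double t, double a, double v, double w, double eps) {
  double lg = log_density(t, a, v, w, eps);
  return R_finite(lg) ? std::exp(lg) : 0.0;
}

double density_ratio(double t, double a, double v, double w, double eps) {
  // g(t) = a^{-2} exp(-vaw - v^2 t/2) f1(t/a^2) =>
  // g'/g = -v^2/2 + f1'(u)/f1(u) / a^2
  double u = t / (a * a);
  F1 f = f1_eval(u, w, eps);
  return -v * v / 2.0 + f.ratio / (a * a);
}

double density_tderiv(double t, double a, double v, double w, double eps) {
  if (!(t > 0.0)) return 0.0;
  double lg = log_density(t, a, v, w, eps);
  if (!R_finite(lg)) return 0.0;
  return std::exp(lg) * density_ratio(t, a, v, w, eps);
}

// ---------------------------------------------------------------------------
// Absorption probability, Eq.-(6)-equivalent stable form:
// P(upper) = expm1(-2 v a w) / expm1(-2 v a)
// ---------------------------------------------------------------------------

double prob_upper(double a, double v, double w) {
  double c = 2.0 * v * a;
  if (std::fabs(c) < 1e-8) return w;       // drift-free limit
  if (c < -1400.0) return std::exp(c * (1.0 - w));  // both expm1 overflow
  double num = std::expm1(-c * w), den = std::expm1(-c);
  if (!R_finite(num) || !R_finite(den))     // one-sided overflow guard
    return std::exp(c * (1.0 - w));
  double p = num / den;
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

double prob_lower(double a, double v, double w) {
  return 1.0 - prob_upper(a, v, w);
}

// ---------------------------------------------------------------------------
// Defective CDF at the lower boundary.
// small t/a^2: method of images; each image is an inverse-Gaussian-type
//   first-passage CDF with closed form in Phi.
// large t/a^2: term-by-term integral of the large-time series tail:
//   F(t) = P_lower - (pi/a^2) e^{-vaw} sum_k k sin(k pi w) e^{-lam_k t}/lam_k
//   with lam_k = (v^2 + k^2 pi^2 / a^2)/2.
// ---------------------------------------------------------------------------

// integral_0^t of the image term with level b>0 and drift m:
// Phi((m t - b)/sqrt t) + e^{2 b m} Phi(-(m t + b)/sqrt t), via logs.
static void ig_cdf_logparts(double t, double b, double m,
                            double &lp1, double &lp2) {
  double st = std::sqrt(t);
  lp1 = ::pnorm5((m * t - b) / st, 0.0, 1.0, 1, 1);
  lp2 = 2.0 * b * m + ::pnorm5(-(m * t + b) / st, 0.0, 1.0, 1, 1);
}

static double cdf_small(double t, double a, double v, double w, double eps) {
  double acc = 0.0;
  double leps = std::log(std::max(eps * 1e-3, 1e-300));
  int quiet = 0;
  for (int j = 0; j <= 60; ++j) {
    // visit k = 0, -1, +1, -2, +2, ... (increasing |w + 2k|)
    int kk[2]; int nk = 0;
    if (j == 0) { kk[nk++] = 0; }
    else { kk[nk++] = -j; kk[nk++] = j; }
    double mx = R_NegInf;
    for (int i = 0; i < nk; ++i) {
      int k = kk[i];
      double wk = w + 2.0 * k;
      double sgn = (wk >= 0.0) ? 1.0 : -1.0;
      double b = a * std::fabs(wk);
      double m = -sgn * v;
      double lp1, lp2;
      ig_cdf_logparts(t, b, m, lp1, lp2);
      double pref = 2.0 * v * a * k;
      double t1 = pref + lp1, t2 = pref + lp2;
      acc += sgn * (std::exp(t1) + std::exp(t2));
      mx = std::max(mx, std::max(t1, t2));
    }
    if (mx < leps) { if (++quiet >= 2) break; } else quiet = 0;
  }
  if (acc < 0.0) acc = 0.0;
  return acc;
}

static double cdf_large(double t, double a, double v, double w, double eps) {
  double plo = prob_lower(a, v, w);
  double S = 0.0;
  double tol = std::max(eps * 1e-2, 1e-17);
  int quiet = 0;
  for (int k = 1; k <= 1000; ++k) {
    double lam = (v * v + (double)k * k * PISQ / (a * a)) / 2.0;
    double ex = -v * a * w - lam * t;
    double term = (M_PI / (a * a)) * k * std::sin(k * M_PI * w)
                  * std::exp(ex) / lam;
    S += term;
    double bound = (M_PI / (a * a)) * k * std::exp(ex) / lam;
    if (bound < tol) { if (++quiet >= 2) break; } else quiet = 0;
  }
  double f = plo - S;
  if (f < 0.0) f = 0.0;
  if (f > plo) f = plo;
  return f;
}

double cdf(double t, double a, double v, double w, double eps) {
  if (!(t > 0.0)) return 0.0;
  double u = t / (a * a);
  return (u < 0.2) ? cdf_small(t, a, v, w, eps) : cdf_large(t, a, v, w, eps);
}

} // namespace wdm
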
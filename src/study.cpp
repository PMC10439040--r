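#include <Rcpp.h>
#include "wdm.h"
#include "hull.h"
#include "internal.h"
#include <cmath>
#include <algorithm>

using namespace Rcpp;
using namespace diffsamp;

// ===========================================================================
// Kolmogorov-Smirnov helpers
// ===========================================================================

// asymptotic two-sided one-sample p-value, x = sqrt(n) * D
static double kolmogorov_p(double x) {
  if (x < 0.1) return 1.0;
  double s = 0.0;
  for (int k = 1; k <= 200; ++k) {
    double term = 2.0 * ((k % 2 == 1) ? 1.0 : -1.0)
                  * std::exp(-2.0 * (double)k * k * x * x);
    s += term;
    if (std::fabs(term) < 1e-14) break;
  }
  if (s < 0.0) s = 0.0;
  if (s > 1.0) s = 1.0;
  return s;
}

// [[Rcpp::export]]
double cpp_ks_pvalue(double d, int n) {
  return kolmogorov_p(std::sqrt((double)n) * d);
}

static double ks_stat_uniform(std::vector<double> &u) {
  std::sort(u.begin(), u.end());
  int n = (int)u.size();
  double d = 0.0;
  for (int i = 0; i < n; ++i) {
    d = std::max(d, (i + 1.0) / n - u[i]);
    d = std::max(d, u[i] - (double)i / n);
  }
  return d;
}

// ===========================================================================
// monotone cubic interpolation of a CDF on a grid with exact slopes
// ===========================================================================

struct CdfGrid {
  std::vector<double> t, F, f;  // knots, values, slopes

  // Fritsch-Carlson monotone slopes from the CDF values alone
  void set_monotone_slopes() {
    int n = (int)t.size();
    f.assign(n, 0.0);
    std::vector<double> d(n - 1);
    for (int j = 0; j < n - 1; ++j)
      d[j] = (F[j + 1] - F[j]) / (t[j + 1] - t[j]);
    f[0] = d[0]; f[n - 1] = d[n - 2];
    for (int j = 1; j < n - 1; ++j) {
      if (d[j - 1] * d[j] <= 0.0) f[j] = 0.0;
      else {
        double w1 = 2.0 * (t[j + 1] - t[j]) + (t[j] - t[j - 1]);
        double w2 = (t[j + 1] - t[j]) + 2.0 * (t[j] - t[j - 1]);
        f[j] = (w1 + w2) / (w1 / d[j - 1] + w2 / d[j]);
      }
    }
  }
  double eval(double tt) const {
    int n = (int)t.size();
    if (tt <= t.front()) return F.front();
    if (tt >= t.back()) return F.back();
    int j = (int)(std::upper_bound(t.begin(), t.end(), tt) - t.begin()) - 1;
    if (j >= n - 1) j = n - 2;
    double hseg = t[j + 1] - t[j];
    double s = (tt - t[j]) / hseg;
    double h00 = (1 + 2 * s) * (1 - s) * (1 - s), h10 = s * (1 - s) * (1 - s),
           h01 = s * s * (3 - 2 * s), h11 = s * s * (s - 1);
    double val = h00 * F[j] + h10 * hseg * f[j] + h01 * F[j + 1]
               + h11 * hseg * f[j + 1];
    if (val < 0.0) val = 0.0;
    if (val > 1.0) val = 1.0;
    return val;
  }
};

// ===========================================================================
// two-step trial sampler at fixed hyper-parameters: draw trial (nu, w) from
// the variability laws, accept with probability F_b(bound_T; theta) so the
// boundary- (and truncation-) conditional parameter distribution is correct,
// then draw the first-passage time at fixed theta.
// method: 1 = P-ARS, 2 = ITS, 3 = RS (ARS uses the mixed-density route)
// ===========================================================================

static double ars_fixed_one(double a, double v, double w, bool upper,
                            double boundT, double eps) {
  CoreAlphaTarget tg(a, upper ? -v : v, upper ? 1.0 - w : w, eps);
  double hi = R_finite(boundT) ? std::log(boundT) : R_PosInf;
  ars::Hull H;
  ars::ArsDiag diag;
  std::vector<double> out;
  ars::ars_sample_loop(tg, H, 1, true, R_NegInf, hi,
                       start_alpha(a, v, w, upper, boundT), out, diag);
  return std::exp(out[0]);
}

static double fixed_draw(int method, double a, double v, double w, bool upper,
                         double boundT, double eps) {
  switch (method) {
  case 1: return ars_fixed_one(a, v, w, upper, boundT, eps);
  case 2: {
    double va = upper ? -v : v, wa = upper ? 1.0 - w : w;
    double fb = R_finite(boundT) ? wdm::cdf(boundT, a, va, wa, eps)
                                 : wdm::prob_lower(a, va, wa);
    return its_bisect(unif_rand() * fb, a, va, wa, boundT, eps);
  }
  case 3: return rs_conditional(a, v, w, upper, boundT, eps);
  default: Rcpp::stop("unknown fixed-parameter method");
  }
}

// accept theta for conditioning on boundary `upper` truncated at boundT
static bool accept_theta(double a, double v, double w, bool upper,
                         double boundT, double eps) {
  double va = upper ? -v : v, wa = upper ? 1.0 - w : w;
  double u = unif_rand();
  double pb = wdm::prob_lower(a, va, wa);
  if (u > pb) return false;                     // cheap pretest
  if (!R_finite(boundT)) return true;
  return u <= wdm::cdf(boundT, a, va, wa, eps);
}

// [[Rcpp::export]]
List cpp_twostep_fpt(int n, double a, double mu_nu, double s_nu, double mu_w,
                     double s_w, double min_t0, double s_t0, int response,
                     double bound, int method, double eps) {
  NumericVector q(n);
  IntegerVector up(n);
  if (R_finite(bound) && min_t0 >= bound)
    Rcpp::stop("truncation bound is below the minimal non-decision time");
  for (int i = 0; i < n; ++i) {
    long guard = 0;
    for (;;) {
      if (++guard > 1000000L) Rcpp::stop("two-step sampler guard exceeded");
      double t0 = (s_t0 > 0.0) ? min_t0 + s_t0 * unif_rand() : min_t0;
      if (R_finite(bound) && t0 >= bound) continue;
      double boundT = R_finite(bound) ? bound - t0 : R_PosInf;
      double v = (s_nu > 0.0) ? R::rnorm(mu_nu, s_nu) : mu_nu;
      double w = (s_w > 0.0) ? mu_w + s_w * (unif_rand() - 0.5) : mu_w;
      bool upper;
      if (response == 2) {
        // joint (boundary, time): accept theta by total truncated mass,
        // then Bernoulli on the boundary-wise split
        double fu, fl;
        if (R_finite(boundT)) {
          fu = wdm::cdf(boundT, a, -v, 1.0 - w, eps);
          fl = wdm::cdf(boundT, a, v, w, eps);
          if (unif_rand() > fu + fl) continue;
        } else {
          fu = wdm::prob_upper(a, v, w);
          fl = 1.0 - fu;
        }
        upper = (unif_rand() < fu / (fu + fl));
      } else {
        upper = (response == 1);
        if (!accept_theta(a, v, w, upper, boundT, eps)) continue;
      }
      q[i] = fixed_draw(method, a, v, w, upper, boundT, eps) + t0;
      up[i] = upper ? 1 : 0;
      break;
    }
  }
  return List::create(_["q"] = q, _["upper"] = up);
}

// ===========================================================================
// KS calibration cell: one method x truncation x variability condition
// method: 0 = ARS, 1 = P-ARS, 2 = ITS, 3 = RS
// ===========================================================================

// [[Rcpp::export]]
List cpp_ks_cell(int method, double bound, bool snu_on, bool sw_on, int n_sets,
                 int n_per, double eps, NumericVector ghx, NumericVector ghw,
                 NumericVector glx01, NumericVector glw01, int grid_n) {
  NumericVector pv(n_sets), dv(n_sets);
  int redraws = 0;
  std::vector<double> gx(ghx.begin(), ghx.end()), gw(ghw.begin(), ghw.end());
  std::vector<double> lx(glx01.begin(), glx01.end()),
                      lw(glw01.begin(), glw01.end());

  for (int s = 0; s < n_sets; ++s) {
    double a, mu_nu, mu_w, s_nu, s_w, mass;
    bool upper;
    std::vector<double> nu, nuW, ww, wW;
    for (int g = 0;; ++g) {
      if (g > 10000) Rcpp::stop("parameter-set redraw guard exceeded");
      a = R::runif(0.6, 2.0);
      mu_nu = R::rnorm(0.0, 1.0);
      mu_w = R::rbeta(8.0, 8.0);
      s_nu = snu_on ? R::runif(0.0, 1.0) : 0.0;
      s_w = sw_on ? R::runif(0.0, 0.2) : 0.0;
      upper = (unif_rand() < 0.5);
      if (mu_w - s_w / 2.0 <= 0.0 || mu_w + s_w / 2.0 >= 1.0) { ++redraws; continue; }
      make_nodes(mu_nu, s_nu, mu_w, s_w, upper, gx, gw, lx, lw, nu, nuW, ww, wW);
      mass = mixed_mass_nodes(bound, a, nu, nuW, ww, wW, eps);
      if (mass < 1e-6) { ++redraws; continue; }
      break;
    }
    bool has_var = (s_nu > 0.0 || s_w > 0.0);

    std::vector<double> ts(n_per);
    if (method == 0 && !has_var) {
      CoreAlphaTarget tg(a, upper ? -mu_nu : mu_nu,
                         upper ? 1.0 - mu_w : mu_w, eps);
      double hi = R_finite(bound) ? std::log(bound) : R_PosInf;
      ars::Hull H; ars::ArsDiag diag;
      std::vector<double> alpha;
      ars::ars_sample_loop(tg, H, n_per, true, R_NegInf, hi,
                           start_alpha(a, mu_nu, mu_w, upper, bound),
                           alpha, diag);
      for (int i = 0; i < n_per; ++i) ts[i] = std::exp(alpha[i]);
    } else if (method == 0) {
      MixedAlphaTarget tg;
      tg.a = a; tg.eps = eps; tg.s_alpha = 1.0; tg.alpha0 = 0.0;
      tg.nu = nu; tg.nuW = nuW; tg.ww = ww; tg.wW = wW;
      double hi = R_finite(bound) ? std::log(bound) : R_PosInf;
      ars::Hull H; ars::ArsDiag diag;
      std::vector<double> alpha;
      ars::ars_sample_loop(tg, H, n_per, true, R_NegInf, hi,
                           start_alpha(a, mu_nu, mu_w, upper, bound),
                           alpha, diag);
      for (int i = 0; i < n_per; ++i) ts[i] = std::exp(alpha[i]);
    } else if (!has_var) {
      switch (method) {
      case 1: {  // P-ARS: hull discarded after each draw
        CoreAlphaTarget tg(a, upper ? -mu_nu : mu_nu,
                           upper ? 1.0 - mu_w : mu_w, eps);
        double hi = R_finite(bound) ? std::log(bound) : R_PosInf;
        ars::Hull H; ars::ArsDiag diag;
        std::vector<double> alpha;
        ars::ars_sample_loop(tg, H, n_per, false, R_NegInf, hi,
                             start_alpha(a, mu_nu, mu_w, upper, bound),
                             alpha, diag);
        for (int i = 0; i < n_per; ++i) ts[i] = std::exp(alpha[i]);
        break;
      }
      case 2: {
        double va = upper ? -mu_nu : mu_nu, wa = upper ? 1.0 - mu_w : mu_w;
        double fb = R_finite(bound) ? wdm::cdf(bound, a, va, wa, eps)
                                    : wdm::prob_lower(a, va, wa);
        for (int i = 0; i < n_per; ++i)
          ts[i] = its_bisect(unif_rand() * fb, a, va, wa, bound, eps);
        break;
      }
      case 3:
        for (int i = 0; i < n_per; ++i)
          ts[i] = rs_conditional(a, mu_nu, mu_w, upper, bound, eps);
        break;
      default: Rcpp::stop("unknown method");
      }
    } else {
      // two-step scheme with truncation-aware parameter acceptance
      for (int i = 0; i < n_per; ++i) {
        long guard = 0;
        for (;;) {
          if (++guard > 1000000L) Rcpp::stop("two-step guard exceeded");
          double v = (s_nu > 0.0) ? R::rnorm(mu_nu, s_nu) : mu_nu;
          double w = (s_w > 0.0) ? mu_w + s_w * (unif_rand() - 0.5) : mu_w;
          if (!accept_theta(a, v, w, upper, bound, eps)) continue;
          ts[i] = fixed_draw(method, a, v, w, upper, bound, eps);
          break;
        }
      }
    }

    // probability-integral transform against the conditional CDF
    std::vector<double> u(n_per);
    if (!has_var) {
      double va = upper ? -mu_nu : mu_nu, wa = upper ? 1.0 - mu_w : mu_w;
      for (int i = 0; i < n_per; ++i)
        u[i] = wdm::cdf(ts[i], a, va, wa, eps) / mass;
    } else {
      double tmin = *std::min_element(ts.begin(), ts.end());
      double tmax = *std::max_element(ts.begin(), ts.end());
      tmin = std::max(tmin * 0.999, 1e-12);
      tmax = tmax * 1.001;
      if (R_finite(bound)) tmax = std::min(tmax, bound);
      int G = std::max(grid_n, 8);
      CdfGrid grid;
      grid.t.resize(G); grid.F.resize(G);
      double l0 = std::log(tmin), l1 = std::log(tmax);
      for (int g = 0; g < G; ++g) {
        double tt = std::exp(l0 + (l1 - l0) * g / (G - 1.0));
        grid.t[g] = tt;
        grid.F[g] = mixed_cdf_nodes(tt, a, nu, nuW, ww, wW, eps) / mass;
      }
      grid.set_monotone_slopes();
      for (int i = 0; i < n_per; ++i) u[i] = grid.eval(ts[i]);
    }
    for (int i = 0; i < n_per; ++i) {
      if (u[i] < 0.0) u[i] = 0.0;
      if (u[i] > 1.0) u[i] = 1.0;
    }
    double D = ks_stat_uniform(u);
    dv[s] = D;
    pv[s] = kolmogorov_p(std::sqrt((double)n_per) * D);
    if (s % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["p"] = pv, _["d"] = dv, _["redraws"] = redraws);
}

// ===========================================================================
// log-concavity scan of the transformed log-density (numerical second
// derivative of d/dalpha log f_A via central differences of the exact first
// derivative; flagged points recomputed at escalated precision)
// ===========================================================================

static double second_deriv(MixedAlphaTarget &tg, double alpha, double delta) {
  double h1, d1, h2, d2;
  tg.eval(alpha + delta, h1, d1);
  tg.eval(alpha - delta, h2, d2);
  if (!R_finite(h1) || !R_finite(h2)) return R_NegInf;  // treat as no violation
  return (d1 - d2) / (2.0 * delta);
}

// [[Rcpp::export]]
List cpp_logconc_scan(int n_sets, NumericVector t_grid, double eps_base,
                      double delta, NumericVector ghx, NumericVector ghw,
                      NumericVector glx01, NumericVector glw01,
                      NumericVector ghx2, NumericVector ghw2,
                      NumericVector glx012, NumericVector glw012) {
  std::vector<double> gx(ghx.begin(), ghx.end()), gw(ghw.begin(), ghw.end());
  std::vector<double> lx(glx01.begin(), glx01.end()),
                      lw(glw01.begin(), glw01.end());
  std::vector<double> gx2(ghx2.begin(), ghx2.end()), gw2(ghw2.begin(), ghw2.end());
  std::vector<double> lx2(glx012.begin(), glx012.end()),
                      lw2(glw012.begin(), glw012.end());
  long pre = 0, post = 0, n_alpha = 0;
  for (int s = 0; s < n_sets; ++s) {
    double a, mu_nu, mu_w, s_nu, s_w;
    bool upper;
    for (int g = 0;; ++g) {
      if (g > 10000) Rcpp::stop("redraw guard exceeded");
      a = R::runif(0.5, 2.0);
      mu_nu = R::rnorm(0.0, 1.0);
      mu_w = R::rbeta(8.0, 8.0);
      s_nu = R::runif(0.0, 2.0);
      s_w = R::runif(0.0, 0.2);
      upper = (unif_rand() < 0.5);
      if (mu_w - s_w / 2.0 > 0.0 && mu_w + s_w / 2.0 < 1.0) break;
    }
    MixedAlphaTarget tg;
    tg.a = a; tg.eps = eps_base; tg.s_alpha = 1.0; tg.alpha0 = 0.0;
    make_nodes(mu_nu, s_nu, mu_w, s_w, upper, gx, gw, lx, lw,
               tg.nu, tg.nuW, tg.ww, tg.wW);
    MixedAlphaTarget tg_hi;  // escalated: denser nodes, tighter series eps
    tg_hi.a = a; tg_hi.eps = 1e-15; tg_hi.s_alpha = 1.0; tg_hi.alpha0 = 0.0;
    make_nodes(mu_nu, s_nu, mu_w, s_w, upper, gx2, gw2, lx2, lw2,
               tg_hi.nu, tg_hi.nuW, tg_hi.ww, tg_hi.wW);
    for (R_xlen_t i = 0; i < t_grid.size(); ++i) {
      double alpha = std::log(t_grid[i]);
      ++n_alpha;
      double d2 = second_deriv(tg, alpha, delta);
      if (d2 > 0.0) {
        ++pre;
        // escalate: higher quadrature order and series precision, growing
        // step to beat the roundoff noise; up to 3 escalations
        double dd = delta;
        bool violated = true;
        for (int esc = 0; esc < 3; ++esc) {
          dd *= 2.0;
          double r = second_deriv(tg_hi, alpha, dd);
          if (!(r > 0.0)) { violated = false; break; }
        }
        if (violated) ++post;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["pre"] = (double)pre, _["post"] = (double)post,
                      _["n_alpha"] = (double)n_alpha);
}
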
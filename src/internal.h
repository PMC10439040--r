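#ifndef DIFFSAMP_INTERNAL_H
#define DIFFSAMP_INTERNAL_H

#include <vector>
#include <cmath>
#include <R.h>
#include <Rmath.h>
#include "wdm.h"
#include "hull.h"

// shared between samplers.cpp and study.cpp
namespace diffsamp {

// ARS target in alpha = (log t - alpha0)/s_alpha space:
// h(alpha) = log s_alpha + s_alpha*alpha + alpha0 + log f_T(t)
// h'(alpha) = s_alpha * ((f_T'/f_T)(t) * t + 1),  t = exp(s_alpha*alpha+alpha0)
struct CoreAlphaTarget : ars::Target {
  double a, v, w, eps, s_alpha, alpha0;
  CoreAlphaTarget(double a_, double v_, double w_, double eps_,
                  double s_ = 1.0, double a0 = 0.0)
    : a(a_), v(v_), w(w_), eps(eps_), s_alpha(s_), alpha0(a0) {}
  void eval(double alpha, double &h, double &dh) {
    double ex = s_alpha * alpha + alpha0;
    if (ex > 700.0) { h = R_NegInf; dh = 0.0; return; }
    double t = std::exp(ex);
    double lg = wdm::log_density(t, a, v, w, eps);
    if (!R_finite(lg)) { h = R_NegInf; dh = 0.0; return; }
    h = std::log(s_alpha) + ex + lg;
    dh = s_alpha * (wdm::density_ratio(t, a, v, w, eps) * t + 1.0);
  }
};

// same target for the marginal (quadrature-mixed) defective density; the
// node arrays are already reflected for the boundary of interest
struct MixedAlphaTarget : ars::Target {
  double a, eps, s_alpha, alpha0;
  std::vector<double> nu, nuW, ww, wW;
  void eval(double alpha, double &h, double &dh) {
    double ex = s_alpha * alpha + alpha0;
    if (ex > 700.0) { h = R_NegInf; dh = 0.0; return; }
    double t = std::exp(ex);
    double mx = R_NegInf;
    size_t nn = nu.size(), nw = ww.size();
    std::vector<double> lg(nn * nw), rt(nn * nw);
    for (size_t i = 0; i < nn; ++i)
      for (size_t j = 0; j < nw; ++j) {
        size_t id = i * nw + j;
        lg[id] = std::log(nuW[i] * wW[j])
               + wdm::log_density(t, a, nu[i], ww[j], eps);
        rt[id] = R_finite(lg[id])
               ? wdm::density_ratio(t, a, nu[i], ww[j], eps) : 0.0;
        if (lg[id] > mx) mx = lg[id];
      }
    if (!R_finite(mx)) { h = R_NegInf; dh = 0.0; return; }
    double s0 = 0.0, s1 = 0.0;
    for (size_t id = 0; id < lg.size(); ++id) {
      if (!R_finite(lg[id])) continue;
      double e = std::exp(lg[id] - mx);
      s0 += e; s1 += e * rt[id];
    }
    h = std::log(s_alpha) + ex + mx + std::log(s0);
    dh = s_alpha * ((s1 / s0) * t + 1.0);
  }
};

void make_nodes(double mu_nu, double s_nu, double mu_w, double s_w, bool upper,
                const std::vector<double> &ghx, const std::vector<double> &ghw,
                const std::vector<double> &glx01, const std::vector<double> &glw01,
                std::vector<double> &nu, std::vector<double> &nuW,
                std::vector<double> &ww, std::vector<double> &wW);

double mixed_cdf_nodes(double t, double a, const std::vector<double> &nu,
                       const std::vector<double> &nuW,
                       const std::vector<double> &ww,
                       const std::vector<double> &wW, double eps);

double mixed_mass_nodes(double bound, double a, const std::vector<double> &nu,
                        const std::vector<double> &nuW,
                        const std::vector<double> &ww,
                        const std::vector<double> &wW, double eps);

double mixed_density_nodes(double t, double a, const std::vector<double> &nu,
                           const std::vector<double> &nuW,
                           const std::vector<double> &ww,
                           const std::vector<double> &wW, double eps);

double its_bisect(double utarget, double a, double v, double w, double bound,
                  double eps);

double rs_sample_u(double lam);
void rs_draw(double a, double v, double w, double &t, bool &upper);
double rs_conditional(double a, double v, double w, bool upper, double bound,
                      double eps);
double start_alpha(double a, double v, double w, bool upper, double bound);

} // namespace diffsamp

#endif
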
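#ifndef DIFFSAMP_WDM_H
#define DIFFSAMP_WDM_H

// Core numerical kernel for the two-boundary Wiener diffusion model with
// diffusion coefficient fixed at 1.  All densities/CDFs here are the
// DEFECTIVE quantities for absorption at the LOWER boundary; the upper
// boundary follows by the reflection (v, w) -> (-v, 1-w).

namespace wdm {

// log of the defective first-passage density g_-(t; a, v, w), -Inf for t<=0
double log_density(double t, double a, double v, double w, double eps);

double density(double t, double a, double v, double w, double eps);

// d/dt log g_-(t): finite whenever t > 0 (computable even when g underflows)
double density_ratio(double t, double a, double v, double w, double eps);

// d/dt g_-(t)
double density_tderiv(double t, double a, double v, double w, double eps);

// defective CDF F_-(t) = P(T <= t, absorb lower), 0 for t <= 0
double cdf(double t, double a, double v, double w, double eps);

// absorption probabilities (closed form)
double prob_upper(double a, double v, double w);
double prob_lower(double a, double v, double w);

bool valid_core(double a, double v, double w);

} // namespace wdm

#endif
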
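---
title: "Sampling Wiener diffusion first-passage times: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling Wiener diffusion first-passage times: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffsamp)
```

## The model

A Wiener process with drift $\nu$ and diffusion coefficient fixed at 1 starts
at $z = a\,w$ between absorbing boundaries $0$ and $a$ ($a>0$, $0<w<1$).  The
boundary reached first is the binary response; the first-passage time $T$ is
the decision time, and the observed response time is $q = T + t_0$ with an
additive non-decision time.  The *defective* density of terminating at the
lower boundary at time $t$ is

$$
g_-(t) = \frac{1}{a^2}\,
  e^{-\nu a w - \nu^2 t/2}\; f_1\!\left(\frac{t}{a^2};\, w\right),
$$

with $f_1$ available as two equivalent series,

$$
f_1(u;w) = \frac{1}{\sqrt{2\pi u^3}} \sum_{k\in\mathbb Z} (w+2k)\,
           e^{-(w+2k)^2/(2u)}
         = \pi \sum_{k\ge1} k\, e^{-k^2\pi^2 u/2} \sin(k\pi w),
$$

and $g_+(t;\nu,a,w) = g_-(t;-\nu,a,1-w)$ by reflection.  Each defective
density integrates to the absorption probability at its boundary, which is
closed-form:
$P(\text{upper}) = \operatorname{expm1}(-2\nu a w)/\operatorname{expm1}(-2\nu a)$,
with the limit $P(\text{upper}) = w$ taken explicitly for $|2\nu a| < 10^{-8}$
and a log-space branch when the exponents would overflow (beyond
$|2\nu a| \approx 1400$ the subdominant term is below double-precision
resolution).

**Series evaluation.**  Both representations are computed with the dominant
exponential factored out, so the remaining sums are well scaled at any
parameter value and the log-density is available even where the density
underflows.  The representation is chosen by comparing conservative
(Gaussian-tail vs. geometric-tail) term-count estimates at the requested
absolute precision `eps` (default $10^{-12}$, user range $(0, 10^{-3}]$);
within a representation, summation stops adaptively once two consecutive
terms fall below `eps`/100 relative to the accumulated sum.  The time
derivative $g'(t)$ reuses the same factored sums, so the ratio $g'/g$ — the
quantity the sampler needs — is computed stably without forming $g$ itself.

**CDF.**  For $t/a^2 \ge 0.2$ the large-time series is integrated term by
term ($\int_t^\infty e^{-\lambda_k s}\,ds = e^{-\lambda_k t}/\lambda_k$ with
$\lambda_k = (\nu^2 + k^2\pi^2/a^2)/2$).  For small $t/a^2$ that form loses
accuracy by cancellation against the absorption probability, so the
method-of-images representation is used instead: each image term is an
inverse-Gaussian-type first-passage CDF with a closed form in $\Phi$,
evaluated in log space.  Adaptive quadrature of the density is not needed in
the implementation, but it serves as the independent oracle in the test
suite (both routes agree to $10^{-7}$ there).

## The adaptive rejection sampler

The conditional FPT density is not log-concave, but its push-forward under
the log-time change of variables

$$
A = \frac{\log T - \alpha_0}{s_\alpha}, \qquad
f_A(\alpha) = s_\alpha\, e^{s_\alpha \alpha + \alpha_0}\,
              f_T\!\left(e^{s_\alpha \alpha + \alpha_0}\right)
$$

empirically is, with

$$
\frac{d}{d\alpha} \log f_A(\alpha)
  = s_\alpha\left(\frac{f_T'(t)}{f_T(t)}\, t + 1\right),
  \qquad t = e^{s_\alpha\alpha + \alpha_0}.
$$

Any $(\alpha_0, s_\alpha)$ gives the same transform family up to an affine
map, so correctness is invariant to the choice; the package defaults to the
pure log transform $\alpha_0 = 0$, $s_\alpha = 1$ and only exposes the
parameters for numerical-conditioning experiments.  No formal proof of
log-concavity is known; the package relies on the same three safeguards used
to justify the approach empirically: a large-scale numerical scan
(`log_concavity_scan()`), the fact that a hull update on a non-concave
region raises an immediate, loud error rather than corrupting samples, and
distribution-level validation of the output (`ks_accuracy_study()`).

Given log-concavity, ARS proceeds with a piecewise-linear *upper hull*
$u_k$ from tangents at support points and a *lower hull* $l_k$ from chords.
Proposals come from the normalized piecewise-exponential envelope
$e^{u_k}$: a segment is chosen from the renormalized segment masses and the
within-segment exponential CDF inverted in closed form.  A proposal $x^*$
with uniform $u$ is accepted without evaluating the target if
$u \le e^{l_k(x^*) - u_k(x^*)}$ (the squeeze); otherwise $h(x^*), h'(x^*)$
are computed, $x^*$ is inserted into the hull (the updating step), and
$u \le e^{h(x^*) - u_k(x^*)}$ decides acceptance.  The pseudo-adaptive
variant (P-ARS) resets the hull to its initial state after every accepted
draw.

Design choices where the construction is open:

* **Initial points** (3 by default): starting from a cheap guess of the mode
  ($t \approx (a\tilde w)^2/3$ in original time, $\tilde w$ the distance to
  the conditioned boundary), the search expands geometrically left until
  $h' > 0$ and right until $h' < 0$, guaranteeing finite envelope mass on
  unbounded domains; points where the density underflows ($h = -\infty$)
  are never used as support and the search steps around them.
* **Near-parallel tangents / near-zero slopes**: segment masses and
  inversions use `expm1`/`log1p` forms with a second-order Taylor fallback
  when $|h'| < 10^{-10}$, avoiding cancellation in $(e^{s\Delta}-1)/s$.
* **Tie-breaking**: a proposal landing exactly on a cumulative segment
  boundary belongs to the right segment (half-open intervals).
* **Hull size cap**: 200 support points; beyond the cap updates are skipped
  and sampling continues as plain rejection against the frozen envelope,
  which bounds memory and per-proposal cost without affecting the sampled
  distribution (acceptance tests stay exact).
* **Violations**: an insert that would make the slopes non-decreasing
  (beyond a $10^{-7}$ relative tolerance for roundoff) raises a
  log-concavity error — deliberately a hard failure, since it is the
  diagnostic that the target is outside the sampler's contract.

Truncation from above is domain restriction in $\alpha$: the hull's right
domain edge is $\log(\text{bound})$, so no post-hoc rejection is needed.

## Inverse transform and rejection sampling

**ITS.**  With no analytic quantile function, $F_b(t) = u$ is solved by
bisection to an absolute tolerance of $10^{-10}$ s.  For untruncated
sampling the initial bracket $[0, a^2/(1+|\nu|)]$ is doubled until it
contains the root; with truncation the bracket is simply $[0,
\text{bound}]$ and $u \sim U(0, F_b(\text{bound}))$, which renormalizes the
truncated distribution exactly.

**RS.**  For $w = 1/2$ the boundary label and the first-passage time are
independent (the ratio $g_+/g_-$ is constant in $t$), so the boundary is a
Bernoulli draw and the time is sampled in normalized units $u = t/a^2$ from
a density proportional to $e^{-\lambda u} f_0(u)$,
$\lambda = (\nu a)^2/2$, where $f_0$ is the drift-free symmetric FPT density
with the two alternating-series representations obtained from $f_1(u; 1/2)$.
Below the switch point $\bar u = 0.64$ (any value where both series have
decreasing terms works; the admissible interval is roughly $(0.028, 0.91)$)
the proposal is the leading small-time term — a truncated inverse Gaussian
with mean $1/(2|\nu| a)$ and shape $1/4$ when the drift is appreciable
($|\nu| a \ge 0.4$), otherwise the drift-free scaled-inverse-$\chi^2$ form
sampled through a truncated-normal tail with the factor $e^{-\lambda u}$
moved into the acceptance weight.  Above $\bar u$ the proposal is a shifted
exponential with rate $\pi^2/2 + \lambda$.  Acceptance uses the
alternating-series sandwich: partial sums alternately bound the target from
above and below, so the decision is almost always made after one or two
terms without ever evaluating the full series.

For $w \ne 1/2$ the sampler uses the nested symmetric-exit decomposition:
from position $z$, the process first leaves $[z-d, z+d]$ with
$d = \min(z, a-z)$ — a symmetric subproblem of separation $2d$ — and the
exit time and side are sampled as above; exits repeat, doubling the distance
to the nearer boundary each stage, until a true boundary is hit.  This is
exact by the strong Markov property.  Boundary-conditional draws resample
whole trajectories until the requested boundary is hit; truncated draws
resample until $t \le$ bound, with a fallback to ITS on the truncated CDF
when the acceptable mass fraction $F_b(\text{bound})/P_b$ drops below 1%
(naive resampling degenerates for tight bounds).

## Trial-to-trial variability

With $\nu \sim N(\mu_\nu, s_\nu)$, $w \sim U(\mu_w \pm s_w/2)$ and
$t_0 \sim U(\min t_0, \min t_0 + s_{t_0})$, two routes produce the same
distribution and are cross-validated against each other:

* **Two-step (ITS, RS, P-ARS)**: draw trial parameters, then sample the FPT
  at those fixed parameters.  Conditioning on a boundary requires the
  parameter-rejection step — accept a proposed $\theta$ only if
  $u \le P(\text{absorb at } b \mid \theta)$ — because trials ending at a
  given boundary overrepresent parameters that favour it.  Under truncation
  this acceptance probability generalizes to the truncated mass
  $F_b(\text{bound} \mid \theta)$: conditioning on the joint event
  \{boundary $b$, $q \le$ bound\} reweights parameters by exactly that
  probability, and only this choice makes the two-step output agree with
  the truncated mixed reference CDF (the package's KS harness checks this
  agreement in every truncated variability condition).  A cheap pretest
  against $P_b(\theta)$ avoids most CDF evaluations in the rejection loop.
* **Marginal (ARS)**: the mixed density
  $\int\!\!\int g_b(t;\nu,w)\, dN(\nu)\, dU(w)$ is a fixed function of $t$
  given the hyper-parameters, so one hull serves all draws.  The mixture is
  evaluated by Gauss–Hermite (drift) × Gauss–Legendre (starting point)
  quadrature in log space; the user-facing `mixed_density()`/`mixed_cdf()`
  use 32 nodes per dimension with an order-doubling refinement check
  (32→64, escalating to 128 before failing).  Inside the calibration-study
  loop the starting-point integral — a uniform over a range of at most
  0.2 — is machine-exact already at 8 Gauss–Legendre nodes (verified
  against the 32×32 reference to $\sim10^{-15}$), so the study uses
  32 GH × 8 GL for a fourfold speedup with no measurable accuracy cost.

The non-decision time never enters the FPT computation: it is added after
sampling, with $t_0$'s own uniform draw per trial.  Truncation applies to
the returned total $q = T + t_0$; internally $T$ is truncated at
$\text{bound} - t_0$ per trial and trials with $t_0 \ge$ bound are
redrawn.  (With `response = "both"`, variability, *and* a finite bound, the
ARS route splits boundaries by the marginal truncated masses at
$\text{bound} - \min t_0$; when additionally $s_{t_0} > 0$ this split is
approximate at the order of the $t_0$ range relative to the bound, while
the two-step methods handle the same case exactly per trial.)

## The validation studies

* **Log-concavity scan**: random parameter sets with $a \sim U[0.5, 2]$,
  $\mu_\nu \sim N(0,1)$, $\mu_w \sim \mathrm{Beta}(8,8)$,
  $s_\nu \sim U[0,2]$, $s_w \sim U[0,0.2]$, response
  $\sim \mathrm{Bernoulli}(.5)$; the derivative of $\log f_A$ is evaluated
  exactly and second-differenced centrally ($\delta = 10^{-3}$ in
  $\alpha$).  A positive value is re-examined at escalated precision —
  64-node quadrature, series tolerance $10^{-15}$, and doubled steps (the
  difference quotient's roundoff noise scales as $1/\delta$, so growing
  $\delta$ suppresses false positives while the $O(\delta^2)$ truncation
  bias stays far below the true curvature) — up to three times.  The
  package default is 200 parameter sets × 500 grid points over 0.01–5 s
  (100,000 evaluations), which keeps a full scan under a minute while
  retaining power: genuine convexity (e.g. $h = x^2$ pushed through the
  same machinery) is flagged at every grid point.
* **KS calibration study**: the full crossing of 4 methods × truncation
  $\{\infty, 0.5\,\mathrm s\}$ × $s_\nu$ on/off × $s_w$ on/off (32
  conditions) with $a \sim U[0.6,2]$ and the other priors as above
  ($s_\nu \sim U(0,1)$ here).  Parameter sets whose conditional mass at the
  sampled boundary is below $10^{-6}$ are redrawn (and counted).  Each
  sample is PIT-transformed through the truncated, renormalized conditional
  CDF — computed pointwise when parameters are fixed, and through a
  monotone cubic interpolant (Fritsch–Carlson slopes) of the mixed CDF on a
  64-point log-spaced grid under variability, whose interpolation error
  ($\ll 10^{-4}$) is negligible against the KS resolution at $n = 1000$ —
  and tested with the asymptotic one-sample Kolmogorov–Smirnov p-value
  (the same approximation `stats::ks.test` uses at these sample sizes).
  The package defaults are 1,000 parameter sets × 1,000 draws per
  condition: at that size the binomial standard error of the 5% rejection
  share is 0.7 percentage points, small enough to detect a miscalibrated
  sampler while keeping the full 32-condition study at a few minutes on
  one CPU; both sizes are arguments for larger runs.
* **Binomial meta-test**: `binomial_meta_probability()` is the exact tail
  $P(X \ge k)$, $X \sim \mathrm{Binomial}(n, \alpha)$, for judging a few
  significant uniformity tests across many conditions.
* **Timing harness**: `speed_harness()` reproduces the 16-condition ×
  sample-size grid (median over repetitions, default 100) and attaches no
  assertions: wall-clock comparisons are hardware- and load-dependent.

**What the generators emulate — and what they do not.**  The study priors
describe the parameter ranges typical of two-choice response-time
experiments (boundary separations 0.5–2 evidence units, drifts within a few
units per second, mild start-point bias, sub-second decisions).  Passing
calibration under these conditions shows the samplers draw from exactly the
intended mathematical distributions; it says nothing about whether that
model describes any particular dataset (contaminant responses, drifting
attention, collapsing boundaries and sequential effects are all outside the
model), and parameter regions far outside the priors (e.g. $|\nu a|$ in the
hundreds) are exercised only by the overflow-guard unit tests, not by the
calibration study.

**Seeds.**  All randomness flows through R's RNG; every study function takes
a `seed` argument, and `sample_wiener()` is byte-reproducible given one.
Raw pre-escalation flag counts in the scan are seed- and
precision-dependent; only the post-escalation count is a stable quantity.

## Known limitations

* Log-concavity of the transformed density is empirical, not proven; the
  sampler's failure mode under a violation is a hard error, never a silent
  bias.
* The RS symmetric-core switch point $\bar u$ and the IG/χ² proposal
  threshold are fixed constants chosen inside their admissible ranges, not
  per-parameter optimized; acceptance rates are insensitive to the choice.
* `n_threads > 1` partitions work across independent substreams: the pooled
  sample is distribution-identical to a single-threaded run, but per-draw
  ordering (and hence the exact stream) differs from `n_threads = 1`.
* Lévy/fractional noise, collapsing boundaries, non-uniform $t_0$ laws and
  correlated parameter variability are out of scope.
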
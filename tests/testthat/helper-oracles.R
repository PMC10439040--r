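# Independent oracles, implemented in plain R with generous term counts;
# deliberately separate from the package's C++ evaluation paths.

# small-time series for f1(u; w) (unit separation, zero drift, lower boundary)
f1_small_oracle <- function(u, w, K = 80) {
  k <- -K:K
  sum((w + 2 * k) * exp(-(w + 2 * k)^2 / (2 * u))) / sqrt(2 * pi * u^3)
}

# large-time series
f1_large_oracle <- function(u, w, K = 600) {
  k <- 1:K
  pi * sum(k * exp(-k^2 * pi^2 * u / 2) * sin(k * pi * w))
}

# defective density at the lower boundary, both representations
dens_oracle <- function(t, a, v, w, series = c("small", "large")) {
  series <- match.arg(series)
  u <- t / a^2
  f1 <- if (series == "small") f1_small_oracle(u, w) else f1_large_oracle(u, w)
  exp(-v * a * w - v^2 * t / 2) * f1 / a^2
}

dens_oracle_upper <- function(t, a, v, w, series = "small")
  dens_oracle(t, a, -v, 1 - w, series)

# defective CDF via adaptive quadrature of the oracle density
cdf_oracle <- function(t, a, v, w) {
  stats::integrate(function(s) vapply(s, dens_oracle, 0, a = a, v = v, w = w,
                                      series = "small"),
                   0, t, rel.tol = 1e-11, abs.tol = 1e-13)$value
}

# absorption probability straight from the printed closed form (unguarded)
prob_upper_oracle <- function(a, v, w) {
  (1 - exp(2 * v * a * w)) / (exp(-2 * v * a * (1 - w)) - exp(2 * v * a * w))
}

# random plausible core parameter sets
random_core <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(a = runif(n, 0.6, 2), v = rnorm(n), w = rbeta(n, 8, 8))
}

# standard-normal log-density target for the generic ARS engine
norm_target <- function(x) c(-x^2 / 2, -x)

# two-sided KS p of sample against conditional truncated (possibly mixed) CDF
ks_p_cond <- function(q, a, v, w, response, bound = Inf, sv = 0, sw = 0) {
  m <- pwfpt(if (is.finite(bound)) bound else Inf, a, v, w, sv = sv, sw = sw,
             response = response)
  u <- pwfpt(q, a, v, w, sv = sv, sw = sw, response = response) / m
  stats::ks.test(u, "punif")$p.value
}
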
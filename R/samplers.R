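# Boundary-conditional first-passage time samplers at fixed core parameters.
# All return DECISION times (no non-decision time added); truncation `bound`
# applies on the decision-time scale here.

#' Inverse transform sampling of first-passage times
#'
#' Draws boundary-conditional (optionally truncated) first-passage times by
#' inverting the defective CDF: `u ~ U(0, F_b(bound))` and the root of
#' `F_b(t) = u` is located by bisection to an absolute tolerance of 1e-10 in
#' `t` (the quantile function has no analytic form).  The map `u -> t` is
#' strictly monotone.
#'
#' @inheritParams dwfpt
#' @param n number of draws.
#' @param response `"upper"` or `"lower"`.
#' @param bound truncation from above of the decision time (default `Inf`).
#' @return numeric vector of `n` decision times, all `<= bound`.
#' @export
its_sample <- function(n, a, v, w, response = c("lower", "upper"),
                       bound = Inf, precision = 1e-12) {
  response <- match.arg(response)
  check_core(a, v, w)
  check_bound(bound)
  check_precision(precision)
  up <- response == "upper"
  mass <- if (is.finite(bound))
    cpp_fpt_cdf(bound, a, v, w, up, precision)
  else if (up) cpp_prob_upper(a, v, w) else 1 - cpp_prob_upper(a, v, w)
  if (mass <= 0)
    stop("no probability mass at the requested boundary below the bound",
         call. = FALSE)
  cpp_its_fpt(as.integer(n), a, v, w, up, bound, precision)
}

# quantile function backing its_sample: p is the conditional (renormalized)
# probability level in [0, 1]
its_quantile <- function(p, a, v, w, response = c("lower", "upper"),
                         bound = Inf, precision = 1e-12) {
  response <- match.arg(response)
  cpp_its_quantile(p, a, v, w, response == "upper", bound, precision)
}

#' Rejection sampling of first-passage times
#'
#' Exact rejection sampler built on proposal distributions based on the
#' exponential, scaled-inverse-chi-square and inverse-Gaussian distributions
#' with alternating-series acceptance tests.  For `w = 0.5` the symmetric
#' sampler applies directly (boundary and time are independent there); other
#' starting points are handled by the nested symmetric-exit decomposition:
#' from position `z` the process first leaves `[z-d, z+d]` with
#' `d = min(z, a-z)`, which is a symmetric subproblem of separation `2d`, and
#' exit times accumulate until a true boundary is hit (exact by the strong
#' Markov property).  Boundary-conditional draws resample until the requested
#' boundary is hit; truncation resamples, falling back to inverse-transform
#' sampling when the truncated mass fraction is below 1%.
#'
#' @inheritParams its_sample
#' @param response `"upper"`, `"lower"`, or `"both"`.
#' @return for conditional responses, a vector of decision times; for
#'   `response = "both"`, a list with `t` and `response`.
#' @export
rs_sample <- function(n, a, v, w, response = c("lower", "upper", "both"),
                      bound = Inf, precision = 1e-12) {
  response <- match.arg(response)
  check_core(a, v, w)
  check_bound(bound)
  check_precision(precision)
  n <- as.integer(n)
  if (response == "both") {
    r <- cpp_rs_fpt_both(n, a, v, w, bound, precision)
    return(list(t = r$t, response = ifelse(r$upper == 1, "upper", "lower")))
  }
  cpp_rs_fpt(n, a, v, w, response == "upper", bound, precision)
}

# ARS / pseudo-ARS draws of conditional decision times at fixed parameters.
# Returns list(t, hull, squeeze, diag).
ars_fpt_sample <- function(n, a, v, w, response, bound = Inf,
                           precision = 1e-12, keep_hull = TRUE, hull = NULL,
                           want_flags = FALSE) {
  cpp_ars_fpt(as.integer(n), a, v, w, response == "upper", bound, precision,
              keep_hull, hull, want_flags)
}

ars_fpt_sample_mixed <- function(n, a, mu_nu, s_nu, mu_w, s_w, response,
                                 bound = Inf, precision = 1e-12,
                                 keep_hull = TRUE, hull = NULL,
                                 want_flags = FALSE, order = 32L) {
  nd <- gauss_nodes(order)
  cpp_ars_fpt_mixed(as.integer(n), a, mu_nu, s_nu, mu_w, s_w,
                    response == "upper", bound, precision, keep_hull, hull,
                    want_flags, nd$ghx, nd$ghw, nd$glx01, nd$glw01)
}
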
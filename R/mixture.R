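# Trial-to-trial ("within-person") parameter variability: the drift rate is
# normal, the relative starting point and the non-decision time are uniform.
# Two sampling routes exist and must agree: the two-step scheme (draw trial
# parameters, then sample the FPT at fixed parameters) used by ITS/RS/P-ARS,
# and the marginal quadrature-mixed density route used by ARS so its hull
# can be reused across trials.

#' Variability (hyper-)parameters for trial-to-trial sampling
#'
#' Bundles the trial-level distributions: drift `v ~ Normal(mu_nu, s_nu)`,
#' starting point `w ~ Uniform(mu_w - s_w/2, mu_w + s_w/2)`, non-decision
#' time `t0 ~ Uniform(min_t0, min_t0 + s_t0)`.  Zero spreads are degenerate
#' (the mean is returned deterministically).
#'
#' @param mu_nu mean drift rate.
#' @param s_nu drift standard deviation (>= 0).
#' @param mu_w mean relative starting point in (0, 1).
#' @param s_w starting-point range (>= 0); the support must stay inside (0, 1).
#' @param min_t0 minimal non-decision time (>= 0, seconds).
#' @param s_t0 non-decision-time range (>= 0, seconds).
#' @return an object of class `"variability_params"`.
#' @export
variability_params <- function(mu_nu = 0, s_nu = 0, mu_w = 0.5, s_w = 0,
                               min_t0 = 0, s_t0 = 0) {
  check_variability(1, mu_nu, s_nu, mu_w, s_w, min_t0, s_t0)
  structure(list(mu_nu = mu_nu, s_nu = s_nu, mu_w = mu_w, s_w = s_w,
                 min_t0 = min_t0, s_t0 = s_t0),
            class = "variability_params")
}

#' Draw trial-level parameters
#'
#' One draw per trial from the three variability laws; degenerate spreads
#' return the mean.
#'
#' @param vp a [variability_params()] object.
#' @param n number of trials.
#' @return data frame with columns `v`, `w`, `t0`.
#' @export
draw_trial_params <- function(vp, n = 1) {
  stopifnot(inherits(vp, "variability_params"))
  data.frame(
    v = if (vp$s_nu > 0) rnorm(n, vp$mu_nu, vp$s_nu) else rep(vp$mu_nu, n),
    w = if (vp$s_w > 0) runif(n, vp$mu_w - vp$s_w / 2, vp$mu_w + vp$s_w / 2)
        else rep(vp$mu_w, n),
    t0 = if (vp$s_t0 > 0) runif(n, vp$min_t0, vp$min_t0 + vp$s_t0)
         else rep(vp$min_t0, n))
}

#' Boundary-conditional parameter acceptance
#'
#' When sampling conditional on a response boundary under trial-to-trial
#' variability, parameters that favour that boundary are overrepresented
#' among the conditioned trials.  The two-step scheme corrects for this by
#' accepting a proposed parameter draw only if `u <= P(absorption at b |
#' theta)` for `u ~ U(0,1)`, so accepted parameters are distributed
#' proportional to prior x absorption probability.
#'
#' @inheritParams dwfpt
#' @param u uniform(0, 1) variates (vectorized with `v`, `w`).
#' @param response `"upper"` or `"lower"`.
#' @return logical vector of acceptances.
#' @export
conditional_param_accept <- function(u, a, v, w,
                                     response = c("upper", "lower")) {
  response <- match.arg(response)
  p <- mapply(function(vi, wi) cpp_prob_upper(a, vi, wi), v, w)
  if (response == "lower") p <- 1 - p
  u <= p
}

#' Marginal (mixed) defective density and CDF under variability
#'
#' The core defective density/CDF integrated over the trial-level drift and
#' starting-point distributions by Gauss-Hermite (drift) x Gauss-Legendre
#' (starting point) quadrature, 32 nodes each with an order-doubling
#' refinement check.  With all spreads zero these collapse exactly to the
#' core quantities.  These are the reference distributions the
#' Kolmogorov-Smirnov validation tests samples against, and the ARS target
#' under variability.
#'
#' @param t decision times (seconds).
#' @param a boundary separation.
#' @param vp a [variability_params()] object (`min_t0`/`s_t0` are not used
#'   here: the non-decision time shifts samples but not the decision-time
#'   density).
#' @param response `"upper"` or `"lower"`.
#' @param precision absolute error bound.
#' @return numeric vector.
#' @export
mixed_density <- function(t, a, vp, response = c("lower", "upper"),
                          precision = 1e-12) {
  response <- match.arg(response)
  stopifnot(inherits(vp, "variability_params"))
  dwfpt(t, a, vp$mu_nu, vp$mu_w, t0 = 0, sv = vp$s_nu, sw = vp$s_w,
        response = response, precision = precision)
}

#' @rdname mixed_density
#' @export
mixed_cdf <- function(t, a, vp, response = c("lower", "upper"),
                      precision = 1e-12) {
  response <- match.arg(response)
  stopifnot(inherits(vp, "variability_params"))
  pwfpt(t, a, vp$mu_nu, vp$mu_w, t0 = 0, sv = vp$s_nu, sw = vp$s_w,
        response = response, precision = precision)
}

#' Sample first-passage times under trial-to-trial variability
#'
#' For `"its"`, `"rs"` and `"p-ars"` the two-step scheme is used: trial
#' parameters are drawn from their laws (with the boundary-conditional
#' acceptance step when `response` is not `"both"`, extended to the
#' truncated mass when `bound` is finite), then the FPT is sampled at those
#' fixed parameters.  For `"ars"` the hull is built once on the marginal
#' quadrature-mixed density and reused across draws.  The non-decision time
#' is added after FPT sampling; truncation applies to the returned total
#' time `q = T + t0`.
#'
#' @param method one of `"ars"`, `"rs"`, `"its"`, `"p-ars"`.
#' @param vp a [variability_params()] object.
#' @param a boundary separation.
#' @param response `"upper"`, `"lower"`, or `"both"`.
#' @param n number of trials.
#' @param bound truncation from above of `q` (default `Inf`).
#' @param precision absolute error bound.
#' @return list with `q` (times) and `response` (labels).
#' @export
sample_with_variability <- function(method = c("ars", "rs", "its", "p-ars"),
                                    vp, a, response = c("both", "upper", "lower"),
                                    n, bound = Inf, precision = 1e-12) {
  method <- match.arg(method)
  response <- match.arg(response)
  stopifnot(inherits(vp, "variability_params"))
  check_variability(a, vp$mu_nu, vp$s_nu, vp$mu_w, vp$s_w, vp$min_t0, vp$s_t0)
  check_bound(bound)
  check_precision(precision)
  n <- as.integer(n)
  if (method == "ars")
    return(ars_variability_route(vp, a, response, n, bound, precision))
  mcode <- c("p-ars" = 1L, "its" = 2L, "rs" = 3L)[[method]]
  rcode <- c(lower = 0L, upper = 1L, both = 2L)[[response]]
  r <- cpp_twostep_fpt(n, a, vp$mu_nu, vp$s_nu, vp$mu_w, vp$s_w, vp$min_t0,
                       vp$s_t0, rcode, bound, mcode, precision)
  list(q = r$q, response = ifelse(r$upper == 1, "upper", "lower"))
}

# ARS route: hull on the marginal mixed density (valid because the marginal
# is a fixed function of t given the hyper-parameters); t0 added afterwards,
# with per-trial re-truncation when t0 itself varies under a finite bound.
ars_variability_route <- function(vp, a, response, n, bound, precision,
                                  hull = NULL, store_hull = FALSE) {
  draw_side <- function(side, m, hull_in) {
    if (m == 0) {
      return(list(t = numeric(0), hull = hull_in))
    }
    boundT <- if (is.finite(bound)) bound - vp$min_t0 else Inf
    if (boundT <= 0)
      stop("truncation bound is below the minimal non-decision time",
           call. = FALSE)
    r <- ars_fpt_sample_mixed(m, a, vp$mu_nu, vp$s_nu, vp$mu_w, vp$s_w,
                              side, boundT, precision, keep_hull = TRUE,
                              hull = hull_in)
    tt <- r$t
    t0 <- if (vp$s_t0 > 0) runif(m, vp$min_t0, vp$min_t0 + vp$s_t0)
          else rep(vp$min_t0, m)
    if (is.finite(bound) && vp$s_t0 > 0) {
      # per-trial truncation of T at bound - t0: resample T where needed
      bad <- which(tt > bound - t0)
      guard <- 0
      while (length(bad) > 0) {
        guard <- guard + 1
        if (guard > 10000) stop("truncation resampling guard exceeded",
                                call. = FALSE)
        r2 <- ars_fpt_sample_mixed(length(bad), a, vp$mu_nu, vp$s_nu,
                                   vp$mu_w, vp$s_w, side, boundT, precision,
                                   keep_hull = TRUE, hull = r$hull)
        r$hull <- r2$hull
        tt[bad] <- r2$t
        bad <- bad[tt[bad] > bound - t0[bad]]
      }
    }
    list(t = tt + t0, hull = r$hull)
  }
  if (response != "both") {
    r <- draw_side(response, n, hull)
    out <- list(q = r$t, response = rep(response, n))
    if (store_hull) out$hull <- r$hull
    return(out)
  }
  # response = "both": marginal boundary probabilities (conditional on the
  # truncation event when bound is finite), then one hull per boundary
  boundT <- if (is.finite(bound)) bound - vp$min_t0 else Inf
  nd <- gauss_nodes(32L)
  mass_up <- cpp_mixed_mass(boundT, a, vp$mu_nu, vp$s_nu, vp$mu_w, vp$s_w,
                            TRUE, precision, nd$ghx, nd$ghw, nd$glx01, nd$glw01)
  mass_lo <- cpp_mixed_mass(boundT, a, vp$mu_nu, vp$s_nu, vp$mu_w, vp$s_w,
                            FALSE, precision, nd$ghx, nd$ghw, nd$glx01, nd$glw01)
  is_up <- runif(n) < mass_up / (mass_up + mass_lo)
  hu <- if (!is.null(hull)) hull$upper else NULL
  hl <- if (!is.null(hull)) hull$lower else NULL
  ru <- draw_side("upper", sum(is_up), hu)
  rl <- draw_side("lower", sum(!is_up), hl)
  q <- numeric(n)
  q[is_up] <- ru$t
  q[!is_up] <- rl$t
  out <- list(q = q, response = ifelse(is_up, "upper", "lower"))
  if (store_hull) out$hull <- list(upper = ru$hull, lower = rl$hull)
  out
}
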
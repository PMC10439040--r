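# The log-time change of variables A = (log T - alpha0) / s_alpha.  The
# conditional first-passage density itself is not log-concave, but its
# push-forward under this transform empirically is, which is what makes
# adaptive rejection sampling applicable.  alpha0 shifts and s_alpha scales
# in log-time; correctness is invariant to the choice (it is an affine
# reparameterization), only numerical conditioning changes.  Defaults are
# the pure log transform alpha0 = 0, s_alpha = 1.

#' Log-time transform and its inverse
#'
#' `to_alpha()` maps a decision time to the transformed variable
#' \eqn{\alpha = (\log t - \alpha_0)/s_\alpha}; `from_alpha()` is the inverse
#' \eqn{t = \exp(s_\alpha \alpha + \alpha_0)}.
#'
#' @param t decision times (> 0, seconds).
#' @param alpha transformed times.
#' @param alpha0 location parameter (log-seconds), default 0.
#' @param s_alpha scale parameter (> 0), default 1.
#' @return transformed values (`to_alpha`) or times (`from_alpha`).
#' @export
to_alpha <- function(t, alpha0 = 0, s_alpha = 1) {
  if (s_alpha <= 0) stop("`s_alpha` must be > 0", call. = FALSE)
  if (any(t <= 0)) stop("`t` must be > 0", call. = FALSE)
  (log(t) - alpha0) / s_alpha
}

#' @rdname to_alpha
#' @export
from_alpha <- function(alpha, alpha0 = 0, s_alpha = 1) {
  if (s_alpha <= 0) stop("`s_alpha` must be > 0", call. = FALSE)
  ex <- s_alpha * alpha + alpha0
  if (any(ex > 709))
    stop("`from_alpha` overflow: s_alpha * alpha + alpha0 > 709", call. = FALSE)
  exp(ex)
}

#' Transformed log-density and its derivative
#'
#' Log of the (defective, possibly parameter-mixed) first-passage density of
#' the transformed variable \eqn{A = (\log T - \alpha_0)/s_\alpha},
#' \deqn{h(\alpha) = \log s_\alpha + s_\alpha \alpha + \alpha_0 + \log f_T(t),}
#' and its derivative
#' \deqn{h'(\alpha) = s_\alpha \left( \frac{f_T'(t)}{f_T(t)} t + 1 \right),
#' \quad t = \exp(s_\alpha \alpha + \alpha_0).}
#' This is the target handed to the adaptive rejection sampler.  Where the
#' density underflows, `h` is `-Inf` and `dh` is `NA` (no tangent exists
#' there; such points are never inserted into a hull).
#'
#' @param alpha transformed times.
#' @inheritParams dwfpt
#' @inheritParams to_alpha
#' @return a list with components `h` and `dh` (vectors along `alpha`).
#' @export
log_density_alpha <- function(alpha, a, v, w, sv = 0, sw = 0,
                              response = c("lower", "upper"),
                              alpha0 = 0, s_alpha = 1, precision = 1e-12) {
  response <- match.arg(response)
  check_variability(a, v, sv, w, sw, 0, 0)
  check_precision(precision)
  if (s_alpha <= 0) stop("`s_alpha` must be > 0", call. = FALSE)
  nd <- gauss_nodes(32L)
  m <- cpp_mixed_alpha_h(alpha, a, v, sv, w, sw, response == "upper",
                         precision, s_alpha, alpha0,
                         nd$ghx, nd$ghw, nd$glx01, nd$glw01)
  h <- m[, 1]
  dh <- m[, 2]
  dh[!is.finite(h)] <- NA_real_
  list(h = h, dh = dh)
}
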
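# Generic adaptive rejection sampling for log-concave targets specified by
# (h, h') where h = log of the (possibly unnormalized) density.  The hull
# state is a plain list: support abscissae `xs`, values `hs`, slopes `dhs`,
# tangent-intersection knots `zs` (with the domain edges at the ends), log
# segment masses `logJs`, and `domain = c(low, high)`.

as_target_fun <- function(target) {
  if (is.function(target)) return(target)
  if (is.list(target) && is.function(target$h) && is.function(target$dh)) {
    h <- target$h; dh <- target$dh
    return(function(x) c(h(x), dh(x)))
  }
  stop("`target` must be a function x -> c(h, dh) or a list(h=, dh=)",
       call. = FALSE)
}

#' Build an initial hull for adaptive rejection sampling
#'
#' Places `k0` support points (default 3) around `start` so that the
#' piecewise-exponential envelope has finite mass: if the domain is unbounded
#' below/above, the leftmost/rightmost tangent slope must be positive/
#' negative, which is ensured by a geometric mode-bracketing search.  Points
#' where the target underflows (`h = -Inf`) are skipped.
#'
#' @param target function `x -> c(h, dh)` (log-density and derivative), or a
#'   list with functions `h` and `dh`.
#' @param domain numeric length-2, possibly infinite.
#' @param start abscissa from which the search expands.
#' @param k0 number of initial support points (>= 2).
#' @return a hull state list (`xs`, `hs`, `dhs`, `zs`, `logJs`, `domain`).
#' @export
init_hull <- function(target, domain = c(-Inf, Inf), start = 0, k0 = 3) {
  f <- as_target_fun(target)
  cpp_init_hull_generic(f, domain[1], domain[2], start, as.integer(k0))
}

#' Insert a support point into a hull
#'
#' Adds `(x, h(x), h'(x))` to the support set, recomputing the affected
#' tangent intersections and segment masses.  Inserting a point already in
#' the support (within 1e-12) leaves the hull unchanged.  A slope ordering
#' violation (non-concave log-density) is an error: the hull update is where
#' adaptive rejection sampling detects a non-log-concave target.
#'
#' @param state a hull state list.
#' @param x,h,dh the new support point, its log-density and derivative.
#' @return the updated hull state.
#' @export
hull_insert <- function(state, x, h, dh) {
  cpp_hull_insert(state, x, h, dh)
}

#' Draw proposal abscissae from the hull envelope
#'
#' Inverts the piecewise-exponential envelope: the segment is selected from
#' the renormalized segment masses (ties on a cumulative boundary go to the
#' right segment) and the within-segment exponential CDF is inverted in
#' closed form.
#'
#' @param state a hull state list.
#' @param u uniform(0,1) variates (one proposal per element).
#' @return abscissae, one per element of `u`.
#' @export
sample_envelope <- function(state, u) {
  cpp_hull_sample(state, u)
}

#' Squeeze/accept test for one proposal
#'
#' Applies the squeeze test `u <= exp(l_k(x) - u_k(x))` first; only if it
#' fails is the target evaluated, in which case the point is inserted into
#' the hull (the updating step) and the full test `u <= exp(h(x) - u_k(x))`
#' decides acceptance.
#'
#' @param state a hull state list.
#' @param x proposal abscissa.
#' @param u uniform(0,1) variate.
#' @param target as in [init_hull()].
#' @return list with `outcome` (one of `"accept_squeeze"`, `"accept_full"`,
#'   `"reject"`), `target_evaluated` (logical), and the possibly updated
#'   `state`.
#' @export
squeeze_accept <- function(state, x, u, target) {
  ev <- cpp_hull_eval(state, x)
  uk <- ev[1, 1]; lk <- ev[1, 2]
  if (log(u) <= lk - uk)
    return(list(outcome = "accept_squeeze", target_evaluated = FALSE,
                state = state))
  f <- as_target_fun(target)
  hv <- f(x)
  if (is.finite(hv[1]))
    state <- cpp_hull_insert(state, x, hv[1], hv[2])
  outcome <- if (is.finite(hv[1]) && log(u) <= hv[1] - uk) "accept_full" else "reject"
  list(outcome = outcome, target_evaluated = TRUE, state = state)
}

#' Adaptive rejection sampling from a log-concave density
#'
#' Draws `n` values from the density proportional to `exp(h)` using the
#' envelope/squeeze scheme with tangent hulls.  With `keep_hull = TRUE`
#' (ARS) the hull persists and grows across draws, so costly target
#' evaluations become increasingly rare; with `keep_hull = FALSE` (the
#' pseudo-adaptive variant) the hull is reset to its initial state after
#' every accepted draw.
#'
#' @inheritParams init_hull
#' @param n number of draws.
#' @param keep_hull persist hull updates across draws?
#' @return list with `x` (draws), `hull` (final state), `squeeze` (per-draw
#'   flag: accepted via squeeze without target evaluation), and `diag`
#'   (proposal/acceptance counters).
#' @examples
#' norm_target <- function(x) c(-x^2 / 2, -x)
#' set.seed(1)
#' s <- ars_sample(norm_target, 1000, start = 0.5)
#' c(mean(s$x), var(s$x))
#' @export
ars_sample <- function(target, n, domain = c(-Inf, Inf), start = 0,
                       keep_hull = TRUE, k0 = 3) {
  f <- as_target_fun(target)
  cpp_ars_generic(f, as.integer(n), domain[1], domain[2], start, keep_hull,
                  as.integer(k0))
}

#' Hull persistence
#'
#' Writes/reads a hull state as a JSON document with fields `xs`, `hs`,
#' `dhs`, `zs`, `logJs`, `domain`, so that an adapted envelope can be reused
#' across calls (a warm start for the adaptive sampler).
#'
#' @param state a hull state list (or, from [sample_wiener()] with
#'   `response = "both"`, a list of two hull states named `upper`/`lower`).
#' @param path file path.
#' @return `read_hull()` returns the hull state; `write_hull()` its path,
#'   invisibly.
#' @export
write_hull <- function(state, path) {
  sanitize <- function(s) {
    # JSON has no Inf: encode infinite domain edges (and the edge knots in
    # zs, which are rebuilt on read anyway) as null
    s$domain[is.infinite(s$domain)] <- NA_real_
    s$zs[is.infinite(s$zs)] <- NA_real_
    s
  }
  out <- if (!is.null(state$xs)) sanitize(state) else lapply(state, sanitize)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE, na = "null")
  invisible(path)
}

#' @rdname write_hull
#' @export
read_hull <- function(path) {
  if (!file.exists(path)) stop("hull file not found: ", path, call. = FALSE)
  st <- jsonlite::read_json(path, simplifyVector = TRUE)
  reconstruct <- function(s) {
    s$domain[is.na(s$domain)] <- c(-Inf, Inf)[is.na(s$domain)]
    # rebuild derived fields so a hand-edited file cannot carry stale masses
    cpp_hull_build(s$xs, s$hs, s$dhs, s$domain[1], s$domain[2])
  }
  if (!is.null(st$xs)) reconstruct(st) else lapply(st, reconstruct)
}

# envelope bin probabilities for goodness-of-fit checking of the
# piecewise-exponential proposal distribution
hull_bin_probs <- function(state, breaks) {
  cpp_hull_bin_probs(state, breaks)
}
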
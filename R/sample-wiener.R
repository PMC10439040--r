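#' Sample responses and response times from the Wiener diffusion model
#'
#' Draws `N` first-passage times and response labels from the two-boundary
#' Wiener diffusion model with boundary separation `a`, drift rate `v`,
#' relative starting point `w` and non-decision time `t0`, optionally with
#' trial-to-trial variability (`sv`, `sw`, `st0`), truncation from above
#' (`bound`), and conditioning on a response boundary.  Four exact sampling
#' methods are available:
#'
#' * `"ars"` (default): adaptive rejection sampling on the log-time
#'   transform of the conditional first-passage density.  The tangent hull
#'   adapts across draws, so density evaluations become increasingly rare.
#'   Under variability the hull is built on the quadrature-mixed marginal
#'   density and reused across trials.
#' * `"p-ars"`: pseudo-adaptive variant; the hull is discarded after every
#'   draw.  Under variability it uses the two-step scheme (trial parameters
#'   first, then the FPT at fixed parameters), avoiding the quadrature.
#' * `"its"`: inverse transform sampling by bisection on the CDF.
#' * `"rs"`: rejection sampling with exponential / scaled-inverse-chi-square
#'   / inverse-Gaussian proposals.
#'
#' When `response = "both"`, the boundary is sampled from the absorption
#' probabilities and the time from the distribution conditional on that
#' boundary.  All returned times satisfy `q <= bound` and `q >= t0`.
#'
#' @param N number of samples.
#' @param a boundary separation (> 0).
#' @param v (mean) drift rate.
#' @param w (mean) relative starting point in (0, 1).
#' @param t0 (minimal) non-decision time (seconds, >= 0). Default 0.
#' @param sv trial-to-trial drift SD (>= 0). Default 0.
#' @param sw trial-to-trial starting-point range (>= 0). Default 0.
#' @param st0 trial-to-trial non-decision-time range (>= 0). Default 0.
#' @param response `"both"` (default), `"upper"`, or `"lower"`.
#' @param bound truncation from above of the response time (default `Inf`).
#' @param method `"ars"` (default), `"rs"`, `"its"`, or `"p-ars"`.
#' @param precision absolute numerical-error bound for density/CDF/derivative
#'   evaluations (default 1e-12).
#' @param n_threads number of worker processes; `N` is partitioned across
#'   independent RNG substreams, so the pooled sample has the same
#'   distribution as a single-threaded run (per-draw ordering differs).
#' @param hull an optional hull state from a previous `"ars"` run (warm
#'   start); with `response = "both"` a list with components `upper` and
#'   `lower`.
#' @param store_hull if `TRUE` and `method = "ars"`, the final hull state(s)
#'   are returned for reuse.
#' @param seed optional integer seed; if supplied, the output is fully
#'   reproducible.
#' @return an object of class `"wiener_samples"`: a list with `q` (response
#'   times, seconds), `response` (character, `"upper"`/`"lower"`), the
#'   matched `call`, and optionally `hull`.
#' @examples
#' s <- sample_wiener(N = 10, a = 1, v = 0.3, w = 0.6, t0 = 0.2, seed = 1)
#' s
#' @export
sample_wiener <- function(N, a, v, w, t0 = 0, sv = 0, sw = 0, st0 = 0,
                          response = c("both", "upper", "lower"),
                          bound = Inf,
                          method = c("ars", "rs", "its", "p-ars"),
                          precision = 1e-12, n_threads = 1, hull = NULL,
                          store_hull = FALSE, seed = NULL) {
  response <- match.arg(response)
  method <- match.arg(method)
  check_variability(a, v, sv, w, sw, t0, st0)
  check_bound(bound)
  check_precision(precision)
  if (!is.numeric(N) || length(N) != 1 || N < 1 || N != round(N))
    stop("`N` must be a positive integer", call. = FALSE)
  N <- as.integer(N)
  if (is.finite(bound) && bound <= t0)
    stop("`bound` must exceed the (minimal) non-decision time", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  n_threads <- max(1L, as.integer(n_threads))
  if (n_threads > 1L) {
    sizes <- diff(round(seq(0, N, length.out = n_threads + 1)))
    seeds <- sample.int(.Machine$integer.max, n_threads)
    runs <- parallel::mclapply(seq_len(n_threads), function(i) {
      set.seed(seeds[i])
      sample_wiener_once(sizes[i], a, v, w, t0, sv, sw, st0, response, bound,
                         method, precision, hull, store_hull = FALSE)
    }, mc.cores = n_threads)
    out <- list(q = unlist(lapply(runs, `[[`, "q")),
                response = unlist(lapply(runs, `[[`, "response")))
  } else {
    out <- sample_wiener_once(N, a, v, w, t0, sv, sw, st0, response, bound,
                              method, precision, hull, store_hull)
  }
  out$call <- match.call()
  class(out) <- "wiener_samples"
  out
}

sample_wiener_once <- function(N, a, v, w, t0, sv, sw, st0, response, bound,
                               method, precision, hull, store_hull) {
  has_var <- sv > 0 || sw > 0 || st0 > 0
  if (has_var) {
    vp <- variability_params(v, sv, w, sw, t0, st0)
    if (method == "ars")
      return(ars_variability_route(vp, a, response, N, bound, precision,
                                   hull = hull, store_hull = store_hull))
    return(sample_with_variability(method, vp, a, response, N, bound,
                                   precision))
  }
  # fixed parameters; truncation on q translates to bound - t0 on T
  boundT <- if (is.finite(bound)) bound - t0 else Inf
  draw_cond <- function(side, m, hull_in) {
    if (m == 0) return(list(t = numeric(0), hull = hull_in))
    switch(method,
      "ars" = {
        r <- ars_fpt_sample(m, a, v, w, side, boundT, precision,
                            keep_hull = TRUE, hull = hull_in)
        list(t = r$t, hull = r$hull, diag = r$diag)
      },
      "p-ars" = {
        r <- ars_fpt_sample(m, a, v, w, side, boundT, precision,
                            keep_hull = FALSE)
        list(t = r$t, hull = NULL)
      },
      "its" = list(t = its_sample(m, a, v, w, side, boundT, precision),
                   hull = NULL),
      "rs" = list(t = rs_sample(m, a, v, w, side, boundT, precision),
                  hull = NULL))
  }
  if (response == "both") {
    # truncation-aware boundary probabilities: P(b | q <= bound)
    pu <- if (is.finite(boundT))
      cpp_fpt_cdf(boundT, a, v, w, TRUE, precision)
    else cpp_prob_upper(a, v, w)
    pl <- if (is.finite(boundT))
      cpp_fpt_cdf(boundT, a, v, w, FALSE, precision)
    else 1 - cpp_prob_upper(a, v, w)
    is_up <- runif(N) < pu / (pu + pl)
    ru <- draw_cond("upper", sum(is_up),
                    if (!is.null(hull)) hull$upper else NULL)
    rl <- draw_cond("lower", sum(!is_up),
                    if (!is.null(hull)) hull$lower else NULL)
    q <- numeric(N)
    q[is_up] <- ru$t
    q[!is_up] <- rl$t
    out <- list(q = q + t0, response = ifelse(is_up, "upper", "lower"))
    if (store_hull && method == "ars")
      out$hull <- list(upper = ru$hull, lower = rl$hull)
    dg <- Filter(Negate(is.null), list(ru$diag, rl$diag))
    if (length(dg))
      out$diag <- Reduce(function(x, y) Map(`+`, x, y), dg)
  } else {
    r <- draw_cond(response, N, if (!is.null(hull) && !is.null(hull$xs))
      hull else if (!is.null(hull)) hull[[response]] else NULL)
    out <- list(q = r$t + t0, response = rep(response, N))
    if (store_hull && method == "ars") out$hull <- r$hull
    if (!is.null(r$diag)) out$diag <- r$diag
  }
  out
}

#' @export
print.wiener_samples <- function(x, ...) {
  n <- length(x$q)
  cat("Wiener diffusion model samples (n = ", n, ")\n", sep = "")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  show <- min(n, 10L)
  cat("  q:        ", paste(formatC(x$q[seq_len(show)], digits = 5,
                                    format = "g"), collapse = " "),
      if (n > show) " ..." else "", "\n", sep = "")
  cat("  response: ", paste(x$response[seq_len(show)], collapse = " "),
      if (n > show) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.wiener_samples <- function(object, ...) {
  q <- object$q
  resp <- object$response
  out <- list(
    n = length(q),
    p_upper = mean(resp == "upper"),
    quantiles = lapply(split(q, resp), stats::quantile,
                       probs = c(.1, .25, .5, .75, .9)),
    mean = vapply(split(q, resp), mean, numeric(1)))
  class(out) <- "summary.wiener_samples"
  out
}

#' @export
print.summary.wiener_samples <- function(x, ...) {
  cat("Wiener FPT samples: n =", x$n,
      sprintf("| P(upper) = %.3f\n", x$p_upper))
  for (b in names(x$quantiles)) {
    cat(sprintf("  %s: mean = %.4f s, quantiles (10/25/50/75/90%%): %s\n", b,
                x$mean[[b]],
                paste(formatC(x$quantiles[[b]], digits = 4, format = "f"),
                      collapse = " ")))
  }
  invisible(x)
}

#' @export
plot.wiener_samples <- function(x, breaks = 50, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (b in c("upper", "lower")) {
    q <- x$q[x$response == b]
    if (length(q) == 0) {
      graphics::plot.new()
      graphics::title(main = paste0(b, " (no samples)"))
      next
    }
    graphics::hist(q, breaks = breaks, freq = FALSE,
                   main = paste0(b, " boundary"),
                   xlab = "response time (s)", ...)
  }
  invisible(x)
}
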
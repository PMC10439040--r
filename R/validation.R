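# Validation harness: the three simulation studies used to check the
# samplers -- a log-concavity scan of the transformed density, a
# Kolmogorov-Smirnov calibration study of all four samplers, and the exact
# binomial meta-test -- plus a timing harness with no timing assertions.

#' Exact binomial meta-test probability
#'
#' Probability of observing `k_min` or more significant outcomes among
#' `n_conditions` independent tests at level `alpha` when all nulls hold:
#' the exact binomial tail \eqn{P(X \ge k_{min})}, \eqn{X \sim
#' \mathrm{Binomial}(n, \alpha)}.  Used to judge how surprising a handful of
#' significant uniformity tests is across the calibration-study conditions.
#'
#' @param n_conditions number of conditions (default 32).
#' @param k_min threshold count (default 3).
#' @param alpha test level (default .05).
#' @return a probability.
#' @examples
#' binomial_meta_probability(32, 3, .05)  # ~ 0.21
#' @export
binomial_meta_probability <- function(n_conditions = 32, k_min = 3,
                                      alpha = 0.05) {
  if (k_min <= 0) return(1)
  pbinom(k_min - 1, n_conditions, alpha, lower.tail = FALSE)
}

#' Scan the transformed log-density for log-concavity violations
#'
#' Draws random parameter sets (boundary separation `a ~ U[0.5, 2]`, mean
#' drift `~ N(0,1)`, mean starting point `~ Beta(8,8)`, drift variability
#' `s_nu ~ U[0,2]`, starting-point variability `s_w ~ U[0,0.2]`, response
#' `~ Bernoulli(.5)`) and, for each, evaluates the derivative of the
#' log-density of the log-time-transformed FPT variable on a time grid.  The
#' second derivative is formed by central differences of the exact first
#' derivative; grid points where it comes out positive are recomputed at
#' escalated precision (denser quadrature, tighter series tolerance, larger
#' step) up to three times.  A persistently positive second derivative would
#' indicate a log-concavity violation, which would invalidate ARS.
#'
#' @param n_sets number of random parameter sets (default 200).
#' @param t_grid time grid in seconds (default 0.01 to 5 by 0.01).
#' @param precision base evaluation precision (default 1e-12).
#' @param delta central-difference step in transformed time (default 1e-3).
#' @param seed optional seed.
#' @return list with `pre` (flagged points before escalation), `post`
#'   (violations remaining after escalation), `n_alpha` (grid points
#'   scanned).
#' @export
log_concavity_scan <- function(n_sets = 200, t_grid = seq(0.01, 5, by = 0.01),
                               precision = 1e-12, delta = 1e-3, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  nd <- gauss_nodes(32L)
  nd2 <- gauss_nodes(64L)
  r <- cpp_logconc_scan(as.integer(n_sets), t_grid, precision, delta,
                        nd$ghx, nd$ghw, nd$glx01, nd$glw01,
                        nd2$ghx, nd2$ghw, nd2$glx01, nd2$glw01)
  list(pre = r$pre, post = r$post, n_alpha = r$n_alpha)
}

# one cell of the KS calibration study; returns p-values etc.
ks_cell <- function(method = c("ars", "p-ars", "its", "rs"), bound = Inf,
                    snu_on = FALSE, sw_on = FALSE, n_sets = 1000,
                    n_per = 1000, precision = 1e-12, grid_n = 64) {
  method <- match.arg(method)
  mcode <- c("ars" = 0L, "p-ars" = 1L, "its" = 2L, "rs" = 3L)[[method]]
  # 32-node Gauss-Hermite for the drift; the starting-point integrand is a
  # narrow uniform (range <= 0.2) and is machine-exact at 8 Gauss-Legendre
  # nodes, so the study loop uses that order
  nd <- gauss_nodes(32L)
  gl <- gauss_nodes(8L)
  cpp_ks_cell(mcode, bound, snu_on, sw_on, as.integer(n_sets),
              as.integer(n_per), precision, nd$ghx, nd$ghw, gl$glx01,
              gl$glw01, as.integer(grid_n))
}

#' Kolmogorov-Smirnov calibration study of the samplers
#'
#' For every requested condition (sampling method x truncation x drift
#' variability on/off x starting-point variability on/off), draws `n_sets`
#' random parameter sets (`a ~ U[0.6, 2]`, mean drift `~ N(0,1)`, mean
#' starting point `~ Beta(8,8)`, `s_nu ~ U(0,1)` when on, `s_w ~ U(0,0.2)`
#' when on, response `~ Bernoulli(.5)`), samples `n_per` boundary-conditional
#' first-passage times per set, and applies a one-sample Kolmogorov-Smirnov
#' test against the corresponding (truncated, renormalized, possibly
#' parameter-mixed) conditional CDF.  For a correct sampler the p-values are
#' uniform and about 5% fall below .05.  Parameter sets with conditional
#' mass below 1e-6 at the sampled boundary are redrawn.
#'
#' @param methods subset of `c("ars", "p-ars", "its", "rs")`.
#' @param trunc truncation bounds to cross (default `c(Inf, 0.5)`).
#' @param snu_on,sw_on logical vectors to cross (default `c(FALSE, TRUE)`).
#' @param n_sets parameter sets per condition (default 1000).
#' @param n_per draws per parameter set (default 1000).
#' @param precision evaluation precision.
#' @param grid_n CDF interpolation grid size for mixed conditions.
#' @param seed optional seed.
#' @return list with `results` (data frame: one row per condition with
#'   `share_significant`, the fraction of KS p-values below .05, and
#'   `uniformity_p`, the KS p-value of the p-values against U(0,1)) and
#'   `p_values` (list of per-condition p-value vectors).
#' @export
ks_accuracy_study <- function(methods = c("ars", "its", "rs", "p-ars"),
                              trunc = c(0.5, Inf), snu_on = c(FALSE, TRUE),
                              sw_on = c(FALSE, TRUE), n_sets = 1000,
                              n_per = 1000, precision = 1e-12, grid_n = 64,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  grid <- expand.grid(method = methods, bound = trunc, snu = snu_on,
                      sw = sw_on, stringsAsFactors = FALSE)
  res <- vector("list", nrow(grid))
  pvals <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- ks_cell(grid$method[i], grid$bound[i], grid$snu[i], grid$sw[i],
                    n_sets, n_per, precision, grid_n)
    p <- cell$p
    unif_p <- stats::ks.test(p, "punif")$p.value
    res[[i]] <- data.frame(
      method = grid$method[i], bound = grid$bound[i],
      s_nu_on = grid$snu[i], s_w_on = grid$sw[i], n_sets = n_sets,
      n_per = n_per, share_significant = mean(p < 0.05),
      uniformity_p = unif_p, redraws = cell$redraws)
    pvals[[i]] <- p
  }
  list(results = do.call(rbind, res), p_values = pvals)
}

#' Timing harness for the samplers
#'
#' Measures median sampling wall-time over a grid of conditions (truncation
#' x response mode x drift variability x starting-point variability -- 16
#' conditions) and sample sizes, for each method.  Core parameters are drawn
#' per repetition from the calibration-study priors (with `s_nu ~ U(0,2)`
#' when drift variability is on).  This harness reports times only; no
#' assertions are attached, as absolute and relative speeds are hardware-
#' dependent.
#'
#' @param methods subset of `c("ars", "p-ars", "its", "rs")`.
#' @param sizes sample sizes (default `10^(0:6)`).
#' @param reps repetitions per condition; the median is reported
#'   (default 100).
#' @param precision evaluation precision.
#' @param seed optional seed.
#' @return data frame with one row per condition x method x size and the
#'   median elapsed seconds.
#' @export
speed_harness <- function(methods = c("ars", "its", "rs", "p-ars"),
                          sizes = 10^(0:6), reps = 100, precision = 1e-12,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  conds <- expand.grid(bound = c(Inf, 0.5), response = c("both", "one"),
                       snu = c(FALSE, TRUE), sw = c(FALSE, TRUE),
                       stringsAsFactors = FALSE)
  out <- list()
  for (ci in seq_len(nrow(conds))) {
    for (m in methods) for (N in sizes) {
      times <- numeric(reps)
      for (r in seq_len(reps)) {
        a <- runif(1, 0.6, 2)
        mu_nu <- rnorm(1)
        mu_w <- rbeta(1, 8, 8)
        repeat {
          s_w <- if (conds$sw[ci]) runif(1, 0, 0.2) else 0
          if (mu_w - s_w / 2 > 0 && mu_w + s_w / 2 < 1) break
        }
        s_nu <- if (conds$snu[ci]) runif(1, 0, 2) else 0
        resp <- if (conds$response[ci] == "both") "both"
                else sample(c("upper", "lower"), 1)
        times[r] <- system.time(
          try(sample_wiener(N, a, mu_nu, mu_w, sv = s_nu, sw = s_w,
                            response = resp, bound = conds$bound[ci],
                            method = m, precision = precision),
              silent = TRUE))[["elapsed"]]
      }
      out[[length(out) + 1]] <- data.frame(
        bound = conds$bound[ci], response = conds$response[ci],
        s_nu_on = conds$snu[ci], s_w_on = conds$sw[ci], method = m, N = N,
        median_seconds = stats::median(times))
    }
  }
  do.call(rbind, out)
}
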
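# The log-time change of variables and the transformed log-density target.

test_that("to_alpha/from_alpha are inverse and behave at the location", {
  expect_identical(to_alpha(1, 0, 1), 0)
  expect_equal(to_alpha(exp(1.7), alpha0 = 1.7, s_alpha = 3.2), 0)
  set.seed(1)
  t <- exp(runif(50, -4, 3))
  expect_equal(from_alpha(to_alpha(t, 0.3, 2), 0.3, 2), t, tolerance = 1e-12)
  expect_error(to_alpha(-1), "`t`")
  expect_error(from_alpha(1000), "overflow")
  expect_error(to_alpha(1, s_alpha = 0), "s_alpha")
})

test_that("dh matches a finite difference of h at random points", {
  pars <- random_core(25, seed = 202)
  alphas <- runif(25, -2.5, 1)
  for (i in seq_len(25)) {
    a <- pars$a[i]; v <- pars$v[i]; w <- pars$w[i]; al <- alphas[i]
    d <- 1e-6
    r <- log_density_alpha(c(al - d, al, al + d), a, v, w, response = "lower")
    if (all(is.finite(r$h))) {
      fd <- (r$h[3] - r$h[1]) / (2 * d)
      expect_equal(r$dh[2], fd, tolerance = 1e-4, label = sprintf("case %d", i))
    }
  }
})

test_that("the zero of dh is the mode of the transformed density", {
  a <- 1.3; v <- 0.6; w <- 0.45
  grid <- seq(-4, 1.5, by = 0.002)
  r <- log_density_alpha(grid, a, v, w, response = "lower")
  i0 <- which(diff(sign(r$dh)) < 0)[1]  # sign change + -> -
  mode_alpha <- grid[i0]
  h_at <- function(al) log_density_alpha(al, a, v, w, response = "lower")$h
  expect_gte(h_at(mode_alpha), h_at(mode_alpha - 0.5))
  expect_gte(h_at(mode_alpha), h_at(mode_alpha + 0.5))
})

test_that("numerical second derivative of h is non-positive on the grid", {
  # the log-concavity property that makes ARS applicable, at fixed parameters
  pars <- random_core(10, seed = 203)
  tg <- seq(0.01, 5, by = 0.01)
  for (i in seq_len(10)) {
    al <- log(tg)
    r <- log_density_alpha(al, pars$a[i], pars$v[i], pars$w[i],
                           response = "upper")
    d <- 1e-3
    dp <- log_density_alpha(al + d, pars$a[i], pars$v[i], pars$w[i],
                            response = "upper")$dh
    dm <- log_density_alpha(al - d, pars$a[i], pars$v[i], pars$w[i],
                            response = "upper")$dh
    d2 <- (dp - dm) / (2 * d)
    ok <- is.finite(d2)
    expect_true(all(d2[ok] <= 1e-8), label = sprintf("set %d", i))
  }
})

test_that("affine invariance: back-transformed samples do not depend on (alpha0, s_alpha)", {
  # h changes only by an affine reparameterization; samples mapped through
  # from_alpha() must have the same distribution
  a <- 1; v <- 0.4; w <- 0.55
  target_for <- function(a0, sa) {
    function(x) {
      r <- log_density_alpha(x, a, v, w, response = "lower",
                             alpha0 = a0, s_alpha = sa)
      c(r$h, ifelse(is.na(r$dh), 0, r$dh))
    }
  }
  set.seed(42)
  s1 <- ars_sample(target_for(0, 1), 10000, start = -1)
  s2 <- ars_sample(target_for(-0.5, 2), 10000, start = -0.25)
  t1 <- from_alpha(s1$x, 0, 1)
  t2 <- from_alpha(s2$x, -0.5, 2)
  expect_gt(stats::ks.test(t1, t2)$p.value, 0.001)
})

test_that("exp(h) integrates to the absorption probability", {
  a <- 1.4; v <- -0.3; w <- 0.6
  f <- function(al) exp(log_density_alpha(al, a, v, w, response = "lower")$h)
  m <- stats::integrate(function(x) vapply(x, f, 0), -12, 4,
                        rel.tol = 1e-9)$value
  expect_equal(m, wdm_absorption(a, v, w, "lower"), tolerance = 1e-6)
})
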
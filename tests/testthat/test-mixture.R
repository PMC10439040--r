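# Trial-to-trial variability: the two-step scheme, the boundary-conditional
# parameter rejection step, and the quadrature-mixed density/CDF.

test_that("trial parameter draws follow their laws; degenerate spreads collapse", {
  vp0 <- variability_params(mu_nu = 0.7, s_nu = 0, mu_w = 0.4, s_w = 0,
                            min_t0 = 0.15, s_t0 = 0)
  d <- draw_trial_params(vp0, 5)
  expect_identical(d$v, rep(0.7, 5))
  expect_identical(d$w, rep(0.4, 5))
  expect_identical(d$t0, rep(0.15, 5))
  set.seed(10)
  vp <- variability_params(mu_nu = 0.5, s_nu = 0.8, mu_w = 0.45, s_w = 0.2,
                           min_t0 = 0.1, s_t0 = 0.2)
  d <- draw_trial_params(vp, 100000)
  expect_lt(abs(mean(d$v) - 0.5), 3 * 0.8 / sqrt(1e5))
  expect_lt(abs(sd(d$v) - 0.8), 0.01)
  expect_true(min(d$w) >= 0.35 && max(d$w) <= 0.55)
  expect_true(min(d$t0) >= 0.1 && max(d$t0) <= 0.3)
  expect_error(variability_params(mu_w = 0.95, s_w = 0.2), "out of range")
})

test_that("conditional parameter acceptance reweights by absorption probability", {
  set.seed(11)
  # near-certain upper absorption accepts almost always
  acc <- conditional_param_accept(runif(10000), a = 1, v = rep(50, 10000),
                                  w = rep(0.5, 10000), response = "upper")
  expect_gt(mean(acc), 0.999)
  # at v = 0, P(upper) = w: accepted-w density prop. to w, so
  # E[w | accept] = E[w^2]/E[w] for w ~ U(0.3, 0.7)
  n <- 100000
  w <- runif(n, 0.3, 0.7)
  acc <- conditional_param_accept(runif(n), a = 1.2, v = rep(0, n), w = w,
                                  response = "upper")
  m_exact <- mean(w^2) / mean(w)
  expect_gt(m_exact - mean(w), 0.02)  # a real shift upward
  expect_lt(abs(mean(w[acc]) - m_exact), 3 * sd(w) / sqrt(sum(acc)))
})

test_that("conditional acceptance is equivalent to discarding wrong-boundary trials", {
  set.seed(12)
  a <- 1; vp <- variability_params(mu_nu = 0.3, s_nu = 0.7, mu_w = 0.5,
                                   s_w = 0.2)
  s1 <- sample_with_variability("its", vp, a, response = "lower", n = 4000)
  # brute-force route: unconditional two-step, keep lower-boundary trials
  q2 <- c()
  while (length(q2) < 4000) {
    d <- draw_trial_params(vp, 2000)
    for (i in seq_len(2000)) {
      pu <- wdm_absorption(a, d$v[i], d$w[i], "upper")
      if (runif(1) < pu) next
      q2 <- c(q2, its_sample(1, a, d$v[i], d$w[i], "lower"))
      if (length(q2) >= 4000) break
    }
  }
  expect_gt(stats::ks.test(s1$q, q2)$p.value, 0.001)
})

test_that("mixed density/CDF collapse exactly to the core when spreads are zero", {
  vp0 <- variability_params(mu_nu = 0.4, s_nu = 0, mu_w = 0.6, s_w = 0)
  ts <- c(0.05, 0.2, 0.8, 2)
  expect_equal(mixed_density(ts, 1.1, vp0, "lower"),
               dwfpt(ts, 1.1, 0.4, 0.6, response = "lower"), tolerance = 1e-14)
  expect_equal(mixed_cdf(ts, 1.1, vp0, "lower"),
               pwfpt(ts, 1.1, 0.4, 0.6, response = "lower"), tolerance = 1e-14)
})

test_that("mixed density integrates to the Monte-Carlo marginal absorption probability", {
  vp <- variability_params(mu_nu = 0.2, s_nu = 0.9, mu_w = 0.45, s_w = 0.15)
  m <- stats::integrate(function(t) mixed_density(t, 1.2, vp, "upper"), 0, Inf,
                        rel.tol = 1e-9)$value
  set.seed(13)
  n <- 200000
  d <- draw_trial_params(vp, n)
  pu <- vapply(seq_len(n), function(i)
    wdm_absorption(1.2, d$v[i], d$w[i], "upper"), 0)
  mc <- mean(pu)
  expect_lt(abs(m - mc), 3 * sd(pu) / sqrt(n))
})

test_that("mixed CDF matches the empirical CDF of two-step samples", {
  set.seed(14)
  vp <- variability_params(mu_nu = -0.3, s_nu = 0.8, mu_w = 0.55, s_w = 0.18)
  s <- sample_with_variability("rs", vp, 1.3, response = "upper", n = 10000)
  expect_gt(ks_p_cond(s$q, 1.3, -0.3, 0.55, "upper", sv = 0.8, sw = 0.18),
            0.001)
})

test_that("ARS (mixed-density) route agrees with the two-step route", {
  set.seed(15)
  vp <- variability_params(mu_nu = 0.4, s_nu = 0.6, mu_w = 0.45, s_w = 0.15)
  s_ars <- sample_with_variability("ars", vp, 1.2, response = "lower", n = 10000)
  s_two <- sample_with_variability("p-ars", vp, 1.2, response = "lower", n = 10000)
  expect_gt(stats::ks.test(s_ars$q, s_two$q)$p.value, 0.001)
})

test_that("variability sampling honors truncation on the total time", {
  set.seed(16)
  vp <- variability_params(mu_nu = 0.2, s_nu = 0.5, mu_w = 0.5, s_w = 0.1,
                           min_t0 = 0.1, s_t0 = 0.1)
  for (m in c("ars", "its", "rs", "p-ars")) {
    s <- sample_with_variability(m, vp, 1, response = "both", n = 2000,
                                 bound = 0.5)
    expect_lte(max(s$q), 0.5)
    expect_gte(min(s$q), 0.1)
  }
})

test_that("boundary frequencies under degenerate variability match the closed form", {
  set.seed(17)
  vp0 <- variability_params(mu_nu = 0.3, s_nu = 0, mu_w = 0.6, s_w = 0)
  s <- sample_with_variability("rs", vp0, 1, response = "both", n = 100000)
  p <- wdm_absorption(1, 0.3, 0.6, "upper")
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(mean(s$response == "upper") - p), 3 * se)
})

test_that("collapse property: zero spreads reproduce the fixed-parameter sampler", {
  set.seed(18)
  vp0 <- variability_params(mu_nu = 0.5, s_nu = 0, mu_w = 0.4, s_w = 0)
  s <- sample_with_variability("its", vp0, 1.4, response = "lower", n = 5000)
  t_fixed <- its_sample(5000, 1.4, 0.5, 0.4, "lower")
  expect_gt(stats::ks.test(s$q, t_fixed)$p.value, 0.001)
})

test_that("accepted parameters are proportional to prior x absorption probability", {
  set.seed(19)
  a <- 1; n <- 200000
  w <- runif(n, 0.3, 0.7)  # prior
  u <- runif(n)
  acc <- conditional_param_accept(u, a, v = rep(0, n), w = w, "upper")
  # at v = 0 the absorption probability is w, so accepted w has density
  # prop. to w on (0.3, 0.7)
  br <- seq(0.3, 0.7, length.out = 51)
  obs <- table(cut(w[acc], br))
  dens <- (br[-1]^2 - br[-51]^2)  # integral of w over each bin, up to const.
  chi <- stats::chisq.test(as.vector(obs), p = dens / sum(dens))
  expect_gt(chi$p.value, 0.001)
})
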
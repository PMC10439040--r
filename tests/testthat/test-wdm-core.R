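# Core kernel: defective density, its time derivative, defective CDF, and
# the absorption probability.

test_that("density matches the dual-series oracle and its own two branches agree", {
  # spec-fixture case
  expect_equal(dwfpt(0.35, 1.5, 1, 0.5, response = "lower"),
               dens_oracle(0.35, 1.5, 1, 0.5, "small"), tolerance = 1e-10)
  expect_equal(dens_oracle(0.35, 1.5, 1, 0.5, "small"),
               dens_oracle(0.35, 1.5, 1, 0.5, "large"), tolerance = 1e-12)
  pars <- random_core(40, seed = 101)
  ts <- exp(runif(40, log(0.03), log(4)))
  for (i in seq_len(40)) {
    a <- pars$a[i]; v <- pars$v[i]; w <- pars$w[i]
    d <- dwfpt(ts[i], a, v, w, response = "lower")
    expect_equal(d, dens_oracle(ts[i], a, v, w, "small"),
                 tolerance = 1e-9, label = sprintf("case %d (small)", i))
    expect_equal(d, dens_oracle(ts[i], a, v, w, "large"),
                 tolerance = 1e-9, label = sprintf("case %d (large)", i))
  }
})

test_that("defective densities integrate to the absorption probabilities", {
  iu <- stats::integrate(function(t) dwfpt(t, 1, 0.3, 0.6, response = "upper"),
                         0, Inf, rel.tol = 1e-10)$value
  il <- stats::integrate(function(t) dwfpt(t, 1, 0.3, 0.6, response = "lower"),
                         0, Inf, rel.tol = 1e-10)$value
  expect_equal(iu + il, 1, tolerance = 1e-8)
  expect_equal(iu, wdm_absorption(1, 0.3, 0.6, "upper"), tolerance = 1e-8)
})

test_that("reflection symmetry (v, w) -> (-v, 1-w) with boundary swap", {
  pars <- random_core(25, seed = 7)
  ts <- exp(runif(25, log(0.05), log(3)))
  for (i in seq_len(25)) {
    a <- pars$a[i]; v <- pars$v[i]; w <- pars$w[i]; t <- ts[i]
    expect_equal(dwfpt(t, a, v, w, response = "upper"),
                 dwfpt(t, a, -v, 1 - w, response = "lower"), tolerance = 1e-12)
    expect_equal(dwfpt_dt(t, a, v, w, response = "upper"),
                 dwfpt_dt(t, a, -v, 1 - w, response = "lower"),
                 tolerance = 1e-12)
    expect_equal(pwfpt(t, a, v, w, response = "upper"),
                 pwfpt(t, a, -v, 1 - w, response = "lower"), tolerance = 1e-12)
    expect_equal(wdm_absorption(a, v, w, "upper"),
                 wdm_absorption(a, -v, 1 - w, "lower"), tolerance = 1e-14)
  }
})

test_that("time derivative matches a finite difference and flips sign at the mode", {
  pars <- random_core(100, seed = 33)
  ts <- exp(runif(100, log(0.05), log(3)))
  for (i in seq_len(100)) {
    a <- pars$a[i]; v <- pars$v[i]; w <- pars$w[i]; t <- ts[i]
    h <- 1e-6 * t
    fd <- (dwfpt(t + h, a, v, w) - dwfpt(t - h, a, v, w)) / (2 * h)
    an <- dwfpt_dt(t, a, v, w)
    if (abs(fd) > 1e-12)
      expect_equal(an, fd, tolerance = 1e-4, label = sprintf("case %d", i))
  }
  # derivative changes sign across the (numerically bracketed) mode
  grid <- seq(0.01, 3, by = 0.005)
  d <- dwfpt(grid, 1.2, 0.4, 0.45)
  mode_i <- which.max(d)
  expect_gt(dwfpt_dt(grid[mode_i - 2], 1.2, 0.4, 0.45), 0)
  expect_lt(dwfpt_dt(grid[mode_i + 2], 1.2, 0.4, 0.45), 0)
})

test_that("CDF agrees with adaptive quadrature of the density and is monotone", {
  pars <- random_core(25, seed = 55)
  ts <- exp(runif(25, log(0.05), log(3)))
  for (i in seq_len(25)) {
    a <- pars$a[i]; v <- pars$v[i]; w <- pars$w[i]; t <- ts[i]
    expect_equal(pwfpt(t, a, v, w, response = "lower"), cdf_oracle(t, a, v, w),
                 tolerance = 1e-7, label = sprintf("case %d", i))
  }
  grid <- seq(0.001, 6, length.out = 1000)
  pars <- random_core(20, seed = 56)
  for (i in seq_len(20)) {
    Fv <- pwfpt(grid, pars$a[i], pars$v[i], pars$w[i], response = "upper")
    expect_true(all(diff(Fv) >= -1e-12), label = sprintf("monotone %d", i))
    expect_true(all(Fv >= 0 & Fv <= 1))
  }
})

test_that("CDF boundary values: F(0) = 0 and F(Inf) sums to one", {
  expect_identical(pwfpt(0, 1, 0.5, 0.4), 0)
  expect_identical(pwfpt(-1, 1, 0.5, 0.4), 0)
  pars <- random_core(10, seed = 77)
  for (i in seq_len(10)) {
    fu <- pwfpt(Inf, pars$a[i], pars$v[i], pars$w[i], response = "upper")
    fl <- pwfpt(Inf, pars$a[i], pars$v[i], pars$w[i], response = "lower")
    expect_equal(fu + fl, 1, tolerance = 1e-8)
    expect_equal(fu, wdm_absorption(pars$a[i], pars$v[i], pars$w[i], "upper"),
                 tolerance = 1e-12)
  }
})

test_that("absorption probability: closed form, limits, and stability", {
  expect_equal(wdm_absorption(1, 1, 0.5, "upper"), 1 / (1 + exp(-1)),
               tolerance = 1e-7)
  # drift-free limit branch returns w
  expect_identical(wdm_absorption(1, 1e-12, 0.37, "upper"), 0.37)
  # complements are exact
  pars <- random_core(20, seed = 88)
  for (i in seq_len(20)) {
    expect_identical(wdm_absorption(pars$a[i], pars$v[i], pars$w[i], "upper") +
                     wdm_absorption(pars$a[i], pars$v[i], pars$w[i], "lower"), 1)
    expect_equal(wdm_absorption(pars$a[i], pars$v[i], pars$w[i], "upper"),
                 prob_upper_oracle(pars$a[i], pars$v[i], pars$w[i]),
                 tolerance = 1e-12)
  }
  # |2va| large enough to overflow the naive form stays in [0, 1]
  expect_equal(wdm_absorption(200, 2, 0.5, "upper"), 1, tolerance = 1e-12)
  p <- wdm_absorption(200, -2, 0.5, "upper")
  expect_true(p >= 0 && p < 1e-100)
})

test_that("invalid parameters raise structured errors; t <= 0 returns zero", {
  expect_error(dwfpt(0.3, -1, 0, 0.5), "boundary separation")
  expect_error(dwfpt(0.3, 1, Inf, 0.5), "drift")
  expect_error(dwfpt(0.3, 1, 0, 1.2), "starting point")
  expect_error(dwfpt(0.3, 1, 0, 0.5, precision = 1), "precision")
  expect_identical(dwfpt(c(-1, 0), 1, 0, 0.5), c(0, 0))
})
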
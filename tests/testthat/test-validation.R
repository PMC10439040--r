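# Validation harness: binomial meta-test, log-concavity scan machinery, the
# KS calibration study (small scale here), and the timing-harness contract.

test_that("binomial meta-probability is exact", {
  expect_equal(round(binomial_meta_probability(32, 3, 0.05), 2), 0.21)
  expect_identical(binomial_meta_probability(32, 0, 0.05), 1)
  # cross-check against direct summation and the regularized-beta route
  direct <- 1 - sum(choose(32, 0:2) * 0.05^(0:2) * 0.95^(32 - (0:2)))
  expect_equal(binomial_meta_probability(32, 3, 0.05), direct,
               tolerance = 1e-12)
  beta_route <- stats::pbeta(0.05, 3, 30)
  expect_equal(binomial_meta_probability(32, 3, 0.05), beta_route,
               tolerance = 1e-12)
})

# the scan machinery in miniature: central differences of an exact first
# derivative with escalation, applied to generic targets
scan_generic <- function(dh, grid, delta = 1e-3) {
  d2 <- (dh(grid + delta) - dh(grid - delta)) / (2 * delta)
  sum(d2 > 0)
}

test_that("second-derivative machinery: exact concave and convex negative controls", {
  grid <- seq(-3, 3, by = 0.01)
  expect_identical(scan_generic(function(x) -x, grid), 0L)     # gaussian h'
  expect_identical(scan_generic(function(x) 2 * x, grid),
                   length(grid))                               # h = x^2
})

test_that("log-concavity scan over random parameter sets finds no violations", {
  r <- log_concavity_scan(n_sets = 15, t_grid = seq(0.01, 5, by = 0.05),
                          seed = 42)
  expect_identical(r$post, 0)
  expect_equal(r$n_alpha, 15 * length(seq(0.01, 5, by = 0.05)))
})

test_that("KS calibration is near nominal and p-values are uniform (small scale)", {
  set.seed(99)
  cell <- diffsamp:::ks_cell("rs", Inf, FALSE, FALSE, n_sets = 150,
                             n_per = 500)
  share <- mean(cell$p < 0.05)
  expect_lt(abs(share - 0.05), 3 * sqrt(0.05 * 0.95 / 150) + 0.01)
  expect_gt(stats::ks.test(cell$p, "punif")$p.value, 0.001)
})

test_that("a deliberately wrong reference CDF is rejected with high power", {
  set.seed(100)
  n_sets <- 40
  p <- numeric(n_sets)
  for (i in seq_len(n_sets)) {
    a <- runif(1, 0.6, 2); v <- rnorm(1); w <- rbeta(1, 8, 8)
    t <- its_sample(500, a, v, w, "lower")
    # shift the sample by +0.05 s against the correct conditional CDF
    u <- pwfpt(t + 0.05, a, v, w, response = "lower") /
      wdm_absorption(a, v, w, "lower")
    p[i] <- stats::ks.test(u, "punif")$p.value
  }
  expect_gt(mean(p < 0.05), 0.5)
})

test_that("the asymptotic KS p-value matches stats::ks.test", {
  set.seed(101)
  u <- runif(1000)
  d <- max(abs(seq_along(u) / 1000 - sort(u)),
           abs(sort(u) - (seq_along(u) - 1) / 1000))
  expect_equal(diffsamp:::cpp_ks_pvalue(d, 1000),
               stats::ks.test(u, "punif")$p.value, tolerance = 1e-6)
})

test_that("timing harness covers the full condition grid and reports medians", {
  df <- speed_harness(sizes = c(1, 10), reps = 2, seed = 1)
  # 16 conditions x 4 methods x 2 sizes
  expect_identical(nrow(df), 16L * 4L * 2L)
  expect_true(all(df$median_seconds >= 0))
  expect_identical(length(unique(paste(df$bound, df$response, df$s_nu_on,
                                       df$s_w_on))), 16L)
})
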
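# Inverse transform sampling and rejection sampling, boundary-conditional
# and truncation-aware.

test_that("ITS quantiles invert the conditional CDF (roundtrip)", {
  a <- 1.3; v <- 0.5; w <- 0.4
  pb <- wdm_absorption(a, v, w, "lower")
  for (u in c(0.1, 0.5, 0.9)) {
    t <- diffsamp:::its_quantile(u, a, v, w, "lower")
    expect_equal(pwfpt(t, a, v, w, response = "lower") / pb, u,
                 tolerance = 1e-7)
  }
  # monotone: larger u maps to larger t
  us <- seq(0.02, 0.98, by = 0.02)
  ts <- diffsamp:::its_quantile(us, a, v, w, "lower")
  expect_true(all(diff(ts) > 0))
})

test_that("truncation is respected exactly", {
  set.seed(2)
  t1 <- its_sample(10000, 1, 0.3, 0.6, "upper", bound = 0.5)
  expect_lte(max(t1), 0.5)
  t2 <- rs_sample(10000, 1, 0.3, 0.6, "upper", bound = 0.5)
  expect_lte(max(t2), 0.5)
  # and the truncated draws follow the renormalized conditional CDF
  expect_gt(ks_p_cond(t1, 1, 0.3, 0.6, "upper", bound = 0.5), 0.001)
  expect_gt(ks_p_cond(t2, 1, 0.3, 0.6, "upper", bound = 0.5), 0.001)
})

test_that("ITS errors when no mass lies below the bound", {
  # strong positive drift, lower boundary, very tight bound
  expect_error(its_sample(10, 1.5, 8, 0.9, "lower", bound = 1e-4), "mass")
})

test_that("RS agrees with ITS at w = 0.5 and at w != 0.5", {
  set.seed(3)
  for (w in c(0.5, 0.3)) {
    t_rs <- rs_sample(10000, 1.2, 0.8, w, "lower")
    t_its <- its_sample(10000, 1.2, 0.8, w, "lower")
    expect_gt(stats::ks.test(t_rs, t_its)$p.value, 0.001,
              label = sprintf("w = %.1f", w))
  }
})

test_that("unconditional RS boundary frequencies match the closed form", {
  set.seed(4)
  r <- rs_sample(100000, 1, 0.3, 0.6, "both")
  p <- wdm_absorption(1, 0.3, 0.6, "upper")
  se <- sqrt(p * (1 - p) / 100000)
  expect_lt(abs(mean(r$response == "upper") - p), 3 * se)
})

test_that("all four methods are pairwise KS-compatible at fixed parameters", {
  set.seed(6)
  cases <- list(list(bound = Inf), list(bound = 0.5))
  for (cs in cases) {
    draws <- lapply(c("ars", "p-ars", "its", "rs"), function(m)
      sample_wiener(4000, 1.1, -0.4, 0.55, response = "lower",
                    bound = cs$bound, method = m)$q)
    pr <- utils::combn(4, 2, function(ij)
      stats::ks.test(draws[[ij[1]]], draws[[ij[2]]])$p.value)
    expect_true(all(stats::p.adjust(pr, "bonferroni") > 0.001),
                label = sprintf("bound = %s", cs$bound))
  }
})
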
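# Generic adaptive rejection sampling engine: hull construction, envelope
# inversion, squeeze/accept logic, updating, and the pseudo-adaptive variant.

test_that("initial hull on a normal target has decreasing slopes and dominating mass", {
  st <- init_hull(norm_target, start = 0.3)
  expect_true(all(diff(st$dhs) < 0))
  expect_gt(st$dhs[1], 0)
  expect_lt(st$dhs[length(st$dhs)], 0)
  # envelope mass >= the target's normalizing constant sqrt(2*pi)
  expect_gte(exp(diffsamp:::cpp_hull_total_logmass(st)), sqrt(2 * pi))
})

test_that("non-differentiable kink target |x| still yields a valid hull", {
  tgt <- function(x) c(-abs(x), -sign(x))
  st <- init_hull(tgt, start = 0.7)
  expect_true(all(diff(st$dhs) <= 0))
  expect_true(is.finite(diffsamp:::cpp_hull_total_logmass(st)))
})

test_that("linear target on a truncated domain gives the closed-form envelope mass", {
  tgt <- function(x) c(2 * x, 2)
  st <- init_hull(tgt, domain = c(-1, 1), start = 0)
  expect_equal(exp(diffsamp:::cpp_hull_total_logmass(st)),
               (exp(2) - exp(-2)) / 2, tolerance = 1e-10)
})

test_that("insert is idempotent for duplicates and never increases envelope mass", {
  st <- init_hull(norm_target, start = 0)
  st2 <- hull_insert(st, st$xs[2], st$hs[2], st$dhs[2])
  expect_equal(st2$xs, st$xs)
  set.seed(5)
  mass <- diffsamp:::cpp_hull_total_logmass(st)
  for (i in 1:1000) {
    x <- rnorm(1, sd = 2)
    hv <- norm_target(x)
    st <- hull_insert(st, x, hv[1], hv[2])
    m2 <- diffsamp:::cpp_hull_total_logmass(st)
    expect_lte(m2, mass + 1e-12)
    mass <- m2
  }
  # after many updates the envelope hugs the target: mass close to sqrt(2*pi)
  expect_lt(exp(mass), sqrt(2 * pi) * 1.001)
})

test_that("an insert tightens both hulls pointwise (3-point hull + 1 insert)", {
  st <- init_hull(norm_target, start = 0.4, k0 = 3)
  xnew <- 0.9
  hv <- norm_target(xnew)
  st2 <- hull_insert(st, xnew, hv[1], hv[2])
  grid <- seq(-3, 3, length.out = 1000)
  e1 <- diffsamp:::cpp_hull_eval(st, grid)
  e2 <- diffsamp:::cpp_hull_eval(st2, grid)
  expect_true(all(e2[, 1] <= e1[, 1] + 1e-10))  # upper hull comes down
  expect_true(all(e2[, 2] >= e1[, 2] - 1e-10))  # lower hull comes up
})

test_that("upper hull dominates the target which dominates the lower hull", {
  set.seed(9)
  for (rep in 1:20) {
    st <- init_hull(norm_target, start = runif(1, -1, 1))
    for (j in 1:sample(0:6, 1)) {
      x <- rnorm(1, sd = 1.5); hv <- norm_target(x)
      st <- hull_insert(st, x, hv[1], hv[2])
    }
    xs <- runif(200, -4, 4)
    ev <- diffsamp:::cpp_hull_eval(st, xs)
    h <- -xs^2 / 2
    expect_true(all(ev[, 1] >= h - 1e-10))
    expect_true(all(ev[, 2] <= h + 1e-10))
  }
})

test_that("single-segment envelope inversion matches numerical CDF inversion", {
  # one tangent with slope s on [z0, z1]: closed form
  # x* = z0 + log(1 + u*(exp(s(z1-z0)) - 1))/s
  tgt <- function(x) c(2 * x, 2)
  st <- init_hull(tgt, domain = c(-1, 1), start = 0)
  s <- 2; z0 <- -1; z1 <- 1
  for (u in c(0.1, 0.5, 0.9)) {
    xs <- sample_envelope(st, u)
    closed <- z0 + log1p(u * (exp(s * (z1 - z0)) - 1)) / s
    expect_equal(xs, closed, tolerance = 1e-10)
    # numeric inversion of the segment CDF
    Fseg <- function(x) (exp(s * (x - z0)) - 1) / (exp(s * (z1 - z0)) - 1)
    num <- stats::uniroot(function(x) Fseg(x) - u, c(z0, z1), tol = 1e-12)$root
    expect_equal(xs, num, tolerance = 1e-8)
  }
  # u = 0 maps to the (finite) left domain edge
  expect_equal(sample_envelope(st, 0), -1, tolerance = 1e-10)
})

test_that("envelope draws follow the piecewise-exponential density (chi-square GOF)", {
  st <- init_hull(norm_target, start = 0.2)
  for (x in c(-1.7, -0.6, 0.9, 1.8)) {
    hv <- norm_target(x); st <- hull_insert(st, x, hv[1], hv[2])
  }
  set.seed(31)
  draws <- diffsamp:::cpp_hull_sample_n(st, 100000)
  breaks <- c(-Inf, seq(-3.5, 3.5, length.out = 49), Inf)
  fin <- breaks[is.finite(breaks)]
  probs_mid <- diffsamp:::hull_bin_probs(st, fin)
  p_left <- NULL
  # tail probabilities from the total mass minus the covered part
  p_tails <- 1 - sum(probs_mid)
  obs <- table(cut(draws, breaks))
  counts <- as.vector(obs)
  counts_mid <- counts[2:(length(counts) - 1)]
  counts_tail <- counts[1] + counts[length(counts)]
  expected <- c(probs_mid, p_tails)
  chi <- stats::chisq.test(c(counts_mid, counts_tail), p = expected,
                           rescale.p = TRUE)
  expect_gt(chi$p.value, 0.001)
})

test_that("squeeze/accept: support points always squeeze; outside hull never squeezes", {
  st <- init_hull(norm_target, start = 0)
  x1 <- st$xs[2]
  r <- squeeze_accept(st, x1, u = 1 - 1e-12, target = norm_target)
  expect_identical(r$outcome, "accept_squeeze")
  expect_false(r$target_evaluated)
  # outside [x_1, x_k]: lower hull is -Inf so the squeeze cannot fire
  xo <- max(st$xs) + 1
  ev <- diffsamp:::cpp_hull_eval(st, xo)
  expect_identical(ev[1, 2], -Inf)
  r2 <- squeeze_accept(st, xo, u = 1e-9, target = norm_target)
  expect_true(r2$target_evaluated)
  expect_identical(r2$outcome, "accept_full")  # tiny u accepts under Eq. 3
  expect_gt(length(r2$state$xs), length(st$xs))  # updating step happened
})

test_that("long-run acceptance probability equals the mass ratio", {
  st <- init_hull(norm_target, start = 0.1)
  for (x in c(-1.2, 1.4)) { hv <- norm_target(x); st <- hull_insert(st, x, hv[1], hv[2]) }
  env_mass <- exp(diffsamp:::cpp_hull_total_logmass(st))
  p_expect <- sqrt(2 * pi) / env_mass
  set.seed(77)
  n <- 100000
  xs <- diffsamp:::cpp_hull_sample_n(st, n)
  ev <- diffsamp:::cpp_hull_eval(st, xs)
  acc <- runif(n) <= exp((-xs^2 / 2) - ev[, 1])
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(mean(acc) - p_expect), 3 * se)
})

test_that("ARS draws have the target's moments and match P-ARS in distribution", {
  set.seed(123)
  s <- ars_sample(norm_target, 100000, start = 0.5)
  expect_lt(abs(mean(s$x)), 0.02)
  expect_true(var(s$x) > 0.98 && var(s$x) < 1.02)
  expect_gt(stats::ks.test(s$x, "pnorm")$p.value, 0.001)
  sp <- ars_sample(norm_target, 10000, start = 0.5, keep_hull = FALSE)
  expect_gt(stats::ks.test(s$x[1:10000], sp$x)$p.value, 0.001)
  # P-ARS discards updates: its final hull stays at the initial size
  expect_lte(length(sp$hull$xs), 3)
})

test_that("squeeze-acceptance fraction grows and full evaluations become rare", {
  set.seed(99)
  s <- ars_sample(norm_target, 10000, start = 0)
  fr <- tapply(s$squeeze, rep(1:10, each = 1000), mean)
  expect_true(all(diff(fr) >= -0.02))
  expect_gt(fr[10], 0.98)
})

test_that("a non-log-concave target is detected in the updating step", {
  convex <- function(x) c(x^2, 2 * x)  # log-density x^2: convex
  expect_error(init_hull(convex, domain = c(-2, 2), start = 0.5),
               "log-concavity")
  # violation introduced by an insert on an otherwise fine hull
  st <- init_hull(norm_target, start = 0)
  expect_error(hull_insert(st, 0.65, norm_target(0.65)[1], 5), "log-concavity")
})

test_that("hull persistence round-trips through JSON", {
  st <- init_hull(norm_target, start = 0.2)
  hv <- norm_target(1.1); st <- hull_insert(st, 1.1, hv[1], hv[2])
  path <- tempfile(fileext = ".json")
  write_hull(st, path)
  st2 <- read_hull(path)
  expect_equal(st2$xs, st$xs, tolerance = 1e-15)
  expect_equal(st2$hs, st$hs, tolerance = 1e-15)
  expect_equal(st2$dhs, st$dhs, tolerance = 1e-15)
  expect_equal(st2$zs, st$zs, tolerance = 1e-12)
  expect_equal(st2$logJs, st$logJs, tolerance = 1e-12)
  expect_identical(st2$domain, c(-Inf, Inf))
})
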
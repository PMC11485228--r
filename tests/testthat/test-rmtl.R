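test_that("product-limit estimate matches hand calculation", {
  k <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(k$n_risk, c(3, 2, 1))
  ## a single censored subject leaves S at 1
  k2 <- km_fit(5, 0)
  expect_equal(k2$survival, 1)
  expect_equal(sum(k2$n_event), 0)
})

test_that("KM agrees with survival::survfit on censored data", {
  set.seed(11)
  t <- rexp(400, 0.4); cns <- runif(400, 0, 5)
  tt <- pmin(t, cns); e <- as.integer(t <= cns)
  k <- km_fit(tt, e)
  sf <- survival::survfit(survival::Surv(tt, e) ~ 1)
  expect_equal(k$event_times, sf$time)
  expect_equal(k$survival, sf$surv, tolerance = 1e-12)
  expect_equal(sqrt(k$greenwood_var), sf$std.err * sf$surv,
               tolerance = 1e-10)
})

test_that("Greenwood bands cover the true exponential curve", {
  ## pointwise coverage is correlated along one curve, so aggregate the
  ## fraction of covered grid points over replicate samples
  set.seed(12)
  grid <- seq(0.2, 4, by = 0.1)
  truth <- exp(-0.5 * grid)
  frac <- replicate(20, {
    t <- rexp(500, 0.5)
    k <- km_fit(t, rep(1, 500))
    idx <- findInterval(grid, k$event_times)
    s_hat <- ifelse(idx == 0, 1, k$survival[pmax(idx, 1)])
    se <- sqrt(ifelse(idx == 0, 0, k$greenwood_var[pmax(idx, 1)]))
    mean(abs(s_hat - truth) <= 1.96 * se)
  })
  expect_gte(mean(frac), 0.90)
  ## and the estimate itself is uniformly close to the truth
  expect_lt(1 - max(frac), 0.2)
})

test_that("RMTL reduces to rectangle integrals in degenerate cases", {
  ## everyone fails at t = 1, tau = 2: rmst = 1, rmtl = 1
  k <- km_fit(rep(1, 10), rep(1, 10))
  r <- rmtl(k, 2)
  expect_equal(r$rmst, 1)
  expect_equal(r$rmtl, 1)
  ## no events by tau: rmtl = 0 with zero variance
  k2 <- km_fit(rep(3, 10), rep(0, 10))
  r2 <- rmtl(k2, 3)
  expect_equal(r2$rmtl, 0)
  expect_equal(r2$variance, 0)
  ## horizon beyond the observed range is refused while S is still > 0
  expect_error(rmtl(k2, 5), "beyond")
  ## ... but is admissible once the curve has reached S = 0
  expect_equal(rmtl(k, 5)$rmtl, 4)
})

test_that("rmst + rmtl = tau for arbitrary censored curves", {
  set.seed(13)
  for (r in 1:10) {
    t <- rexp(100, runif(1, 0.1, 1)); cns <- runif(100, 0.5, 4)
    tt <- pmin(t, cns); e <- as.integer(t <= cns)
    tau <- runif(1, 0.3, max(tt))
    est <- rmtl(km_fit(tt, e), tau)
    expect_equal(est$rmst + est$rmtl, tau, tolerance = 1e-12)
    ## lean fast path agrees with the full estimator
    expect_equal(natexp:::.rmtl_value(tt, e, tau), est$rmtl,
                 tolerance = 1e-12)
  }
})

test_that("estimates are invariant to patient row order", {
  set.seed(14)
  t <- rexp(200, 0.3); cns <- runif(200, 0, 6)
  tt <- pmin(t, cns); e <- as.integer(t <= cns)
  perm <- sample(200)
  r1 <- rmtl(km_fit(tt, e), 2)
  r2 <- rmtl(km_fit(tt[perm], e[perm]), 2)
  expect_equal(r1$rmtl, r2$rmtl)
  expect_equal(r1$variance, r2$variance)
})

test_that("RMTL comparison handles symmetry and simple ratios", {
  k <- km_fit(rep(1, 20), rep(1, 20))
  r <- rmtl(k, 2)
  same <- rmtl_compare(r, r)
  expect_equal(same$ratio, 1)
  expect_equal(same$additional_days, 0)
  ## comparator loses twice the time of the primary group: ratio 0.5
  kp <- km_fit(rep(c(1, 2), each = 10), c(rep(1, 10), rep(0, 10)))
  rp <- rmtl(kp, 2)       # S = 0.5 on [1, 2): rmtl = 0.5
  cmp <- rmtl_compare(rp, r)
  expect_equal(cmp$ratio, 0.5)
  expect_true(cmp$ci[1] <= cmp$ratio && cmp$ratio <= cmp$ci[2])
})

test_that("zero RMTL in a group yields a flagged difference-only result", {
  k0 <- km_fit(rep(2, 10), rep(0, 10))     # no events
  k1 <- km_fit(rep(1, 10), rep(1, 10))
  cmp <- rmtl_compare(rmtl(k0, 2), rmtl(k1, 2))
  expect_false(cmp$ratio_defined)
  expect_true(is.na(cmp$ratio))
  expect_true(is.finite(cmp$p_value))
})
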
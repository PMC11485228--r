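test_that("df = (1,1) log-likelihood equals the Weibull-PH maximum", {
  d <- .fpm_testdata()
  f <- fpm_fit(d$t, d$e, d$g, 1, 1)
  oracle <- fit_weib_ph(d$t, d$e, d$g)
  expect_equal(f$loglik, -oracle$value, tolerance = 1e-4)
  ## and the AFT-parameterized fit from survreg agrees as well
  sr <- survival::survreg(survival::Surv(d$t, d$e) ~ d$g, dist = "weibull")
  expect_equal(f$loglik, as.numeric(logLik(sr)), tolerance = 1e-4)
})

test_that("Weibull shape and group effect are recovered at scale", {
  set.seed(72)
  n <- 5000
  g <- rep(0:1, each = n / 2)
  beta <- log(0.7); shape <- 1.5
  t <- rweib_ph(n, shape = shape, scale = 2, beta = beta, g = g)
  cns <- runif(n, 1, 8)
  tt <- pmin(t, cns); e <- as.integer(t <= cns)
  f <- fpm_fit(tt, e, g, 1, 1)
  se <- sqrt(diag(f$vcov))
  expect_lt(abs(f$gamma[["gamma1"]] - shape), 3 * se[["gamma1"]])
  expect_lt(abs(f$delta[["delta0"]] - beta), 3 * se[["delta0"]])
  ## df_group = 1 is the proportional sub-case: HR(t) is constant
  hr <- time_varying_hr(f, c(0.5, 1, 2, 4))
  expect_equal(hr$hr, rep(exp(f$delta[["delta0"]]), 4))
})

test_that("a constant group indicator yields zero deltas and HR 1", {
  d <- .fpm_testdata(1000)
  f <- fpm_fit(d$t, d$e, rep(0, length(d$t)), 1, 2)
  expect_equal(unname(f$delta), c(0, 0))
  hr <- time_varying_hr(f, c(0.5, 1, 2))
  expect_equal(hr$hr, rep(1, 3))
})

test_that("spline fit matches flexsurv's Royston-Parmar fit", {
  skip_if_not_installed("flexsurv")
  d <- .fpm_testdata()
  f <- fpm_fit(d$t, d$e, d$g, 1, 1)
  fs <- flexsurv::flexsurvspline(survival::Surv(t, e) ~ g,
                                 data = data.frame(t = d$t, e = d$e,
                                                   g = d$g),
                                 k = 0, scale = "hazard")
  expect_equal(f$loglik, as.numeric(logLik(fs)), tolerance = 1e-4)
})

test_that("AIC selection reports the grid minimum and honours ties", {
  d <- .fpm_testdata(1500)
  sel <- select_fpm(d$t, d$e, d$g)
  expect_equal(sel$aic, min(sel$aic_grid$aic, na.rm = TRUE))
  expect_true(sel$df_baseline %in% 1:3 && sel$df_group %in% 1:3)
})

test_that("selection is invariant to rescaling time from years to days", {
  d <- .fpm_testdata(1500)
  sel_y <- select_fpm(d$t, d$e, d$g)
  sel_d <- select_fpm(d$t * 365.25, d$e, d$g)
  expect_equal(sel_d$df_baseline, sel_y$df_baseline)
  expect_equal(sel_d$df_group, sel_y$df_group)
  ## log-likelihoods differ by the Jacobian constant n_events * log(365.25)
  expect_equal(sel_d$loglik, sel_y$loglik - sum(d$e) * log(365.25),
               tolerance = 1e-3)
})

test_that("pointwise confidence bands tighten with sample size", {
  fit_at <- function(n, seed) {
    set.seed(seed)
    g <- rep(0:1, each = n / 2)
    t <- rweib_ph(n, 1.3, 2, log(0.8), g)
    cns <- runif(n, 1, 6)
    fpm_fit(pmin(t, cns), as.integer(t <= cns), g, 1, 2)
  }
  small <- time_varying_hr(fit_at(2000, 73), 2)
  big <- time_varying_hr(fit_at(20000, 74), 2)
  expect_lt(big$se_log_hr, small$se_log_hr)
})

test_that("formula interface and accessors behave like a fitted model", {
  d <- .fpm_testdata(1200)
  df <- data.frame(time = d$t, status = d$e, era = factor(
    ifelse(d$g == 1, "primary", "comparator"),
    levels = c("comparator", "primary")))
  f <- fpm(survival::Surv(time, status) ~ era, df, 1, 1)
  expect_s3_class(f, "fpm")
  expect_length(coef(f), 3)
  expect_equal(AIC(f), f$aic)
  expect_error(time_varying_hr(f, 1e6), "time range")
  s <- predict(f, times = c(0.5, 1, 2), type = "survival", group = 0)
  expect_true(all(diff(s) < 0) && all(s > 0 & s < 1))
})
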
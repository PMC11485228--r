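test_that("Cox estimate is near zero under permuted null labels", {
  set.seed(41)
  t <- rexp(300, 0.5); e <- rep(1L, 300)
  zs <- replicate(30, {
    g <- sample(rep(0:1, each = 150))
    f <- cox_fit(t, e, g)
    f$log_hr / f$se
  })
  expect_lt(abs(mean(zs)), 3 / sqrt(30))
  expect_lt(mean(abs(zs) > 1.96), 0.2)
})

test_that("partial likelihood maximum matches a grid-search oracle", {
  t <- c(1, 2, 3, 4, 5, 6)
  e <- c(1, 1, 1, 1, 1, 0)
  g <- c(1, 0, 1, 0, 1, 0)
  f <- cox_fit(t, e, g)
  ## independent Breslow partial log-likelihood on a fine grid
  pll <- function(b) {
    idx <- order(t)
    tt <- t[idx]; ee <- e[idx]; gg <- g[idx]
    ll <- 0
    for (i in seq_along(tt)) {
      if (ee[i] == 0) next
      risk <- tt >= tt[i]
      ll <- ll + b * gg[i] - log(sum(exp(b * gg[risk])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-4)
  b_star <- grid[which.max(vapply(grid, pll, numeric(1)))]
  expect_equal(f$log_hr, b_star, tolerance = 1e-3)
})

test_that("a known hazard ratio is recovered at scale", {
  set.seed(42)
  n <- 5000
  g <- rep(0:1, each = n / 2)
  t <- rweib_ph(n, shape = 1, scale = 1 / 0.3, beta = log(0.7), g = g)
  cns <- runif(n, 1, 6)
  tt <- pmin(t, cns); e <- as.integer(t <= cns)
  f <- cox_fit(tt, e, g)
  expect_lt(abs(f$log_hr - log(0.7)), 3 * f$se)
  expect_lt(logrank_test(tt, e, g), 0.05)
})

test_that("no events in a group flags a monotone likelihood", {
  t <- c(1, 2, 3, 4, 5, 6)
  e <- c(1, 1, 1, 0, 0, 0)
  g <- c(0, 0, 0, 1, 1, 1)
  expect_warning(f <- cox_fit(t, e, g), "monotone")
  expect_true(f$flagged)
  expect_lte(abs(f$log_hr), 15)
})

test_that("both PH time transforms return valid p-values", {
  set.seed(43)
  t <- rexp(400, 0.5); cns <- runif(400, 0, 5)
  tt <- pmin(t, cns); e <- as.integer(t <= cns)
  g <- rep(0:1, each = 200)
  p_km <- ph_test(tt, e, g, transform = "km")
  p_id <- ph_test(tt, e, g, transform = "identity")
  expect_true(p_km >= 0 && p_km <= 1)
  expect_true(p_id >= 0 && p_id <= 1)
  expect_error(ph_test(c(1, 2), c(1, 0), c(0, 1)), "2 events")
})
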
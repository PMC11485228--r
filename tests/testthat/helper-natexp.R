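## shared fixtures, all generated in code

## minimal covariate specification: age only, no drift
min_covariates <- function() {
  list(list(name = "age", type = "age",
            mean = c(comparator = 73, primary = 73),
            sd = c(comparator = 5, primary = 5)))
}

## single constant-hazard outcome, administrative censoring at the
## horizon only (no dropout, no staggered entry)
exp_config <- function(lambda, n, seed = 1L, horizon = 6) {
  sim_config(
    n_comparator = n, n_primary = n,
    covariates = min_covariates(),
    outcomes = list(outcome_spec("evt", c(0, horizon), lambda)),
    censoring = list(
      comparator = list(admin_horizon = 100, entry_window = 0,
                        dropout_rate = 0),
      primary = list(admin_horizon = 100, entry_window = 0,
                     dropout_rate = 0)),
    missing_rate = 0, horizon = horizon, seed = seed)
}

## Weibull proportional-hazards sampler: H(t | g) = (t/b)^k * exp(beta*g)
rweib_ph <- function(n, shape, scale, beta = 0, g = rep(0, n)) {
  e <- rexp(n)
  scale * (e * exp(-beta * g))^(1 / shape)
}

## piecewise-exponential sampler by inversion (independent oracle for
## the generator's event-time machinery)
rpwexp <- function(n, breaks, rates) {
  widths <- diff(breaks)
  cumh <- c(0, cumsum(rates * widths))
  e <- rexp(n)
  t <- rep(Inf, n)
  for (k in seq_along(rates)) {
    hit <- is.infinite(t) & e <= cumh[k + 1] & rates[k] > 0
    t[hit] <- breaks[k] + (e[hit] - cumh[k]) / rates[k]
  }
  t
}

## independently coded Weibull-PH negative log-likelihood (oracle for
## the spline model's df = (1,1) anchor); param = (log H intercept,
## log-time slope, group log HR)
weib_ph_negll <- function(par, tdat, edat, gdat) {
  eta <- par[1] + par[2] * log(tdat) + par[3] * gdat
  -(sum(edat * (eta + log(par[2]) - log(tdat))) - sum(exp(eta)))
}

## fixed seeded censored Weibull-PH dataset shared by the spline-model
## anchor tests
.fpm_testdata <- function(n = 2000, beta = log(0.75), shape = 1.4) {
  set.seed(71)
  g <- rep(0:1, each = n / 2)
  t <- rweib_ph(n, shape = shape, scale = 2, beta = beta, g = g)
  cns <- runif(n, 0.5, 6)
  list(t = pmin(t, cns), e = as.integer(t <= cns), g = g)
}

fit_weib_ph <- function(tdat, edat, gdat) {
  opt <- optim(c(-1, 1, 0), weib_ph_negll, tdat = tdat, edat = edat,
               gdat = gdat, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  optim(opt$par, weib_ph_negll, tdat = tdat, edat = edat, gdat = gdat,
        method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
}
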
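test_that("uninformative covariates give intercept-only propensity scores", {
  set.seed(21)
  n <- 300
  rec <- data.frame(patient_id = as.character(1:n),
                    era = rep(c("comparator", "primary"), c(120, 180)),
                    age_years = sample(65:90, n, TRUE),
                    flag = rbinom(n, 1, 0.5))
  ## flag is independent of era: scores should sit near the primary share
  fit <- fit_propensity(rec, "flag")
  expect_true(all(abs(fit$scores - 0.6) < 0.1))
  ## a drifted covariate gets a coefficient of the right sign
  rec$drifted <- rbinom(n, 1, ifelse(rec$era == "primary", 0.7, 0.3))
  fit2 <- fit_propensity(rec, c("flag", "drifted"))
  expect_gt(fit2$coefficients[["drifted"]], 0)
})

test_that("propensity scores match an independent likelihood optimizer", {
  rec <- data.frame(
    patient_id = letters[1:8],
    era = rep(c("comparator", "primary"), each = 4),
    x = c(0, 0, 1, 0, 1, 1, 0, 1))
  fit <- fit_propensity(rec, "x")
  ## independent generic MLE of the same binomial likelihood
  y <- as.integer(rec$era == "primary")
  nll <- function(b) {
    eta <- b[1] + b[2] * rec$x
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  oracle <- plogis(opt$par[1] + opt$par[2] * rec$x)
  expect_equal(unname(fit$scores), oracle, tolerance = 1e-6)
})

test_that("matching handles identical multisets and zero calipers", {
  s <- c(a1 = .2, a2 = .4, a3 = .6, b1 = .2, b2 = .4, b3 = .6)
  era <- rep(c("comparator", "primary"), each = 3)
  m <- match_nearest(s, era, caliper = 0.1, seed = 1)
  expect_equal(nrow(m$pairs), 3L)
  expect_true(all(abs(m$pairs$ps_comparator - m$pairs$ps_primary) < 1e-12))
  ## distinct scores under a zero caliper cannot pair
  s2 <- c(a = .2, b = .3)
  m2 <- match_nearest(s2, c("comparator", "primary"), caliper = 0, seed = 1)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(sort(m2$unmatched), c("a", "b"))
})

test_that("greedy matching respects the caliper and brute-force bound", {
  ## brute-force maximum bipartite matching under the caliper
  max_matching <- function(sc, sp, cal) {
    adj <- lapply(seq_along(sp), function(j)
      which(abs(sc - sp[j]) <= cal))
    match_c <- rep(0L, length(sc))
    try_aug <- function(j, seen) {
      for (i in adj[[j]]) {
        if (seen[i]) next
        seen[i] <- TRUE
        if (match_c[i] == 0L || Recall(match_c[i], seen)) {
          match_c[i] <<- j
          return(TRUE)
        }
      }
      FALSE
    }
    n <- 0L
    for (j in seq_along(sp))
      if (try_aug(j, rep(FALSE, length(sc)))) n <- n + 1L
    n
  }
  set.seed(33)
  for (rep in 1:5) {
    sc <- runif(10); sp <- runif(10)
    s <- c(sc, sp)
    names(s) <- paste0("p", 1:20)
    era <- rep(c("comparator", "primary"), each = 10)
    m <- match_nearest(s, era, caliper = 0.05, seed = rep)
    expect_true(all(abs(m$pairs$ps_comparator - m$pairs$ps_primary) <= 0.05))
    expect_lte(nrow(m$pairs), max_matching(sc, sp, 0.05))
  }
})

test_that("standardized mean difference follows its definition", {
  expect_equal(standardized_mean_difference(rep(c(0, 1), c(6, 4)),
                                            rep(c(0, 1), c(3, 2)), "binary"),
               0)
  ## p_a = .5, p_b = .3 -> 0.2 / sqrt(0.23)
  a <- rep(c(0, 1), each = 10)
  b <- rep(c(0, 1), c(7, 3))
  expect_equal(standardized_mean_difference(a, b, "binary"),
               0.2 / sqrt((0.25 + 0.21) / 2), tolerance = 1e-12)
  ## continuous case against an independently coded formula
  set.seed(5)
  for (r in 1:5) {
    x <- rnorm(40, 1, 2); y <- rnorm(30, 0.5, 1.5)
    oracle <- abs(mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2)
    expect_equal(standardized_mean_difference(x, y, "continuous"), oracle)
  }
  ## degenerate groups: equal -> 0, unequal -> Inf
  expect_equal(standardized_mean_difference(rep(1, 5), rep(1, 3),
                                            "continuous"), 0)
  expect_equal(standardized_mean_difference(rep(1, 5), rep(2, 3),
                                            "continuous"), Inf)
})

test_that("coarsened exact matching counts pairs per stratum", {
  rec <- data.frame(patient_id = as.character(1:8),
                    era = rep(c("comparator", "primary"), c(3, 5)),
                    age_years = 70, sex = "F")
  m <- coarsened_exact_match(rec, cem_spec(c("age", "sex")), seed = 1)
  expect_equal(nrow(m$pairs), 3L)
  expect_true(all(m$pairs$stratum == m$pairs$stratum[1]))
  ## disjoint signatures across eras pair nothing
  rec$sex <- rep(c("F", "M"), c(3, 5))
  m2 <- coarsened_exact_match(rec, cem_spec(c("age", "sex")), seed = 1)
  expect_equal(nrow(m2$pairs), 0L)
})

test_that("CEM strata are seed-invariant and never worsen balance", {
  co <- generate_cohorts(scenario_config("paper-like", 1500, 1500, seed = 8))
  vars <- c("age", "sex", "race", "stroke", "hearing_loss")
  m1 <- coarsened_exact_match(co, cem_spec(vars), seed = 1)
  m2 <- coarsened_exact_match(co, cem_spec(vars), seed = 99)
  expect_setequal(unique(m1$pairs$stratum), unique(m2$pairs$stratum))
  m1 <- balance_table(co, vars, m1)
  bt <- m1$balance_table
  expect_true(all(bt$smd_after <= bt$smd_before + 1e-9))
})
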
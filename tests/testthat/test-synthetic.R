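test_that("zero baseline hazard forces censoring everywhere", {
  cfg <- sim_config(50, 50, covariates = min_covariates(),
                    outcomes = list(outcome_spec("evt", c(0, 6), 0)),
                    missing_rate = 0, seed = 4)
  co <- generate_cohorts(cfg)
  expect_true(all(co$evt_event == 0))
  expect_equal(co$evt_time, co$followup_end_years)
})

test_that("record invariants hold on the paper-like scenario", {
  co <- generate_cohorts(scenario_config("paper-like", 500, 500, seed = 2))
  expect_equal(nrow(co), 1000L)
  expect_true(all(co$age_years >= 65))
  expect_true(all(co$sex %in% c("F", "M", "missing")))
  for (oc in c("dementia", "zoster", "mortality", "negative_control")) {
    tm <- co[[paste0(oc, "_time")]]
    ev <- co[[paste0(oc, "_event")]]
    expect_true(all(tm <= co$followup_end_years + 1e-9))
    expect_true(all(tm[ev == 0] == co$followup_end_years[ev == 0]))
    expect_true(all(ev %in% 0:1))
  }
})

test_that("constant-hazard event proportion matches the exponential CDF", {
  n <- 5000
  co <- generate_cohorts(exp_config(0.2, n, seed = 10))
  p_true <- 1 - exp(-0.2 * 6)
  p_hat <- mean(co$evt_event)
  se <- sqrt(p_true * (1 - p_true) / (2 * n))
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("covariate prevalences per era match the configuration", {
  n <- 4000
  co <- generate_cohorts(scenario_config("paper-like", n, n, seed = 6))
  covs <- default_covariates()
  for (cv in covs[c(2, 10, 30, 42)]) {   # a spread of binary covariates
    for (er in c("comparator", "primary")) {
      p_hat <- mean(co[[cv$name]][co$era == er])
      p <- cv$p[[er]]
      expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
    }
  }
  ## drift shows up pre-match: several SMDs above 0.15
  idx_c <- co$era == "comparator"
  smds <- vapply(covs[-1], function(cv) {
    if (cv$type != "binary") return(0)
    standardized_mean_difference(co[[cv$name]][idx_c],
                                 co[[cv$name]][!idx_c], "binary")
  }, numeric(1))
  expect_gte(sum(smds > 0.15), 3)
})

test_that("null scenario gives exchangeable eras (log-rank calibration)", {
  n_rep <- 40
  rej <- 0
  for (r in seq_len(n_rep)) {
    co <- generate_cohorts(scenario_config("null", 400, 400,
                                           seed = 100 + r))
    p <- logrank_test(co$dementia_time, co$dementia_event, co$era)
    rej <- rej + (p < 0.05)
  }
  ## 3 binomial SEs around the nominal 5%
  expect_lte(rej / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("configuration errors are rejected", {
  expect_error(outcome_spec("x", c(0, 6), -0.1), "rates")
  expect_error(sim_config(0, 10), "count")
  expect_error(sim_config(10, 10, sex_prob = c(comparator = 1.2, primary = 0.5)),
               "probability")
})

test_that("identical seed and config give identical cohorts", {
  a <- generate_cohorts(scenario_config("paper-like", 300, 300, seed = 9))
  b <- generate_cohorts(scenario_config("paper-like", 300, 300, seed = 9))
  expect_identical(a, b)
  d <- generate_cohorts(scenario_config("paper-like", 300, 300, seed = 10))
  expect_false(identical(a, d))
})
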
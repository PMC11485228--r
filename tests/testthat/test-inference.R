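# four-stratum survival data with optional sex-specific era effect
.mod_data <- function(n_per = 150, era_hr = 0.7, extra_f = 1,
                      seed = 1) {
  set.seed(seed)
  strata <- expand.grid(sex = c("F", "M"),
                        era = c("comparator", "primary"),
                        stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    s <- strata[i, ]
    hr <- if (s$era == "primary") era_hr * (if (s$sex == "F") extra_f else 1)
    else 1
    t <- rexp(n_per, 0.25 * hr)
    cns <- runif(n_per, 2, 6)
    data.frame(time = pmin(t, cns), event = as.integer(t <= cns),
               era = s$era, sex = s$sex, stringsAsFactors = FALSE)
  }))
  out
}

test_that("permutation p-value follows the resampling formula and bounds", {
  ## an extreme sex-specific effect drives the exceedance count to zero
  d <- .mod_data(n_per = 250, era_hr = 0.9, extra_f = 0.05, seed = 2)
  pr <- permutation_moderation(d$time, d$event, d$era, d$sex, tau = 4,
                               n_perm = 1000, seed = 3)
  expect_equal(pr$p_value, (1 + pr$n_exceed) / (1 + pr$n_perm))
  expect_gte(pr$p_value, 1 / 1001)
  expect_lte(pr$p_value, 1)
  expect_equal(pr$n_exceed, 0L)
  expect_equal(pr$p_value, 1 / 1001)
  ## no moderation at all: most permutations exceed, p near 1
  d0 <- .mod_data(n_per = 200, era_hr = 1, extra_f = 1, seed = 4)
  pr0 <- permutation_moderation(d0$time, d0$event, d0$era, d0$sex, tau = 4,
                                n_perm = 200, seed = 5)
  expect_gt(pr0$p_value, 0.05)
})

test_that("permutation p is seed-stable and reproducible", {
  d <- .mod_data(seed = 6)
  a <- permutation_moderation(d$time, d$event, d$era, d$sex, tau = 4,
                              n_perm = 300, seed = 11)
  b <- permutation_moderation(d$time, d$event, d$era, d$sex, tau = 4,
                              n_perm = 300, seed = 11)
  expect_identical(a$p_value, b$p_value)
  c_ <- permutation_moderation(d$time, d$event, d$era, d$sex, tau = 4,
                               n_perm = 300, seed = 12)
  ## a different permutation stream agrees within binomial resampling error
  se <- sqrt(a$p_value * (1 - a$p_value) / 300)
  expect_lt(abs(a$p_value - c_$p_value), 4 * se + 2 / 301)
})

test_that("pair bootstrap collapses on degenerate pairs and covers the point", {
  pairs <- data.frame(time_comparator = rep(c(1, 2), 20),
                      event_comparator = rep(c(1, 0), 20),
                      time_primary = rep(c(1.5, 2), 20),
                      event_primary = rep(c(1, 0), 20))
  b <- pair_bootstrap_rmtl(pairs, tau = 2, n_boot = 200, seed = 7)
  expect_true(b$ci[1] <= b$estimate && b$estimate <= b$ci[2])
  ## identical duplicated pairs: every resample gives the same ratio
  same <- pairs[rep(1, 30), ]
  same$event_comparator <- 1; same$event_primary <- 1
  same$time_primary <- 1.5
  b2 <- pair_bootstrap_rmtl(same, tau = 2, n_boot = 100, seed = 8)
  expect_equal(diff(range(b2$estimates)), 0)
  expect_gte(b2$p_value, 1 / 100)
})

test_that("follow-up alignment applies the censoring rules", {
  rec <- data.frame(patient_id = c("c1", "p1", "c2", "p2"),
                    era = c("comparator", "primary", "comparator", "primary"),
                    followup_end_years = c(6, 4, 6, 5),
                    evt_time = c(5, 4, 6, 2), evt_event = c(1L, 0L, 0L, 1L))
  ## equal follow-up everywhere: identity
  eq <- rec; eq$followup_end_years <- 5; eq$evt_time <- pmin(eq$evt_time, 5)
  expect_equal(align_followup(eq, "cohortwise"), eq)
  ## cohortwise: both eras cut at min(6, 5) = 5
  al <- align_followup(rec, "cohortwise")
  expect_true(all(al$followup_end_years <= 5))
  expect_equal(al$evt_time[3], 5)
  expect_equal(al$evt_event[3], 0L)
  ## pairwise: event at 5 in a (6, 4) pair becomes censoring at 4
  pw <- align_followup(rec, "pairwise", pair_id = c(1, 1, 2, 2))
  expect_equal(pw$evt_time[1], 4)
  expect_equal(pw$evt_event[1], 0L)
  expect_error(align_followup(rec, "pairwise"), "pair_id")
})

test_that("alignment never lengthens follow-up nor adds events", {
  co <- generate_cohorts(scenario_config("paper-like", 400, 400, seed = 9))
  cm <- coarsened_exact_match(co, cem_spec(c("age", "sex")), seed = 1)
  idx <- match(c(cm$pairs$comparator_id, cm$pairs$primary_id),
               co$patient_id)
  sub <- co[idx, ]
  pid <- rep(cm$pairs$pair_id, 2)
  al <- align_followup(sub, "pairwise", pair_id = pid)
  expect_true(all(al$followup_end_years <= sub$followup_end_years))
  for (oc in c("dementia", "zoster", "negative_control")) {
    expect_lte(sum(al[[paste0(oc, "_event")]]),
               sum(sub[[paste0(oc, "_event")]]))
    expect_true(all(al[[paste0(oc, "_time")]] <=
                      sub[[paste0(oc, "_time")]]))
  }
  ## both members of every pair share the administrative horizon
  expect_true(all(tapply(al$followup_end_years, pid,
                         function(x) diff(range(x))) == 0))
})
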
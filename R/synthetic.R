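#' Specify a time-to-event outcome for the synthetic cohort generator
#'
#' Describes one outcome of the data-generating process: a
#' piecewise-constant baseline hazard, multiplicative covariate effects,
#' a piecewise-constant era effect on the log-hazard scale (so a waning
#' protective effect is a step function rising towards zero), and an
#' optional extra era effect in females (sex moderation).
#'
#' @param name outcome name; becomes the `<name>_time` / `<name>_event`
#'   column pair in the cohort table.
#' @param baseline_breaks strictly increasing break points partitioning
#'   `[0, horizon]`, starting at 0; the last break is the horizon.
#' @param baseline_rates per-year event rates, one per interval between
#'   consecutive breaks; all must be `>= 0`.
#' @param log_hr named numeric vector of log hazard ratios per covariate.
#'   Names are either a binary covariate name, `"age"` (effect per year,
#'   centred at 75), or `"covariate=level"` for one level of a
#'   categorical covariate.
#' @param era_breaks,era_log_hr piecewise-constant era effect (log HR of
#'   the primary era versus the comparator era) over follow-up time;
#'   `era_log_hr = 0` everywhere encodes a null (negative-control)
#'   outcome.
#' @param sex_interaction_log_hr additional era log HR applied to
#'   females in the primary era (0 = no sex moderation).
#' @param terminal logical; a terminal outcome (death) ends observation
#'   and censors all other outcomes.  At most one outcome may be
#'   terminal.
#' @return an object of class `outcome_spec`.
#' @seealso [sim_config()], [generate_cohorts()]
#' @export
outcome_spec <- function(name, baseline_breaks, baseline_rates,
                         log_hr = numeric(0),
                         era_breaks = baseline_breaks,
                         era_log_hr = 0,
                         sex_interaction_log_hr = 0,
                         terminal = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  baseline_breaks <- as.numeric(baseline_breaks)
  if (baseline_breaks[1] != 0 || is.unsorted(baseline_breaks, strictly = TRUE))
    stop("'baseline_breaks' must start at 0 and be strictly increasing",
         call. = FALSE)
  if (length(baseline_rates) != length(baseline_breaks) - 1L)
    stop("need one baseline rate per interval", call. = FALSE)
  if (any(baseline_rates < 0))
    stop("configuration error: baseline rates must be >= 0", call. = FALSE)
  era_breaks <- as.numeric(era_breaks)
  if (era_breaks[1] != 0 || is.unsorted(era_breaks, strictly = TRUE))
    stop("'era_breaks' must start at 0 and be strictly increasing",
         call. = FALSE)
  if (length(era_log_hr) == 1L)
    era_log_hr <- rep(era_log_hr, length(era_breaks) - 1L)
  if (length(era_log_hr) != length(era_breaks) - 1L)
    stop("need one era log HR per era interval", call. = FALSE)
  if (length(log_hr) && is.null(names(log_hr)))
    stop("'log_hr' must be a named vector", call. = FALSE)
  structure(
    list(name = name,
         baseline_breaks = baseline_breaks,
         baseline_rates = as.numeric(baseline_rates),
         log_hr = log_hr,
         era_breaks = era_breaks,
         era_log_hr = as.numeric(era_log_hr),
         sex_interaction_log_hr = as.numeric(sex_interaction_log_hr),
         terminal = isTRUE(terminal)),
    class = "outcome_spec")
}

#' Simulation configuration for a synthetic two-era cohort
#'
#' Bundles everything the generator needs: cohort sizes, the covariate
#' specification (with era-specific prevalences encoding population
#' drift), outcome specifications, per-era censoring, demographic
#' missingness and the master seed.
#'
#' Censoring emulates a live EHR network with staggered entry: each
#' patient enters uniformly within their era's enrolment window, and
#' administrative follow-up is `admin_horizon - entry` years (capped at
#' the global horizon), with additional exponential early dropout.
#'
#' @param n_comparator,n_primary cohort sizes (patients per era).
#' @param covariates list of covariate specifications as produced by
#'   [default_covariates()]; each element is a list with `name`, `type`
#'   (`"binary"`, `"categorical"` or `"age"`) and era-specific
#'   probabilities.
#' @param sex_prob probability of female sex per era, named
#'   `comparator` / `primary`.
#' @param outcomes list of [outcome_spec()] objects.
#' @param censoring per-era list with elements `admin_horizon` (years
#'   from era start to the administrative data cut), `entry_window`
#'   (years over which entry is uniform) and `dropout_rate` (per-year
#'   exponential loss to follow-up).
#' @param missing_rate probability that each of sex, race and ethnicity
#'   is recorded as the explicit category `"missing"`.
#' @param horizon maximum follow-up in years.
#' @param seed master integer seed; all randomness derives from it via
#'   fixed per-concern sub-seeds (covariates, censoring, one per
#'   outcome, missingness), so adding a covariate does not perturb the
#'   event draws.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_comparator, n_primary,
                       covariates = default_covariates(),
                       sex_prob = c(comparator = 0.56, primary = 0.56),
                       outcomes = default_outcomes(),
                       censoring = default_censoring(),
                       missing_rate = 0.02,
                       horizon = 6,
                       seed = 1L) {
  n_comparator <- check_count(n_comparator, "n_comparator")
  n_primary <- check_count(n_primary, "n_primary")
  check_prob(sex_prob, "sex_prob")
  check_prob(missing_rate, "missing_rate")
  stopifnot(horizon > 0)
  if (!all(c("comparator", "primary") %in% names(sex_prob)))
    stop("'sex_prob' needs elements 'comparator' and 'primary'", call. = FALSE)
  for (cv in covariates) {
    if (cv$type == "binary") check_prob(cv$p, cv$name)
    if (cv$type == "categorical") {
      for (er in c("comparator", "primary")) {
        check_prob(cv$probs[[er]], cv$name)
        if (abs(sum(cv$probs[[er]]) - 1) > 1e-8)
          stop(sprintf("configuration error: level probabilities of '%s' must sum to 1",
                       cv$name), call. = FALSE)
      }
    }
  }
  if (sum(vapply(outcomes, function(o) o$terminal, logical(1))) > 1L)
    stop("at most one terminal outcome is supported", call. = FALSE)
  for (er in c("comparator", "primary")) {
    cs <- censoring[[er]]
    if (is.null(cs) || cs$admin_horizon <= 0 || cs$entry_window < 0 ||
        cs$dropout_rate < 0)
      stop("configuration error: invalid censoring spec", call. = FALSE)
  }
  structure(
    list(n_comparator = n_comparator, n_primary = n_primary,
         covariates = covariates, sex_prob = sex_prob,
         outcomes = outcomes, censoring = censoring,
         missing_rate = missing_rate, horizon = horizon,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Two-era synthetic cohort configuration\n")
  cat(sprintf("  comparator n = %d, primary n = %d\n",
              x$n_comparator, x$n_primary))
  cat(sprintf("  covariates: %d   outcomes: %s\n", length(x$covariates),
              paste(vapply(x$outcomes, `[[`, "", "name"), collapse = ", ")))
  cat(sprintf("  horizon %.2f y, missing rate %.3f, seed %d\n",
              x$horizon, x$missing_rate, x$seed))
  invisible(x)
}

#' Default covariate specification (EHR-style, with era drift)
#'
#' Around sixty covariates typical of an older-adult EHR extract: age,
#' sex, race, ethnicity, marital status and ~50 binary comorbidity /
#' healthcare-utilisation flags.  Prevalences differ between eras to
#' emulate drift in the vaccinated population; with `drift = TRUE`
#' several covariates (influenza and pneumococcal vaccination, Z-code
#' utilisation flags, vitamin D deficiency) have pre-match standardized
#' mean differences above 0.15.
#'
#' @param drift logical; `FALSE` sets the primary-era prevalences equal
#'   to the comparator-era ones (no population drift).
#' @return list of covariate specifications for [sim_config()].
#' @export
default_covariates <- function(drift = TRUE) {
  ## name, comparator prevalence, primary prevalence
  bin <- rbind(
    c("hypertension",            .62, .60), c("hyperlipidemia",    .55, .57),
    c("diabetes",                .28, .27), c("obesity",           .18, .24),
    c("ischemic_heart_disease",  .22, .19), c("atrial_fibrillation", .12, .11),
    c("heart_failure",           .09, .08), c("stroke",            .07, .065),
    c("peripheral_vascular",     .08, .07), c("copd",              .12, .11),
    c("asthma",                  .08, .09), c("sleep_apnea",       .09, .13),
    c("chronic_kidney_disease",  .11, .12), c("liver_disease",     .04, .045),
    c("gi_disease",              .30, .31), c("anemia",            .14, .15),
    c("skin_cancer",             .10, .11), c("breast_cancer",     .05, .05),
    c("prostate_cancer",         .06, .055), c("other_cancer",     .12, .12),
    c("depression",              .15, .18), c("anxiety",           .14, .19),
    c("substance_use",           .05, .06), c("psychotic_disorder", .010, .010),
    c("bipolar_disorder",        .015, .017), c("hypothyroidism",  .14, .15),
    c("vitamin_b_deficiency",    .06, .08), c("vitamin_d_deficiency", .12, .18),
    c("osteoarthritis",          .30, .33), c("osteoporosis",      .12, .11),
    c("rheumatoid_arthritis",    .04, .04), c("back_pain",         .28, .31),
    c("hearing_loss",            .10, .12), c("visual_impairment", .06, .06),
    c("cataract",                .20, .18), c("glaucoma",          .08, .08),
    c("migraine",                .03, .035), c("epilepsy",         .012, .013),
    c("herpes_zoster_history",   .04, .05), c("herpes_simplex_history", .015, .02),
    c("influenza_vaccination",   .42, .55), c("pneumococcal_vaccination", .30, .42),
    c("z59_deprivation",         .010, .020), c("z_long_term_medication", .18, .28),
    c("z_screening_encounter",   .25, .35), c("z_personal_risk_factors", .08, .12),
    c("nicotine_dependence",     .08, .09), c("alcohol_related",   .03, .035),
    c("insomnia",                .08, .10), c("dizziness",         .09, .10),
    c("syncope",                 .05, .05), c("falls",             .06, .07),
    c("urinary_incontinence",    .07, .08), c("frailty_marker",    .03, .04)
  )
  covs <- apply(bin, 1L, function(r) {
    p <- c(comparator = as.numeric(r[2]),
           primary = if (drift) as.numeric(r[3]) else as.numeric(r[2]))
    list(name = r[1], type = "binary", p = p)
  })
  cat_spec <- function(name, levels, pc, pp) {
    list(name = name, type = "categorical", levels = levels,
         probs = list(comparator = pc, primary = if (drift) pp else pc))
  }
  covs <- c(
    list(list(name = "age", type = "age",
              mean = c(comparator = 73.5, primary = if (drift) 73.0 else 73.5),
              sd = c(comparator = 6.0, primary = 6.0))),
    covs,
    list(
      cat_spec("race", c("white", "black", "asian", "other"),
               c(.74, .13, .05, .08), c(.71, .13, .06, .10)),
      cat_spec("ethnicity", c("not_hispanic", "hispanic"),
               c(.90, .10), c(.88, .12)),
      cat_spec("marital_status", c("married", "single", "other"),
               c(.55, .13, .32), c(.53, .14, .33))
    ))
  covs
}

#' Default outcome specifications
#'
#' Four outcomes mirroring a shingles-vaccine step-change design: a
#' dementia-like outcome whose protective era effect wanes over
#' follow-up and is stronger in females; a zoster-like outcome with a
#' stronger, also waning, protective era effect; all-cause mortality
#' with a null era effect (terminal: death censors the other outcomes);
#' and a negative-control outcome with a null era effect.
#'
#' @param horizon follow-up horizon in years.
#' @return list of [outcome_spec()] objects.
#' @export
default_outcomes <- function(horizon = 6) {
  list(
    outcome_spec(
      "dementia",
      baseline_breaks = c(0, 2, 4, horizon),
      baseline_rates = c(0.014, 0.017, 0.020),
      log_hr = c(age = 0.10, stroke = 0.5, diabetes = 0.25,
                 depression = 0.35, hearing_loss = 0.30,
                 vitamin_b_deficiency = 0.20,
                 herpes_zoster_history = 0.15, epilepsy = 0.40),
      era_breaks = c(0, 1, 2, 3, 4, 5, horizon),
      era_log_hr = log(c(0.78, 0.83, 0.885, 0.94, 0.98, 1.00)),
      sex_interaction_log_hr = log(0.88)),
    outcome_spec(
      "zoster",
      baseline_breaks = c(0, horizon),
      baseline_rates = 0.010,
      log_hr = c(age = 0.02, herpes_zoster_history = 0.70,
                 diabetes = 0.20, depression = 0.20),
      era_breaks = c(0, 2, 4, horizon),
      era_log_hr = log(c(0.48, 0.68, 0.88))),
    outcome_spec(
      "mortality",
      baseline_breaks = c(0, 2, 4, horizon),
      baseline_rates = c(0.030, 0.036, 0.042),
      log_hr = c(age = 0.09, heart_failure = 0.7, other_cancer = 0.5,
                 copd = 0.4, chronic_kidney_disease = 0.4,
                 diabetes = 0.3, frailty_marker = 0.6),
      era_log_hr = 0, terminal = TRUE),
    outcome_spec(
      "negative_control",
      baseline_breaks = c(0, horizon),
      baseline_rates = 0.040,
      log_hr = c(age = 0.01, back_pain = 0.5, osteoarthritis = 0.4),
      era_log_hr = 0)
  )
}

#' Default per-era censoring specification
#'
#' Staggered uniform entry over a 3-year enrolment window per era, with
#' administrative horizons chosen so median follow-up is about 6.0 years
#' in the comparator era and about 4.15 years in the primary era, plus
#' 2% per-year early dropout.
#'
#' @return per-era censoring list for [sim_config()].
#' @export
default_censoring <- function() {
  list(comparator = list(admin_horizon = 8.65, entry_window = 3,
                         dropout_rate = 0.02),
       primary = list(admin_horizon = 6.12, entry_window = 3,
                      dropout_rate = 0.02))
}

## linear predictor for one outcome given the covariate data
.linear_predictor <- function(spec, dat) {
  lp <- numeric(nrow(dat))
  if (!length(spec$log_hr)) return(lp)
  for (nm in names(spec$log_hr)) {
    beta <- spec$log_hr[[nm]]
    if (nm == "age") {
      lp <- lp + beta * (dat$age_years - 75)
    } else if (grepl("=", nm, fixed = TRUE)) {
      parts <- strsplit(nm, "=", fixed = TRUE)[[1]]
      if (!parts[1] %in% names(dat))
        stop(sprintf("unknown covariate '%s' in log_hr", parts[1]), call. = FALSE)
      lp <- lp + beta * (dat[[parts[1]]] == parts[2])
    } else {
      if (!nm %in% names(dat))
        stop(sprintf("unknown covariate '%s' in log_hr", nm), call. = FALSE)
      lp <- lp + beta * as.numeric(dat[[nm]])
    }
  }
  lp
}

## piecewise-exponential inversion: draw event times given per-subject
## rate multipliers exp(lp) and time-varying multipliers per bin
.draw_event_times <- function(spec, lp, primary, female, horizon) {
  breaks <- sort(unique(c(spec$baseline_breaks, spec$era_breaks, horizon)))
  breaks <- breaks[breaks <= horizon]
  nb <- length(breaks) - 1L
  mids <- (breaks[-1] + breaks[-(nb + 1L)]) / 2
  base <- spec$baseline_rates[findInterval(mids, spec$baseline_breaks,
                                           rightmost.closed = TRUE)]
  era <- spec$era_log_hr[findInterval(mids, spec$era_breaks,
                                      rightmost.closed = TRUE)]
  widths <- diff(breaks)
  n <- length(lp)
  ## n x nb matrix of per-subject per-bin rates
  mult <- exp(lp + (primary * spec$sex_interaction_log_hr) * female)
  rate <- outer(mult, base) * exp(outer(primary, era))
  cumh <- matrix(0, n, nb + 1L) # cumulative hazard at the breaks
  for (k in seq_len(nb)) cumh[, k + 1L] <- cumh[, k] + rate[, k] * widths[k]
  e <- rexp(n)
  t_evt <- rep(Inf, n)
  for (k in seq_len(nb)) {
    hit <- is.infinite(t_evt) & e <= cumh[, k + 1L] & rate[, k] > 0
    t_evt[hit] <- breaks[k] + (e[hit] - cumh[hit, k]) / rate[hit, k]
  }
  t_evt
}

#' Generate a synthetic two-era cohort
#'
#' Draws a patient-level cohort table from the data-generating process
#' described by a [sim_config()]: covariates with era-specific
#' prevalences, event times from piecewise-exponential hazards
#' \eqn{h(t) = h_0(t)\exp(\beta'x + w(t)\,\mathrm{era} + \gamma\,
#' \mathrm{era}\cdot\mathrm{female})}, era-dependent administrative
#' censoring with staggered entry and exponential dropout, and a
#' terminal (death) outcome that censors the others.  Identical seed and
#' config give identical output.
#'
#' @param config a [sim_config()].
#' @return a `data.frame`, one row per patient, with columns
#'   `patient_id`, `era`, `entry_offset_months`, `age_years`, `sex`,
#'   one column per covariate, `followup_end_years`, and per outcome
#'   `<name>_time` / `<name>_event`.  Times are years, rounded to six
#'   decimals; `event == 0` implies `time == followup_end_years`.
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_comparator + config$n_primary
  era <- rep(c("comparator", "primary"),
             c(config$n_comparator, config$n_primary))
  primary <- as.numeric(era == "primary")

  ## --- covariate stream -------------------------------------------------
  dat <- with_seed(sub_seed(config$seed, 101), {
    d <- data.frame(
      patient_id = sprintf("%s%06d", ifelse(primary == 1, "P", "C"),
                           c(seq_len(config$n_comparator),
                             seq_len(config$n_primary))),
      era = era, stringsAsFactors = FALSE)
    sexp <- config$sex_prob[era]
    d$sex_true <- ifelse(runif(n) < sexp, "F", "M")
    for (cv in config$covariates) {
      if (cv$type == "age") {
        ag <- round(cv$mean[era] + cv$sd[era] * stats::rnorm(n))
        d$age_years <- as.integer(pmin(pmax(ag, 65), 100))
      } else if (cv$type == "binary") {
        d[[cv$name]] <- as.integer(runif(n) < cv$p[era])
      } else {
        u <- runif(n)
        lv <- character(n)
        for (er in c("comparator", "primary")) {
          idx <- era == er
          cuts <- cumsum(cv$probs[[er]])
          lv[idx] <- cv$levels[1L + findInterval(u[idx], cuts,
                                                 left.open = TRUE)]
        }
        d[[cv$name]] <- lv
      }
    }
    d
  })
  female <- as.numeric(dat$sex_true == "F")

  ## --- censoring stream -------------------------------------------------
  cens <- with_seed(sub_seed(config$seed, 202), {
    entry <- numeric(n)
    cap <- numeric(n)
    drop_t <- rep(Inf, n)
    for (er in c("comparator", "primary")) {
      idx <- era == er
      cs <- config$censoring[[er]]
      entry[idx] <- runif(sum(idx), 0, cs$entry_window)
      cap[idx] <- pmin(config$horizon,
                       pmax(cs$admin_horizon - entry[idx], 0.01))
      if (cs$dropout_rate > 0)
        drop_t[idx] <- rexp(sum(idx), cs$dropout_rate)
    }
    list(entry = entry, cap = pmin(cap, drop_t))
  })

  ## --- event streams (one per outcome) ----------------------------------
  raw_times <- list()
  for (i in seq_along(config$outcomes)) {
    spec <- config$outcomes[[i]]
    lp <- .linear_predictor(spec, dat)
    raw_times[[spec$name]] <- with_seed(
      sub_seed(config$seed, 300 + 37 * i),
      .draw_event_times(spec, lp, primary, female, config$horizon))
  }

  ## terminal outcome truncates observation for everything else
  terminal <- vapply(config$outcomes, function(o) o$terminal, logical(1))
  followup_raw <- cens$cap
  if (any(terminal)) {
    death_t <- raw_times[[config$outcomes[[which(terminal)]]$name]]
    followup_raw <- pmin(followup_raw, death_t)
  }
  followup <- round(followup_raw, 6)

  out <- dat
  out$sex <- out$sex_true
  out$sex_true <- NULL
  out$entry_offset_months <- round(cens$entry * 12, 3)

  ## --- missingness stream ------------------------------------------------
  if (config$missing_rate > 0) {
    out <- with_seed(sub_seed(config$seed, 404), {
      for (f in intersect(c("sex", "race", "ethnicity"), names(out)))
        out[[f]][runif(n) < config$missing_rate] <- "missing"
      out
    })
  }

  out$followup_end_years <- followup
  for (spec in config$outcomes) {
    t_evt <- raw_times[[spec$name]]
    if (spec$terminal) {
      evt <- as.integer(t_evt <= cens$cap)
      tm <- followup
    } else {
      evt <- as.integer(t_evt <= followup_raw)
      tm <- ifelse(evt == 1L, pmin(round(t_evt, 6), followup), followup)
    }
    out[[paste0(spec$name, "_time")]] <- tm
    out[[paste0(spec$name, "_event")]] <- evt
  }

  ## stable column order: ids, demographics, covariates, follow-up, outcomes
  covnames <- setdiff(vapply(config$covariates, `[[`, "", "name"), "age")
  ord <- c("patient_id", "era", "entry_offset_months", "age_years", "sex",
           covnames, "followup_end_years",
           as.vector(rbind(paste0(names(raw_times), "_time"),
                           paste0(names(raw_times), "_event"))))
  out[, ord]
}
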
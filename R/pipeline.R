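#' Analysis configuration for the two-era pipeline
#'
#' One row of the analysis grid: which outcome, how to match, which
#' window/landmark/horizon, optional follow-up alignment or restriction,
#' sex stratification with the permutation moderation test, and the
#' variance method.
#'
#' @param outcome outcome name (`<outcome>_time` / `<outcome>_event`
#'   columns must exist in the cohort table).
#' @param matching `"propensity"` or `"cem"`.
#' @param caliper propensity-score caliper (raw probability scale).
#' @param covariates covariate columns for the propensity model;
#'   `NULL` uses every non-outcome, non-administrative column (the
#'   matching step never sees outcome columns).
#' @param cem_variables variables for coarsened exact matching; `NULL`
#'   uses age, sex, race and the neurological comorbidity flags present.
#' @param exposure_window_months if set, restrict both eras to patients
#'   vaccinated within this many months of the step change (comparator:
#'   last months of its window; primary: first months).
#' @param landmark follow-up entry time in years (events or censorings
#'   before it are excluded and time is re-origined).
#' @param horizon end of follow-up in years post-vaccination.
#' @param followup_alignment `"none"`, `"cohortwise"` or `"pairwise"`.
#' @param restrict_followup if set, administratively censor everyone at
#'   this many years post-vaccination and additionally report a Cox
#'   hazard ratio and log-rank test (for restricted windows in which
#'   proportional hazards is plausible).
#' @param sex_stratify also analyse females and males separately and
#'   run the permutation moderation test.
#' @param variance `"parametric"` (delta-method z-test) or
#'   `"bootstrap"` (matched-pair bootstrap; requires pairs).
#' @param n_perm,n_boot resampling sizes.
#' @param alpha two-sided level.
#' @param seed integer seed governing matching order, permutations and
#'   bootstrap.
#' @param analysis_id free-text row label.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(outcome,
                            matching = c("propensity", "cem"),
                            caliper = 0.1,
                            covariates = NULL,
                            cem_variables = NULL,
                            exposure_window_months = NULL,
                            landmark = 0.25,
                            horizon = 6,
                            followup_alignment = c("none", "cohortwise",
                                                   "pairwise"),
                            restrict_followup = NULL,
                            sex_stratify = FALSE,
                            variance = c("parametric", "bootstrap"),
                            n_perm = 1000L, n_boot = 1000L,
                            alpha = 0.05, seed = 1L,
                            analysis_id = NULL) {
  matching <- match.arg(matching)
  followup_alignment <- match.arg(followup_alignment)
  variance <- match.arg(variance)
  stopifnot(horizon > landmark, alpha > 0, alpha < 1, caliper >= 0)
  if (!is.null(restrict_followup) && restrict_followup <= landmark)
    stop("'restrict_followup' must exceed the landmark", call. = FALSE)
  structure(
    list(outcome = outcome, matching = matching, caliper = caliper,
         covariates = covariates, cem_variables = cem_variables,
         exposure_window_months = exposure_window_months,
         landmark = landmark, horizon = horizon,
         followup_alignment = followup_alignment,
         restrict_followup = restrict_followup,
         sex_stratify = isTRUE(sex_stratify), variance = variance,
         n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
         alpha = alpha, seed = as.integer(seed),
         analysis_id = analysis_id %||%
           paste0(outcome, "_", matching)),
    class = "analysis_config")
}

## covariate columns available for matching: everything that is not an
## identifier, administrative field or outcome column (design firewall:
## matching never reads outcomes)
.matching_covariates <- function(cohort) {
  drop <- c("patient_id", "era", "entry_offset_months", "age_years",
            "followup_end_years",
            grep("(_time$)|(_event$)", names(cohort), value = TRUE))
  c("age", setdiff(names(cohort), drop))
}

.default_cem_variables <- function(cohort) {
  neuro <- intersect(c("stroke", "epilepsy", "migraine", "hearing_loss"),
                     names(cohort))
  c("age", "sex", intersect("race", names(cohort)), neuro)
}

## landmark transform for one outcome: drop pre-landmark rows, re-origin
.apply_landmark <- function(dat, outcome, landmark) {
  tc <- paste0(outcome, "_time")
  keep <- dat[[tc]] > landmark
  dat <- dat[keep, , drop = FALSE]
  dat[[tc]] <- dat[[tc]] - landmark
  dat$followup_end_years <- pmax(dat$followup_end_years - landmark, 0)
  dat
}

## administrative censoring of everyone at `cut` years post-vaccination
.restrict_followup <- function(dat, cut) {
  tcols <- grep("_time$", names(dat), value = TRUE)
  for (tc in tcols) {
    ec <- sub("_time$", "_event", tc)
    over <- dat[[tc]] > cut
    dat[[ec]][over] <- 0L
    dat[[tc]][over] <- cut
  }
  dat$followup_end_years <- pmin(dat$followup_end_years, cut)
  dat
}

.result_row <- function(config, n_pairs, cmp = NULL, ph_p = NA_real_,
                        cox = NULL, logrank_p = NA_real_, perm = NULL,
                        boot = NULL, note = "", subgroup = "all") {
  data.frame(
    analysis_id = config$analysis_id, outcome = config$outcome,
    subgroup = subgroup, matching = config$matching,
    n_pairs = n_pairs,
    rmtl_primary = if (!is.null(cmp)) cmp$rmtl_primary$rmtl else NA_real_,
    rmtl_comparator = if (!is.null(cmp)) cmp$rmtl_comparator$rmtl
    else NA_real_,
    rmtl_ratio = if (!is.null(boot)) boot$estimate
    else if (!is.null(cmp)) cmp$ratio else NA_real_,
    ci_low = if (!is.null(boot)) boot$ci[1]
    else if (!is.null(cmp)) cmp$ci[1] else NA_real_,
    ci_high = if (!is.null(boot)) boot$ci[2]
    else if (!is.null(cmp)) cmp$ci[2] else NA_real_,
    p_value = if (!is.null(boot)) boot$p_value
    else if (!is.null(cmp)) cmp$p_value else NA_real_,
    additional_days = if (!is.null(cmp)) cmp$additional_days else NA_real_,
    ad_ci_low = if (!is.null(cmp)) cmp$additional_days_ci[1] else NA_real_,
    ad_ci_high = if (!is.null(cmp)) cmp$additional_days_ci[2] else NA_real_,
    ph_p = ph_p,
    cox_hr = if (!is.null(cox)) cox$hr else NA_real_,
    cox_ci_low = if (!is.null(cox)) cox$ci[1] else NA_real_,
    cox_ci_high = if (!is.null(cox)) cox$ci[2] else NA_real_,
    logrank_p = logrank_p,
    moderation_p = if (!is.null(perm)) perm$p_value else NA_real_,
    seed = config$seed, note = note,
    stringsAsFactors = FALSE)
}

#' Run one configured two-era analysis on a cohort table
#'
#' Executes the full pipeline for one [analysis_config()]: optional
#' exposure-window restriction, matching (propensity or CEM — on
#' covariates only, never outcomes), optional follow-up alignment,
#' optional administrative follow-up restriction, the landmark
#' transform, Kaplan-Meier estimation per era, the proportional-hazards
#' diagnostic, the RMTL comparison (parametric or pair-bootstrap
#' variance), a Cox/log-rank analysis when the follow-up is restricted,
#' and optionally sex-stratified estimates with the permutation
#' moderation test.
#'
#' @param cohort cohort `data.frame` (see [generate_cohorts()] /
#'   [read_cohort_table()]).
#' @param config an [analysis_config()].
#' @return an object of class `natexp_result`: `rows` (results table,
#'   one row per subgroup), `comparison`, `km` (per-era curves),
#'   `matched`, `ph_p`, `moderation`, `config`, `provenance`.
#' @export
run_analysis <- function(cohort, config) {
  stopifnot(inherits(config, "analysis_config"))
  tc <- paste0(config$outcome, "_time")
  ec <- paste0(config$outcome, "_event")
  if (!all(c(tc, ec) %in% names(cohort)))
    stop(sprintf("outcome '%s' not present in the cohort table",
                 config$outcome), call. = FALSE)

  dat <- cohort
  if (!is.null(config$exposure_window_months)) {
    m <- config$exposure_window_months
    wmax <- max(dat$entry_offset_months)
    keep <- ifelse(dat$era == "comparator",
                   dat$entry_offset_months >= wmax - m,
                   dat$entry_offset_months <= m)
    dat <- dat[keep, , drop = FALSE]
  }

  ## --- matching (covariates only) --------------------------------------
  if (config$matching == "propensity") {
    covs <- config$covariates %||% .matching_covariates(dat)
    ps <- fit_propensity(dat, covs)
    matched <- match_nearest(ps$scores, dat$era, caliper = config$caliper,
                             seed = config$seed)
    matched <- balance_table(dat, covs, matched)
  } else {
    vars <- config$cem_variables %||% .default_cem_variables(dat)
    matched <- coarsened_exact_match(dat, cem_spec(vars),
                                     seed = config$seed)
    matched <- balance_table(dat, vars, matched)
  }
  if (nrow(matched$pairs) == 0L) {
    row <- .result_row(config, 0L, note = "no matched pairs")
    return(structure(list(rows = row, comparison = NULL, km = NULL,
                          matched = matched, ph_p = NA_real_,
                          moderation = NULL, config = config,
                          provenance = .provenance(config)),
                     class = "natexp_result"))
  }

  idx <- match(c(matched$pairs$comparator_id, matched$pairs$primary_id),
               dat$patient_id)
  adat <- dat[idx, , drop = FALSE]
  pair_of <- rep(matched$pairs$pair_id, 2L)

  if (config$followup_alignment != "none") {
    adat <- align_followup(adat, config$followup_alignment,
                           pair_id = if (config$followup_alignment ==
                                         "pairwise") pair_of)
  }
  horizon_eff <- config$horizon
  if (!is.null(config$restrict_followup)) {
    adat <- .restrict_followup(adat, config$restrict_followup)
    horizon_eff <- min(horizon_eff, config$restrict_followup)
  }

  keep <- adat[[tc]] > config$landmark
  pair_of <- pair_of[keep]
  adat <- .apply_landmark(adat, config$outcome, config$landmark)
  tau <- horizon_eff - config$landmark
  ## tau must lie within observed follow-up on both sides
  tau <- min(tau, tapply(adat[[tc]], adat$era, max))

  is_p <- adat$era == "primary"
  km_c <- km_fit(adat[[tc]][!is_p], adat[[ec]][!is_p])
  km_p <- km_fit(adat[[tc]][is_p], adat[[ec]][is_p])
  ph_p <- tryCatch(ph_test(adat[[tc]], adat[[ec]], is_p),
                   error = function(e) NA_real_)
  cmp <- rmtl_compare(rmtl(km_p, tau), rmtl(km_c, tau),
                      alpha = config$alpha)

  boot <- NULL
  if (config$variance == "bootstrap") {
    ## pairs in which both members passed the landmark
    ptab <- table(pair_of)
    complete <- as.integer(names(ptab)[ptab == 2L])
    pidx <- matched$pairs$pair_id %in% complete
    pr <- matched$pairs[pidx, , drop = FALSE]
    bi_c <- match(pr$comparator_id, adat$patient_id)
    bi_p <- match(pr$primary_id, adat$patient_id)
    bpairs <- data.frame(time_comparator = adat[[tc]][bi_c],
                         event_comparator = adat[[ec]][bi_c],
                         time_primary = adat[[tc]][bi_p],
                         event_primary = adat[[ec]][bi_p])
    boot <- pair_bootstrap_rmtl(bpairs, tau, n_boot = config$n_boot,
                                seed = config$seed, alpha = config$alpha)
  }

  cox <- NULL; lr_p <- NA_real_
  if (!is.null(config$restrict_followup)) {
    cox <- tryCatch(cox_fit(adat[[tc]], adat[[ec]], is_p),
                    error = function(e) NULL)
    lr_p <- tryCatch(logrank_test(adat[[tc]], adat[[ec]], is_p),
                     error = function(e) NA_real_)
  }

  rows <- .result_row(config, nrow(matched$pairs), cmp, ph_p, cox, lr_p,
                      boot = boot)
  perm <- NULL
  if (config$sex_stratify) {
    known <- adat$sex %in% c("F", "M")
    for (sx in c("F", "M")) {
      si <- known & adat$sex == sx
      cmp_s <- tryCatch({
        tau_s <- min(tau, tapply(adat[[tc]][si], adat$era[si], max))
        rmtl_compare(rmtl(km_fit(adat[[tc]][si & is_p],
                                 adat[[ec]][si & is_p]), tau_s),
                     rmtl(km_fit(adat[[tc]][si & !is_p],
                                 adat[[ec]][si & !is_p]), tau_s),
                     alpha = config$alpha)
      }, error = function(e) NULL)
      rows <- rbind(rows, .result_row(config, sum(si) %/% 2L, cmp_s,
                                      subgroup = sx))
    }
    perm <- tryCatch(
      permutation_moderation(adat[[tc]][known], adat[[ec]][known],
                             adat$era[known], adat$sex[known], tau,
                             n_perm = config$n_perm, seed = config$seed),
      error = function(e) NULL)
    if (!is.null(perm)) rows$moderation_p[1] <- perm$p_value
  }

  structure(list(rows = rows, comparison = cmp,
                 km = list(comparator = km_c, primary = km_p),
                 matched = matched, ph_p = ph_p, moderation = perm,
                 bootstrap = boot, tau = tau, config = config,
                 provenance = .provenance(config)),
            class = "natexp_result")
}

.provenance <- function(config) {
  list(config_hash = config_hash(unclass(config)), seed = config$seed,
       timestamp = NA, package = "natexp",
       version = as.character(utils::packageVersion("natexp")))
}

#' @export
print.natexp_result <- function(x, ...) {
  cat(sprintf("Two-era analysis '%s' (outcome %s, %d pairs)\n",
              x$config$analysis_id, x$config$outcome,
              x$rows$n_pairs[1]))
  if (!is.null(x$comparison)) print(x$comparison)
  if (!is.na(x$ph_p))
    cat(sprintf("PH diagnostic P = %.3g\n", x$ph_p))
  if (!is.null(x$moderation))
    cat(sprintf("Sex moderation permutation P = %.4g\n",
                x$moderation$p_value))
  invisible(x)
}

#' Run a grid of analyses
#'
#' Applies [run_analysis()] to each configuration, isolating per-row
#' failures as structured failure rows, and returns the combined
#' results table plus the individual result objects.
#'
#' @param cohort cohort `data.frame`.
#' @param configs list of [analysis_config()] objects.
#' @return an object of class `natexp_grid`: `table` (stacked results
#'   rows, in the configured order) and `results` (per-config objects
#'   or error conditions).
#' @export
run_grid <- function(cohort, configs) {
  stopifnot(length(configs) > 0)
  results <- vector("list", length(configs))
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    res <- tryCatch(run_analysis(cohort, configs[[i]]),
                    error = function(e) e)
    results[[i]] <- res
    rows[[i]] <- if (inherits(res, "error"))
      .result_row(configs[[i]], NA_integer_,
                  note = paste("failed:", conditionMessage(res)))
    else res$rows
  }
  structure(list(table = do.call(rbind, rows), results = results),
            class = "natexp_grid")
}

#' @export
print.natexp_grid <- function(x, ...) {
  cols <- c("analysis_id", "outcome", "subgroup", "n_pairs", "rmtl_ratio",
            "ci_low", "ci_high", "p_value", "additional_days")
  print(x$table[, cols], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Export artifacts of an analysis
#'
#' Writes the results table (CSV), per-era KM curve CSVs
#' (`time, survival, ci_low, ci_high, n_risk`), the balance report CSV,
#' the matched-pairs CSV and a JSON provenance sidecar (config, seed,
#' config hash) into a directory.
#'
#' @param result a `natexp_result`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
export_analysis <- function(result, outdir) {
  stopifnot(inherits(result, "natexp_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  id <- result$config$analysis_id
  write.csv(result$rows, file.path(outdir, paste0(id, "_results.csv")),
            row.names = FALSE)
  if (!is.null(result$km)) {
    for (er in names(result$km)) {
      cv <- result$km[[er]]
      sm <- summary(cv)
      out <- data.frame(time = sm$time, survival = sm$survival,
                        ci_low = sm$ci_low, ci_high = sm$ci_high,
                        n_risk = cv$n_risk)
      write.csv(out, file.path(outdir, paste0(id, "_km_", er, ".csv")),
                row.names = FALSE)
    }
  }
  if (!is.null(result$matched$balance_table))
    write.csv(result$matched$balance_table,
              file.path(outdir, paste0(id, "_balance.csv")),
              row.names = FALSE)
  if (nrow(result$matched$pairs))
    write.csv(result$matched$pairs,
              file.path(outdir, paste0(id, "_pairs.csv")),
              row.names = FALSE)
  jsonlite::write_json(
    list(provenance = result$provenance,
         config = unclass(result$config)),
    file.path(outdir, paste0(id, "_provenance.json")),
    auto_unbox = TRUE, null = "null", digits = NA)
  invisible(outdir)
}
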
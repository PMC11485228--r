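#' Permutation test for moderation of the era effect by sex
#'
#' The RMTL ratio (primary / comparator era) is computed separately in
#' females and males and the absolute difference of the two ratios is
#' the observed statistic.  Each permutation randomly re-allocates
#' individuals to two pseudo-sex groups of the original sizes — by
#' default within each era, preserving era sizes inside the pseudo
#' groups — and recomputes the statistic.  The p-value uses the
#' resampling formula \eqn{P = (1 + n_>)/(1 + n)} where \eqn{n_>} counts
#' permutations whose statistic strictly exceeds the observed one.
#' A permutation with a degenerate stratum (zero RMTL) is counted as
#' exceeding (conservative) and logged.
#'
#' @param time,event survival data for one outcome.
#' @param era `"comparator"` / `"primary"` labels.
#' @param sex `"F"` / `"M"` labels (rows with other values must be
#'   excluded by the caller).
#' @param tau RMTL horizon.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param preserve_era permute sex labels within era (default `TRUE`)
#'   or across the whole sample.
#' @return an object of class `permutation_result`:
#'   `observed_abs_diff`, `ratio_F`, `ratio_M`, `n_perm`, `n_exceed`,
#'   `n_degenerate`, `p_value`, `perm_stats`.
#' @export
permutation_moderation <- function(time, event, era, sex, tau,
                                   n_perm = 1000L, seed = 1L,
                                   preserve_era = TRUE) {
  stopifnot(length(time) == length(event), length(time) == length(era),
            length(time) == length(sex), tau > 0, n_perm >= 1)
  if (!all(sex %in% c("F", "M")))
    stop("sex must be 'F' or 'M'; exclude other rows first", call. = FALSE)
  is_p <- era == "primary"
  is_f <- sex == "F"
  if (min(table(is_p, is_f)) < 1)
    stop("all four sex-by-era strata must be non-empty", call. = FALSE)

  stat <- function(female) {
    rf <- .rmtl_ratio(time[female], event[female], is_p[female], tau)
    rm_ <- .rmtl_ratio(time[!female], event[!female], is_p[!female], tau)
    c(abs(rf - rm_), rf, rm_)
  }
  obs <- stat(is_f)
  if (is.na(obs[1]))
    stop("degenerate stratum (zero RMTL) in the observed data", call. = FALSE)

  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pf <- logical(length(is_f))
      if (preserve_era) {
        for (e in c(TRUE, FALSE)) {
          idx <- which(is_p == e)
          pf[sample(idx, sum(is_f[idx]))] <- TRUE
        }
      } else {
        pf[sample(length(is_f), sum(is_f))] <- TRUE
      }
      stat(pf)[1]
    }, numeric(1))
  })
  n_degenerate <- sum(is.na(perm_stats))
  n_exceed <- sum(perm_stats > obs[1], na.rm = TRUE) + n_degenerate
  structure(list(observed_abs_diff = obs[1], ratio_F = obs[2],
                 ratio_M = obs[3], n_perm = as.integer(n_perm),
                 n_exceed = as.integer(n_exceed),
                 n_degenerate = as.integer(n_degenerate),
                 p_value = (1 + n_exceed) / (1 + n_perm),
                 perm_stats = perm_stats, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("Sex-moderation permutation test: |ratio_F - ratio_M| = ",
                     "%.4f (F %.3f, M %.3f)\n"),
              x$observed_abs_diff, x$ratio_F, x$ratio_M))
  cat(sprintf("  P = (1 + %d) / (1 + %d) = %.4g", x$n_exceed, x$n_perm,
              x$p_value))
  if (x$n_degenerate > 0)
    cat(sprintf("  [%d degenerate permutation(s) counted as exceeding]",
                x$n_degenerate))
  cat("\n")
  invisible(x)
}

#' Matched-pair bootstrap of the RMTL ratio
#'
#' Resamples matched pairs with replacement (both members of a pair
#' enter together, respecting the paired design), recomputes the RMTL
#' ratio per resample, and returns the percentile confidence interval
#' and a two-sided percentile p-value against ratio = 1, floored at
#' `1 / n_boot`.  A resample with zero events in either group is
#' redrawn (and counted).
#'
#' @param pairs `data.frame` with columns `time_comparator`,
#'   `event_comparator`, `time_primary`, `event_primary` (one row per
#'   matched pair).
#' @param tau RMTL horizon.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param alpha two-sided level for the percentile CI.
#' @return an object of class `bootstrap_result`: `estimate` (observed
#'   ratio), `n_boot`, `estimates`, `ci`, `p_value`, `n_redrawn`.
#' @export
pair_bootstrap_rmtl <- function(pairs, tau, n_boot = 1000L, seed = 1L,
                                alpha = 0.05) {
  need <- c("time_comparator", "event_comparator",
            "time_primary", "event_primary")
  if (!all(need %in% names(pairs)))
    stop("'pairs' needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  n <- nrow(pairs)
  if (n < 2) stop("need at least two matched pairs", call. = FALSE)
  ratio_of <- function(idx) {
    r1 <- .rmtl_value(pairs$time_primary[idx], pairs$event_primary[idx], tau)
    r0 <- .rmtl_value(pairs$time_comparator[idx],
                      pairs$event_comparator[idx], tau)
    if (r0 <= 0 || r1 <= 0) NA_real_ else r1 / r0
  }
  est <- ratio_of(seq_len(n))
  res <- with_seed(seed, {
    out <- numeric(n_boot)
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      for (try in 1:100) {
        r <- ratio_of(sample(n, n, replace = TRUE))
        if (!is.na(r)) break
        redrawn <- redrawn + 1L
      }
      if (is.na(r))
        stop("bootstrap resample degenerate after 100 redraws", call. = FALSE)
      out[b] <- r
    }
    list(est = out, redrawn = redrawn)
  })
  ci <- unname(quantile(res$est, c(alpha / 2, 1 - alpha / 2)))
  p <- max(2 * min(mean(res$est <= 1), mean(res$est >= 1)), 1 / n_boot)
  p <- min(p, 1)
  structure(list(estimate = est, n_boot = as.integer(n_boot),
                 estimates = res$est, ci = ci, p_value = p,
                 n_redrawn = res$redrawn, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Pair bootstrap (%d resamples): RMTL ratio %.3f (CI %.3f-%.3f), P %s\n",
              x$n_boot, x$estimate, x$ci[1], x$ci[2],
              if (x$p_value <= 1 / x$n_boot)
                sprintf("< %.3g", 1 / x$n_boot) else
                  sprintf("= %.3g", x$p_value)))
  invisible(x)
}

#' Align follow-up between cohorts or within matched pairs
#'
#' Cohort-wise: both eras are administratively censored at the smaller
#' of the two eras' maximum follow-up.  Pair-wise: each pair is censored
#' at the smaller of its two members' follow-up ends.  Events after the
#' cut become censorings at the cut.  Alignment never increases any
#' subject's follow-up.
#'
#' @param records cohort `data.frame` with `era`, `followup_end_years`
#'   and `<outcome>_time` / `<outcome>_event` columns.
#' @param mode `"cohortwise"` or `"pairwise"`.
#' @param pair_id for `"pairwise"`: vector (aligned with `records`
#'   rows) identifying each patient's pair.
#' @return the transformed `data.frame`.
#' @export
align_followup <- function(records, mode = c("cohortwise", "pairwise"),
                           pair_id = NULL) {
  mode <- match.arg(mode)
  stopifnot("followup_end_years" %in% names(records))
  if (mode == "cohortwise") {
    if (!"era" %in% names(records)) stop("'era' column required", call. = FALSE)
    cut <- min(tapply(records$followup_end_years, records$era, max))
    cut <- rep(cut, nrow(records))
  } else {
    if (is.null(pair_id))
      stop("pairwise alignment requires 'pair_id'", call. = FALSE)
    cut <- ave(records$followup_end_years, pair_id, FUN = min)
  }
  tcols <- grep("_time$", names(records), value = TRUE)
  for (tc in tcols) {
    ec <- sub("_time$", "_event", tc)
    over <- records[[tc]] > cut
    records[[ec]][over] <- 0L
    records[[tc]][over] <- cut[over]
  }
  records$followup_end_years <- pmin(records$followup_end_years, cut)
  records
}
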
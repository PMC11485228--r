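#' Cox model for a two-group contrast
#'
#' Cox partial-likelihood fit (Breslow tie handling) of a binary group
#' effect, for restricted sub-analyses where proportional hazards is
#' plausible.  A monotone likelihood (no events in one group) is
#' flagged with a warning and the estimate capped.
#'
#' @param times,events survival data (1 = event).
#' @param group binary group indicator (0 = comparator, 1 = primary) or
#'   a two-level factor.
#' @return list with `log_hr`, `se`, `hr`, `ci`, `wald_p`, `flagged`,
#'   and the underlying `survival::coxph` fit.
#' @export
cox_fit <- function(times, events, group) {
  g <- if (is.factor(group) || is.character(group))
    as.integer(factor(group)) - 1L else as.integer(group)
  stopifnot(all(g %in% c(0L, 1L)))
  ev_by_g <- tapply(events, g, sum)
  if (length(ev_by_g) < 2L || any(is.na(ev_by_g)))
    stop("need two groups", call. = FALSE)
  flagged <- any(ev_by_g == 0)
  if (all(ev_by_g == 0)) stop("need at least one event per group", call. = FALSE)
  ## coxph's own "coefficient may be infinite" warning is superseded by
  ## the explicit monotone-likelihood flag below
  fit <- suppressWarnings(coxph(Surv(times, events) ~ g, ties = "breslow",
                                control = coxph.control(iter.max = 50)))
  b <- unname(coef(fit))
  se <- sqrt(fit$var[1, 1])
  if (flagged || abs(b) > 15) {
    warning("monotone partial likelihood; hazard-ratio estimate capped",
            call. = FALSE)
    flagged <- TRUE
    b <- pmin(pmax(b, -15), 15)
  }
  list(log_hr = b, se = se, hr = exp(b),
       ci = exp(b + c(-1, 1) * qnorm(0.975) * se),
       wald_p = 2 * pnorm(-abs(b / se)),
       flagged = flagged, fit = fit)
}

#' Log-rank test for a two-group contrast
#'
#' @inheritParams cox_fit
#' @return two-sided p-value from the chi-square(1) log-rank statistic.
#' @export
logrank_test <- function(times, events, group) {
  g <- if (is.factor(group) || is.character(group))
    factor(group) else factor(group)
  sd_ <- survdiff(Surv(times, events) ~ g)
  unname(1 - pchisq(sd_$chisq, df = 1))
}

#' Proportional-hazards diagnostic (generalized Schoenfeld test)
#'
#' Score test correlating the scaled Schoenfeld residuals of the group
#' effect with a transform of event time (Kaplan-Meier transform by
#' default, identity optionally).
#'
#' @inheritParams cox_fit
#' @param transform `"km"` (default) or `"identity"` time transform.
#' @return two-sided p-value; small values indicate non-proportional
#'   hazards.
#' @export
ph_test <- function(times, events, group, transform = c("km", "identity")) {
  transform <- match.arg(transform)
  if (sum(events) < 2) stop("need at least 2 events", call. = FALSE)
  g <- if (is.factor(group) || is.character(group))
    as.integer(factor(group)) - 1L else as.integer(group)
  fit <- coxph(Surv(times, events) ~ g, ties = "breslow")
  zp <- cox.zph(fit, transform = transform)
  unname(zp$table["g", "p"])
}
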
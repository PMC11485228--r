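## vectorized product-limit core shared by km_fit and the resampling
## fast paths; at tied timestamps events precede censorings (both still
## count the censored subject as at risk at that time)
.km_core <- function(time, event) {
  ut <- sort(unique(time))
  d <- tabulate(match(time[event == 1], ut), length(ut))
  cns <- tabulate(match(time[event == 0], ut), length(ut))
  n <- length(time)
  n_risk <- n - c(0, cumsum(d + cns))[seq_along(ut)]
  s <- cumprod(1 - d / n_risk)
  gterm <- ifelse(n_risk > d, d / (n_risk * (n_risk - d)), 0)
  list(times = ut, n_risk = n_risk, n_event = d, n_censor = cns,
       surv = s, cumg = cumsum(gterm), n_total = n)
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator with Greenwood variance.  At tied times,
#' events are handled before censorings (censored subjects remain in
#' the risk set at their own time).  An all-censored input yields the
#' constant curve \eqn{S \equiv 1}.
#'
#' @param times positive event/censoring times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return an object of class `km_curve`: `event_times`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, `greenwood_var`, `n_total`.
#' @export
km_fit <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (!length(times)) stop("no observations", call. = FALSE)
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  k <- .km_core(times, events)
  structure(list(event_times = k$times, n_risk = k$n_risk,
                 n_event = k$n_event, n_censor = k$n_censor,
                 survival = k$surv,
                 greenwood_var = k$surv^2 * k$cumg,
                 n_total = k$n_total),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  nev <- sum(x$n_event)
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, S(max) = %.4f\n",
              x$n_total, nev, x$survival[length(x$survival)]))
  invisible(x)
}

#' @export
summary.km_curve <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$event_times
  idx <- findInterval(times, object$event_times)
  s <- ifelse(idx == 0, 1, object$survival[pmax(idx, 1)])
  v <- ifelse(idx == 0, 0, object$greenwood_var[pmax(idx, 1)])
  se <- sqrt(v)
  data.frame(time = times, survival = s, std_err = se,
             ci_low = pmax(0, s - 1.96 * se),
             ci_high = pmin(1, s + 1.96 * se))
}

#' @export
plot.km_curve <- function(x, ..., incidence = FALSE, xlab = "Time (years)",
                          ylab = NULL) {
  tt <- c(0, x$event_times)
  ss <- c(1, x$survival)
  yy <- if (incidence) 1 - ss else ss
  if (is.null(ylab))
    ylab <- if (incidence) "Cumulative incidence" else "Survival"
  plot(tt, yy, type = "s", xlab = xlab, ylab = ylab,
       ylim = if (incidence) c(0, max(yy) * 1.05) else c(0, 1), ...)
  invisible(x)
}

## S(t) from a km_curve at arbitrary times (right-continuous step)
.km_surv_at <- function(curve, t) {
  idx <- findInterval(t, curve$event_times)
  ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)])
}

#' Restricted mean time lost
#'
#' RMTL up to horizon `tau` is `tau` minus the restricted mean survival
#' time \eqn{\int_0^\tau S(t)\,dt}, computed by exact step-function
#' integration of the Kaplan-Meier curve.  The variance is the standard
#' large-sample RMST variance
#' \eqn{\sum_{t_i \le \tau} \big[\int_{t_i}^{\tau} S\,du\big]^2
#' d_i / (n_i (n_i - d_i))}.
#'
#' @param curve a [km_fit()] result.
#' @param tau horizon; must not exceed the largest observed time.
#' @return an object of class `rmtl_estimate`: `tau`, `rmtl`, `rmst`,
#'   `variance`, `cumulative_incidence` (at `tau`) and its variance
#'   (`cif_variance`), and `n_total`.
#' @export
rmtl <- function(curve, tau) {
  stopifnot(inherits(curve, "km_curve"), length(tau) == 1L, tau > 0)
  tmax <- max(curve$event_times)
  ## a horizon beyond the data is only admissible when the curve is
  ## already fully determined (S reached 0)
  if (tau > tmax + 1e-12 && curve$survival[length(curve$survival)] > 0)
    stop(sprintf(paste0("horizon tau = %g lies beyond the last observed time",
                        " %g; align follow-up or lower the horizon"),
                 tau, tmax), call. = FALSE)
  keep <- curve$event_times < tau
  tt <- c(0, curve$event_times[keep], tau)
  ss <- c(1, curve$survival[keep])        # S on each segment
  seg <- diff(tt) * ss
  rmst <- sum(seg)
  ## tail integrals int_{t_i}^{tau} S du at each retained event time
  tail_int <- rev(cumsum(rev(seg)))[-1]   # drop the [0, t_1) segment
  d <- curve$n_event[keep]
  nr <- curve$n_risk[keep]
  vterm <- ifelse(nr > d, d / (nr * (nr - d)), 0)
  variance <- sum(tail_int^2 * vterm)
  s_tau <- .km_surv_at(curve, tau)
  cif_var <- if (any(curve$event_times <= tau))
    curve$greenwood_var[max(which(curve$event_times <= tau))] else 0
  structure(list(tau = tau, rmtl = tau - rmst, rmst = rmst,
                 variance = variance,
                 cumulative_incidence = 1 - s_tau,
                 cif_variance = cif_var,
                 n_total = curve$n_total),
            class = "rmtl_estimate")
}

#' @export
print.rmtl_estimate <- function(x, ...) {
  cat(sprintf("RMTL to tau = %g: %.4f y (SE %.4f); RMST %.4f y; CIF(tau) %.4f\n",
              x$tau, x$rmtl, sqrt(x$variance), x$rmst,
              x$cumulative_incidence))
  invisible(x)
}

## lean RMTL point estimate for resampling loops (no variance)
.rmtl_value <- function(time, event, tau) {
  ut <- sort(unique(time[time < tau | event == 1]))
  ut <- ut[ut < tau]
  if (!length(ut)) return(0)
  d <- tabulate(match(time[event == 1], ut), length(ut))
  cns <- tabulate(match(time[event == 0], ut), length(ut))
  n_risk <- length(time) - c(0, cumsum(d + cns))[seq_along(ut)]
  s <- cumprod(1 - d / n_risk)
  tau - sum(diff(c(0, ut, tau)) * c(1, s))
}

## RMTL ratio primary/comparator for resampling loops; NA if degenerate
.rmtl_ratio <- function(time, event, is_primary, tau) {
  r1 <- .rmtl_value(time[is_primary], event[is_primary], tau)
  r0 <- .rmtl_value(time[!is_primary], event[!is_primary], tau)
  if (r0 <= 0 || r1 <= 0) return(NA_real_)
  r1 / r0
}

#' Compare two groups on restricted mean time lost
#'
#' RMTL ratio (primary / comparator) with a log-scale delta-method
#' confidence interval and two-sided z-test, plus the translation of the
#' absolute RMTL difference into additional event-free days among those
#' affected: \eqn{(\mathrm{RMTL}_c - \mathrm{RMTL}_p) / F_c(\tau)}
#' converted to days, where \eqn{F_c(\tau)} is the comparator's
#' cumulative incidence at the horizon.  The additional-days CI uses the
#' delta method treating numerator and denominator as independent.
#'
#' @param primary,comparator [rmtl()] estimates sharing the same `tau`.
#' @param alpha two-sided significance level (default 0.05).
#' @return an object of class `rmtl_comparison`: `ratio`, `ci`,
#'   `p_value`, `rmtl_primary`, `rmtl_comparator`, `additional_days`,
#'   `additional_days_ci`, `ratio_defined`.
#' @export
rmtl_compare <- function(primary, comparator, alpha = 0.05) {
  stopifnot(inherits(primary, "rmtl_estimate"),
            inherits(comparator, "rmtl_estimate"))
  if (abs(primary$tau - comparator$tau) > 1e-9)
    stop("both estimates must share the same tau", call. = FALSE)
  z <- qnorm(1 - alpha / 2)
  diff_rmtl <- comparator$rmtl - primary$rmtl
  var_diff <- comparator$variance + primary$variance

  ratio_defined <- primary$rmtl > 0 && comparator$rmtl > 0
  if (ratio_defined) {
    lr <- log(primary$rmtl) - log(comparator$rmtl)
    se_lr <- sqrt(primary$variance / primary$rmtl^2 +
                  comparator$variance / comparator$rmtl^2)
    ratio <- exp(lr)
    ci <- exp(lr + c(-1, 1) * z * se_lr)
    p <- 2 * pnorm(-abs(lr / se_lr))
  } else {
    ratio <- NA_real_; ci <- c(NA_real_, NA_real_)
    se_lr <- NA_real_
    p <- 2 * pnorm(-abs(diff_rmtl / sqrt(var_diff)))
  }

  f0 <- comparator$cumulative_incidence
  if (f0 > 0) {
    ad <- diff_rmtl / f0 * DAYS_PER_YEAR
    var_ad <- (var_diff / f0^2 +
               diff_rmtl^2 * comparator$cif_variance / f0^4) * DAYS_PER_YEAR^2
    ad_ci <- ad + c(-1, 1) * z * sqrt(var_ad)
  } else {
    ad <- NA_real_; ad_ci <- c(NA_real_, NA_real_)
  }

  structure(list(ratio = ratio, ci = ci, se_log_ratio = se_lr, p_value = p,
                 rmtl_primary = primary, rmtl_comparator = comparator,
                 rmtl_difference = diff_rmtl,
                 additional_days = ad, additional_days_ci = ad_ci,
                 ratio_defined = ratio_defined, alpha = alpha),
            class = "rmtl_comparison")
}

#' @export
print.rmtl_comparison <- function(x, ...) {
  if (x$ratio_defined) {
    cat(sprintf("RMTL ratio %.3f (%d%% CI %.3f-%.3f), P = %.3g\n",
                x$ratio, round(100 * (1 - x$alpha)), x$ci[1], x$ci[2],
                x$p_value))
  } else {
    cat(sprintf("RMTL ratio undefined (zero RMTL); difference %.4f y, P = %.3g\n",
                x$rmtl_difference, x$p_value))
  }
  if (!is.na(x$additional_days))
    cat(sprintf("Additional event-free days among affected: %.0f (%.0f-%.0f)\n",
                x$additional_days, x$additional_days_ci[1],
                x$additional_days_ci[2]))
  invisible(x)
}
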
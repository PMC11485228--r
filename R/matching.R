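## 2-year age bins 65-66, 67-68, ..., 93-94, with 95+ pooled
age_bin <- function(age) {
  b <- c(seq(65, 95, by = 2), Inf)
  labs <- c(sprintf("%d-%d", seq(65, 93, by = 2), seq(66, 94, by = 2)), "95+")
  cut(age, breaks = b, labels = labs, right = FALSE)
}

## indicator design matrix for the PS model: age as 2-year-bin dummies,
## categoricals (incl. explicit "missing") as level dummies, binaries as is
.ps_design <- function(records, covariates) {
  cols <- list()
  for (nm in covariates) {
    if (nm == "age" || nm == "age_years") {
      cols[["age_bin"]] <- factor(age_bin(records$age_years))
    } else if (is.character(records[[nm]]) || is.factor(records[[nm]])) {
      cols[[nm]] <- factor(records[[nm]])
    } else {
      cols[[nm]] <- as.numeric(records[[nm]])
    }
  }
  df <- as.data.frame(cols, stringsAsFactors = TRUE)
  mm <- stats::model.matrix(~ ., data = df)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

#' Fit the propensity-score model for era membership
#'
#' Logistic regression of primary-era membership on the covariate
#' indicators (age entered as 2-year-bin dummies, categorical variables
#' as level dummies including any explicit `"missing"` level).  Perfect
#' or quasi-perfect separation is flagged with a warning and the
#' offending coefficients are capped.
#'
#' @param records cohort `data.frame` with an `era` column.
#' @param covariates character vector of covariate column names
#'   (`"age"` expands to the 2-year bins of `age_years`).
#' @return an object of class `propensity_model`: coefficients,
#'   intercept, and per-patient scores (probability of primary era)
#'   named by `patient_id`.
#' @export
fit_propensity <- function(records, covariates) {
  stopifnot(is.data.frame(records), "era" %in% names(records))
  y <- as.integer(records$era == "primary")
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("need at least two records in each era", call. = FALSE)
  x <- .ps_design(records, covariates)
  fit <- suppressWarnings(
    glm.fit(cbind(`(Intercept)` = 1, x), y, family = binomial(),
            control = list(maxit = 100)))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  sep <- !fit$converged || any(abs(cf[-1]) > 15) ||
    any(fit$fitted.values < 1e-10) || any(fit$fitted.values > 1 - 1e-10)
  if (sep) {
    warning("possible separation in the propensity model; coefficients capped",
            call. = FALSE)
    cf[-1] <- pmin(pmax(cf[-1], -15), 15)
  }
  eta <- drop(cbind(1, x) %*% cf)
  scores <- stats::plogis(eta)
  scores <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  names(scores) <- records$patient_id
  structure(list(coefficients = cf[-1], intercept = cf[[1]],
                 scores = scores, covariates = covariates),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("Propensity model: %d coefficients, %d scores (range %.4f-%.4f)\n",
              length(x$coefficients), length(x$scores),
              min(x$scores), max(x$scores)))
  invisible(x)
}

## union-find style nearest-alive lookup with path compression
.find_alive <- function(ptr, i, step) {
  j <- i
  while (j >= 1L && j <= length(ptr) && ptr[j] != j) j <- ptr[j]
  if (j < 1L || j > length(ptr)) return(list(pos = 0L, ptr = ptr))
  ## compress the walked path
  k <- i
  while (k >= 1L && k <= length(ptr) && ptr[k] != k) {
    nxt <- ptr[k]
    ptr[k] <- j
    k <- nxt
  }
  list(pos = j, ptr = ptr)
}

#' Greedy 1:1 nearest-neighbour matching with a caliper
#'
#' Matches each primary-era patient to the nearest unmatched
#' comparator-era patient on the propensity score, without replacement,
#' in an order randomized under `seed` (so record order cannot influence
#' the result).  A pair is emitted only if the score distance is within
#' the caliper.  Ties are broken by a seeded random ranking of the
#' comparator records.
#'
#' @param scores named numeric vector of propensity scores (as from
#'   [fit_propensity()]).
#' @param era character vector aligned with `scores`
#'   (`"comparator"` / `"primary"`).
#' @param caliper maximum allowed score distance within a pair.
#' @param seed integer seed for the processing order randomization.
#' @param caliper_scale `"ps"` applies the caliper on the raw
#'   probability scale; `"logit_sd"` uses `caliper * sd(logit(scores))`.
#' @return an object of class `matched_cohorts` with elements `pairs`
#'   (`data.frame`: `pair_id`, `comparator_id`, `primary_id`,
#'   `ps_comparator`, `ps_primary`, `stratum`), `unmatched` (ids) and
#'   `balance_table` (`NULL` until [balance_table()] fills it).
#' @export
match_nearest <- function(scores, era, caliper = 0.1, seed = 1L,
                          caliper_scale = c("ps", "logit_sd")) {
  caliper_scale <- match.arg(caliper_scale)
  stopifnot(length(scores) == length(era), caliper >= 0)
  ids <- names(scores) %||% as.character(seq_along(scores))
  cal <- if (caliper_scale == "logit_sd")
    caliper * stats::sd(stats::qlogis(scores)) else caliper

  ci <- which(era == "comparator")
  pi_ <- which(era == "primary")
  m <- length(ci)
  pairs <- NULL
  if (m > 0L && length(pi_) > 0L) {
    o <- order(scores[ci])
    cs <- scores[ci][o]        # sorted comparator scores
    cid <- ids[ci][o]
    perm <- with_seed(seed, list(p = sample(length(pi_)),
                                 tie = sample(m)))
    left <- seq_len(m)         # alive pointers
    right <- seq_len(m)
    pc <- character(0); pp <- character(0)
    psc <- numeric(0); psp <- numeric(0)
    for (j in perm$p) {
      sp <- scores[pi_[j]]
      pos <- findInterval(sp, cs)
      fl <- .find_alive(left, pos, -1L); left <- fl$ptr
      fr <- .find_alive(right, pos + 1L, 1L); right <- fr$ptr
      cand <- c(fl$pos, fr$pos)
      cand <- cand[cand != 0L]
      if (!length(cand)) next
      dist <- abs(cs[cand] - sp)
      best <- cand[order(dist, perm$tie[cand])][1L]
      if (dist[match(best, cand)] <= cal) {
        pc <- c(pc, cid[best]); pp <- c(pp, ids[pi_[j]])
        psc <- c(psc, cs[best]); psp <- c(psp, sp)
        ## remove matched comparator from the alive structure
        left[best] <- best - 1L
        right[best] <- best + 1L
      }
    }
    if (length(pc))
      pairs <- data.frame(pair_id = seq_along(pc), comparator_id = pc,
                          primary_id = pp, ps_comparator = psc,
                          ps_primary = psp, stratum = NA_character_,
                          stringsAsFactors = FALSE)
  }
  if (is.null(pairs))
    pairs <- data.frame(pair_id = integer(0), comparator_id = character(0),
                        primary_id = character(0), ps_comparator = numeric(0),
                        ps_primary = numeric(0), stratum = character(0),
                        stringsAsFactors = FALSE)
  matched <- c(pairs$comparator_id, pairs$primary_id)
  structure(list(pairs = pairs, unmatched = setdiff(ids, matched),
                 balance_table = NULL, caliper = cal, seed = seed),
            class = "matched_cohorts")
}

#' @export
print.matched_cohorts <- function(x, ...) {
  cat(sprintf("Matched cohorts: %d pairs, %d unmatched (caliper %.4g)\n",
              nrow(x$pairs), length(x$unmatched), x$caliper))
  if (!is.null(x$balance_table)) {
    n_bad <- sum(x$balance_table$smd_after >= 0.1)
    cat(sprintf("  balance: max post-match SMD %.4f (%d covariate(s) >= 0.1)\n",
                max(x$balance_table$smd_after), n_bad))
  }
  invisible(x)
}

#' Standardized mean difference between two groups
#'
#' Binary: \eqn{|p_a - p_b| / \sqrt{(p_a(1-p_a) + p_b(1-p_b))/2}};
#' continuous: \eqn{|\bar x_a - \bar x_b| / \sqrt{(s_a^2 + s_b^2)/2}}.
#' Returns 0 when both groups are degenerate and equal, and `Inf` when
#' the pooled variance is zero but the means differ.
#'
#' @param values_a,values_b numeric vectors (0/1 for binary).
#' @param type `"binary"` or `"continuous"`.
#' @return a non-negative number (possibly `Inf`).
#' @export
standardized_mean_difference <- function(values_a, values_b,
                                         type = c("binary", "continuous")) {
  type <- match.arg(type)
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty", call. = FALSE)
  if (type == "binary") {
    pa <- mean(values_a); pb <- mean(values_b)
    pool <- (pa * (1 - pa) + pb * (1 - pb)) / 2
    num <- abs(pa - pb)
  } else {
    pool <- (stats::var(values_a) + stats::var(values_b)) / 2
    if (is.na(pool)) pool <- 0   # length-1 groups
    num <- abs(mean(values_a) - mean(values_b))
  }
  if (pool <= 0) return(if (num == 0) 0 else Inf)
  num / sqrt(pool)
}

## SMD of one covariate between eras, expanded over levels where needed
.smd_rows <- function(records, nm, idx_c, idx_p) {
  if (nm %in% c("age", "age_years")) {
    return(data.frame(covariate = "age",
                      smd = standardized_mean_difference(
                        records$age_years[idx_c], records$age_years[idx_p],
                        "continuous")))
  }
  v <- records[[nm]]
  if (is.character(v) || is.factor(v)) {
    levs <- sort(unique(as.character(v)))
    data.frame(covariate = paste0(nm, "=", levs),
               smd = vapply(levs, function(l)
                 standardized_mean_difference(
                   as.numeric(v[idx_c] == l), as.numeric(v[idx_p] == l),
                   "binary"), numeric(1)))
  } else {
    data.frame(covariate = nm,
               smd = standardized_mean_difference(
                 as.numeric(v[idx_c]), as.numeric(v[idx_p]), "binary"))
  }
}

#' Covariate balance before and after matching
#'
#' Standardized mean differences per covariate (categorical covariates
#' expanded per level, age as a continuous SMD), comparing the full
#' cohorts and the matched subsets.  SMD below 0.1 is flagged as well
#' matched.
#'
#' @param records cohort `data.frame`.
#' @param covariates covariate names to assess.
#' @param matched a `matched_cohorts` object.
#' @return the `matched_cohorts` object with its `balance_table` filled:
#'   `covariate`, `smd_before`, `smd_after`, `well_matched`.
#' @export
balance_table <- function(records, covariates, matched) {
  stopifnot(inherits(matched, "matched_cohorts"))
  idx_c <- which(records$era == "comparator")
  idx_p <- which(records$era == "primary")
  mi_c <- match(matched$pairs$comparator_id, records$patient_id)
  mi_p <- match(matched$pairs$primary_id, records$patient_id)
  rows <- lapply(covariates, function(nm) {
    before <- .smd_rows(records, nm, idx_c, idx_p)
    after <- if (nrow(matched$pairs))
      .smd_rows(records, nm, mi_c, mi_p)$smd else rep(NA_real_, nrow(before))
    data.frame(covariate = before$covariate, smd_before = before$smd,
               smd_after = after, stringsAsFactors = FALSE)
  })
  bt <- do.call(rbind, rows)
  bt$well_matched <- bt$smd_after < 0.1
  matched$balance_table <- bt
  matched
}

#' Coarsening specification for coarsened exact matching
#'
#' Age is coarsened into the standard 2-year bins (65-66, 67-68, ...,
#' with 95 and older pooled); every other listed variable is matched on
#' its exact levels.
#'
#' @param variables covariate names to match on (include `"age"` for the
#'   binned age).
#' @return an object of class `cem_spec`.
#' @export
cem_spec <- function(variables) {
  stopifnot(is.character(variables), length(variables) > 0)
  structure(list(variables = variables), class = "cem_spec")
}

#' Coarsened exact matching
#'
#' Stratifies patients by the joint coarsened covariate signature and
#' forms `min(n_comparator, n_primary)` random 1:1 pairs within each
#' stratum.  The set of strata is seed-invariant; only the within-
#' stratum pairing is random.
#'
#' @param records cohort `data.frame`.
#' @param spec a [cem_spec()].
#' @param seed integer seed for within-stratum pairing.
#' @return a `matched_cohorts` object; each pair carries its stratum id.
#' @export
coarsened_exact_match <- function(records, spec, seed = 1L) {
  stopifnot(inherits(spec, "cem_spec"))
  miss <- setdiff(setdiff(spec$variables, c("age", "age_years")),
                  names(records))
  if (length(miss))
    stop(sprintf("coarsening spec covers unknown variable(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  sig_cols <- lapply(spec$variables, function(nm) {
    if (nm %in% c("age", "age_years")) as.character(age_bin(records$age_years))
    else as.character(records[[nm]])
  })
  sig <- do.call(paste, c(sig_cols, sep = "|"))
  pairs <- with_seed(seed, {
    res <- list()
    for (s in sort(unique(sig))) {
      idx <- which(sig == s)
      cc <- idx[records$era[idx] == "comparator"]
      pp <- idx[records$era[idx] == "primary"]
      k <- min(length(cc), length(pp))
      if (k == 0L) next
      cc <- if (length(cc) > 1L) sample(cc, k) else cc
      pp <- if (length(pp) > 1L) sample(pp, k) else pp
      res[[s]] <- data.frame(
        comparator_id = records$patient_id[cc[seq_len(k)]],
        primary_id = records$patient_id[pp[seq_len(k)]],
        ps_comparator = NA_real_, ps_primary = NA_real_,
        stratum = s, stringsAsFactors = FALSE)
    }
    if (length(res)) do.call(rbind, res) else
      data.frame(comparator_id = character(0), primary_id = character(0),
                 ps_comparator = numeric(0), ps_primary = numeric(0),
                 stratum = character(0), stringsAsFactors = FALSE)
  })
  pairs <- cbind(pair_id = seq_len(nrow(pairs)), pairs)
  rownames(pairs) <- NULL
  matched <- c(pairs$comparator_id, pairs$primary_id)
  structure(list(pairs = pairs,
                 unmatched = setdiff(records$patient_id, matched),
                 balance_table = NULL, caliper = NA_real_, seed = seed),
            class = "matched_cohorts")
}
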
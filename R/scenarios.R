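#' Shipped simulation scenarios
#'
#' Three named data-generating scenarios:
#' \describe{
#'   \item{`"paper-like"`}{Two eras with covariate drift, era-dependent
#'     administrative censoring (median follow-up about 6.0 vs 4.15
#'     years), a dementia-like outcome with a waning protective era
#'     effect that is stronger in females, a zoster-like outcome with a
#'     stronger protective era effect, and null mortality and
#'     negative-control outcomes.}
#'   \item{`"null"`}{No era effects anywhere, no covariate drift and
#'     identical censoring in both eras: any downstream estimator
#'     should attain its nominal type-I error.}
#'   \item{`"no-drift"`}{The paper-like era effects without covariate
#'     drift.}
#' }
#'
#' @param name scenario name.
#' @param n_comparator,n_primary cohort sizes.
#' @param seed master seed.
#' @return a [sim_config()].
#' @export
scenario_config <- function(name = c("paper-like", "null", "no-drift"),
                            n_comparator = 20000L, n_primary = 20000L,
                            seed = 1L) {
  name <- match.arg(name)
  if (name == "paper-like") {
    sim_config(n_comparator, n_primary, seed = seed)
  } else if (name == "no-drift") {
    sim_config(n_comparator, n_primary,
               covariates = default_covariates(drift = FALSE),
               seed = seed)
  } else {
    null_outcomes <- lapply(default_outcomes(), function(o) {
      o$era_log_hr[] <- 0
      o$sex_interaction_log_hr <- 0
      o
    })
    cens <- default_censoring()
    cens$primary <- cens$comparator
    sim_config(n_comparator, n_primary,
               covariates = default_covariates(drift = FALSE),
               outcomes = null_outcomes, censoring = cens, seed = seed)
  }
}

#' Read / write a scenario file
#'
#' Scenario YAML files carry the scenario name plus any overrides of
#' the cohort sizes and seed; [read_scenario()] resolves them into a
#' full [sim_config()].  Example files ship under
#' `system.file("extdata", "scenarios", package = "natexp")`.
#'
#' @param path YAML file with fields `scenario`, and optionally
#'   `n_comparator`, `n_primary`, `seed`.
#' @return a [sim_config()].
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$scenario))
    stop("scenario file needs a 'scenario' field", call. = FALSE)
  scenario_config(y$scenario,
                  n_comparator = y$n_comparator %||% 20000L,
                  n_primary = y$n_primary %||% 20000L,
                  seed = y$seed %||% 1L)
}
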
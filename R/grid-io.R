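#' Read an analysis grid from YAML
#'
#' The grid file holds a list of analyses plus optional shared
#' defaults; each entry maps onto the arguments of
#' [analysis_config()].
#'
#' \preformatted{
#' defaults:
#'   landmark: 0.25
#'   horizon: 6
#' analyses:
#'   - analysis_id: primary
#'     outcome: dementia
#'     sex_stratify: true
#'   - analysis_id: zoster
#'     outcome: zoster
#' }
#'
#' @param path YAML file.
#' @param seed if not `NULL`, overrides the seed of every analysis.
#' @return list of [analysis_config()] objects.
#' @export
read_analysis_grid <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (is.null(y$analyses) || !length(y$analyses))
    stop("analysis grid needs a non-empty 'analyses' list", call. = FALSE)
  defaults <- y$defaults %||% list()
  lapply(y$analyses, function(a) {
    args <- utils::modifyList(defaults, a)
    if (!is.null(seed)) args$seed <- seed
    do.call(analysis_config, args)
  })
}
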
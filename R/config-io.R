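# YAML round-trip for scenario configurations.

coerce_num <- function(x) {
  if (is.list(x) && all(vapply(x, is.numeric, NA))) unlist(x) else x
}

#' Read a scenario configuration from a YAML file
#'
#' The YAML mirrors the arguments of [scenario_config()]; coefficient maps
#' become named numeric vectors.
#'
#' @param path Path to a YAML file.
#' @return A [scenario_config()].
#' @export
scenario_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("hazard_model", "outcome_mix"))
    if (!is.null(y[[nm]])) y[[nm]] <- coerce_num(y[[nm]])
  if (!is.null(y$treatment_model))
    y$treatment_model <- lapply(y$treatment_model, coerce_num)
  if (!is.null(y$continuation_model))
    y$continuation_model <- lapply(y$continuation_model, coerce_num)
  if (!is.null(y$censoring_model))
    y$censoring_model <- lapply(y$censoring_model, coerce_num)
  if (!is.null(y$covariate_dynamics))
    y$covariate_dynamics <- lapply(y$covariate_dynamics, function(d) {
      d$exposure <- coerce_num(d$exposure); d
    })
  if (!is.null(y$dispensing)) y$dispensing <- lapply(y$dispensing, unlist)
  do.call(scenario_config, y)
}

#' Write a scenario configuration to a YAML file
#'
#' @param config A [scenario_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
scenario_to_yaml <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  y <- unclass(config)
  tolist <- function(v) as.list(v)
  y$hazard_model <- tolist(y$hazard_model)
  y$outcome_mix <- tolist(y$outcome_mix)
  y$treatment_model <- lapply(y$treatment_model, tolist)
  y$continuation_model <- lapply(y$continuation_model, tolist)
  y$censoring_model <- lapply(y$censoring_model, tolist)
  y$covariate_dynamics <- lapply(y$covariate_dynamics, function(d) {
    d$exposure <- tolist(d$exposure); d
  })
  yaml::write_yaml(y, path)
  invisible(path)
}
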
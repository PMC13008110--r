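#' Read an analysis configuration from YAML
#'
#' Builds package configuration objects from a structured text file whose
#' keys mirror the constructor arguments. Recognised top-level sections:
#' `parameters` ([dmc_parameters()]), `simulation` ([simulation_config()]),
#' `rules` ([preprocess_rules()]), `fit` ([fit_config()]; its `bounds`
#' entry may be a named list of `[lower, upper]` pairs), and `pipeline`
#' (`task`, `input`, `out_dir`, `seed` for [pipeline_config()]). Missing
#' sections fall back to package defaults. A complete annotated example
#' ships at `system.file("extdata", "analysis_config_example.yaml",
#' package = "dmconflict")`.
#'
#' @param path Path to a YAML file.
#' @return A list with any of `parameters`, `simulation`, `rules`, `fit`,
#'   `pipeline` (the pipeline section is returned as a
#'   [pipeline_config()] when `task` and `input` are present).
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$parameters))
    out$parameters <- do.call(dmc_parameters, raw$parameters)
  if (!is.null(raw$simulation))
    out$simulation <- do.call(simulation_config, raw$simulation)
  if (!is.null(raw$rules))
    out$rules <- do.call(preprocess_rules, raw$rules)
  if (!is.null(raw$fit)) {
    fit_args <- raw$fit
    if (!is.null(fit_args$bounds)) {
      b <- fit_args$bounds
      fit_args$bounds <- rbind(
        lower = vapply(b, `[[`, numeric(1), 1),
        upper = vapply(b, `[[`, numeric(1), 2))
    }
    out$fit <- do.call(fit_config, fit_args)
  }
  if (!is.null(raw$pipeline) &&
      all(c("task", "input") %in% names(raw$pipeline))) {
    pl <- raw$pipeline
    out$pipeline <- pipeline_config(
      task = pl$task, input = pl$input,
      rules = if (is.null(out$rules)) preprocess_rules() else out$rules,
      fit = if (is.null(out$fit)) fit_config() else out$fit,
      out_dir = if (is.null(pl$out_dir)) tempfile("dmc_") else pl$out_dir,
      seed = if (is.null(pl$seed)) 1 else pl$seed)
  }
  out
}
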
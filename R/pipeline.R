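#' Pipeline configuration
#'
#' Bundles everything one end-to-end analysis needs: the data source (an
#' external trial table or a generator spec), preprocessing rules, fitting
#' settings, an output directory and a master seed.
#'
#' @param task `"navon"` or `"composite"`.
#' @param input Either a file path to a delimited trial table, a trial
#'   data.frame, or a `dmc_generator_spec` (synthetic input).
#' @param rules A [preprocess_rules()].
#' @param fit A [fit_config()].
#' @param out_dir Output directory for artifacts; created if missing.
#' @param seed Master seed recorded in every artifact.
#' @return A list of class `dmc_pipeline_config`.
#' @export
pipeline_config <- function(task, input, rules = preprocess_rules(),
                            fit = fit_config(), out_dir = tempfile("dmc_"),
                            seed = 1) {
  stopifnot(task %in% c("navon", "composite"))
  if (is.character(input) && !file.exists(input))
    stop("input file does not exist: ", input)
  structure(list(task = task, input = input, rules = rules, fit = fit,
                 out_dir = out_dir, seed = seed),
            class = "dmc_pipeline_config")
}

config_fingerprint <- function(cfg) {
  # stable content hash of the analysis-relevant config (the output
  # location does not change the analysis)
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  txt <- paste(deparse(strip(cfg)), collapse = "")
  # polynomial rolling hash mod 2^31 - 1 over the deparsed text
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full conflict-diffusion analysis
#'
#' Orchestrates: data ingest (or synthetic generation), preprocessing with
#' an exclusion report, per-cell DMC fitting, per-condition delta
#' functions, and observed-vs-predicted diagnostics. Every artifact is
#' written as delimited text (or YAML for reports) into `cfg$out_dir`
#' together with the master seed and a config fingerprint; reruns with the
#' same config are bitwise stable.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with `clean`, `report`, `study`
#'   (`dmc_study_fit`), `delta` (per-cell delta functions), and the paths
#'   of the written artifacts.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "dmc_pipeline_config"))
  stage <- "ingest"
  result <- tryCatch({
    raw <- if (inherits(cfg$input, "dmc_generator_spec"))
      generate_dataset(cfg$input)$trials
    else if (is.character(cfg$input)) read_trials(cfg$input)
    else cfg$input

    stage <- "preprocess"
    pp <- preprocess_dataset(raw, cfg$rules)

    stage <- "fit"
    study <- fit_study(pp$trials, task = cfg$task, cfg = cfg$fit,
                       seed = cfg$seed)

    stage <- "delta"
    level_cols <- intersect(c("session", "time", "level_or_alignment"),
                            names(pp$trials))
    key <- interaction(pp$trials[level_cols], drop = TRUE, lex.order = TRUE)
    delta <- lapply(split(pp$trials, key), function(d) {
      cc <- d[d$congruency == "congruent", ]
      ii <- d[d$congruency == "incongruent", ]
      if (!nrow(cc) || !nrow(ii)) return(NULL)
      delta_function(cc, ii)
    })
    delta <- delta[!vapply(delta, is.null, TRUE)]

    stage <- "write"
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- c(sprintf("# seed: %s", cfg$seed),
              sprintf("# config: %s", config_fingerprint(cfg)))
    write_stamped <- function(df, file) {
      path <- file.path(cfg$out_dir, file)
      con <- file(path, "w")
      writeLines(meta, con)
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
      path
    }
    paths <- list(
      clean = write_stamped(pp$trials, "clean_trials.tsv"),
      parameters = write_stamped(study$parameters, "parameters.tsv"),
      obs_pred = write_stamped(study$obs_pred, "observed_predicted.tsv"),
      delta = write_stamped(
        do.call(rbind, lapply(names(delta), function(k)
          cbind(cell = k, delta[[k]]))), "delta_functions.tsv"))
    report_path <- file.path(cfg$out_dir, "exclusion_report.yaml")
    yaml::write_yaml(c(list(seed = cfg$seed,
                            config = config_fingerprint(cfg)),
                       unclass(pp$report)), report_path)
    paths$report <- report_path

    list(clean = pp$trials, report = pp$report, study = study,
         delta = delta, paths = paths)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Summarise a fitted parameter table
#'
#' Per-parameter cell means and (optionally) within-subject contrasts with
#' seeded bootstrap confidence intervals over subjects.
#'
#' @param parameters Tidy parameter table from [fit_study()] (one row per
#'   subject x cell).
#' @param contrast Optional length-2 character vector naming two levels of
#'   `by` to contrast (first minus second).
#' @param by Column holding the contrasted factor (default
#'   `"level_or_alignment"`).
#' @param params Parameters to summarise.
#' @param n_boot Bootstrap replicates for the contrast CI.
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap resampling.
#' @return A list with `cell_means` (data.frame) and, when a contrast is
#'   requested, `contrasts` (per-parameter mean within-subject difference,
#'   bootstrap CI and the per-subject differences).
#' @export
summarize_parameters <- function(parameters, contrast = NULL,
                                 by = "level_or_alignment",
                                 params = free_par_names,
                                 n_boot = 2000, conf = 0.95, seed = 1) {
  stopifnot(is.data.frame(parameters), by %in% names(parameters))
  cell_cols <- intersect(c("session", "time", "level_or_alignment"),
                         names(parameters))
  key <- interaction(parameters[cell_cols], drop = TRUE, lex.order = TRUE)
  cell_means <- do.call(rbind, lapply(split(parameters, key), function(d) {
    cbind(d[1, cell_cols, drop = FALSE],
          as.data.frame(lapply(d[params], mean)),
          n_subjects = length(unique(d$subject)))
  }))
  rownames(cell_means) <- NULL
  out <- list(cell_means = cell_means)
  if (!is.null(contrast)) {
    stopifnot(length(contrast) == 2L)
    if (!all(contrast %in% parameters[[by]]))
      stop("contrast levels not present in column '", by, "': ",
           paste(setdiff(contrast, parameters[[by]]), collapse = ", "))
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(seed)
    contrasts <- lapply(params, function(pp) {
      per_subj <- vapply(split(parameters, parameters$subject), function(d) {
        mean(d[[pp]][d[[by]] == contrast[1]]) -
          mean(d[[pp]][d[[by]] == contrast[2]])
      }, numeric(1))
      per_subj <- per_subj[is.finite(per_subj)]
      boots <- vapply(seq_len(n_boot), function(i)
        mean(sample(per_subj, replace = TRUE)), numeric(1))
      alpha <- (1 - conf) / 2
      data.frame(parameter = pp,
                 contrast = paste(contrast, collapse = " - "),
                 mean_difference = mean(per_subj),
                 ci_lower = stats::quantile(boots, alpha, names = FALSE),
                 ci_upper = stats::quantile(boots, 1 - alpha, names = FALSE),
                 n_subjects = length(per_subj))
    })
    out$contrasts <- do.call(rbind, contrasts)
    out$per_subject <- NULL
  }
  out
}
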
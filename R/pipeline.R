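#' Pipeline configuration
#'
#' Assembles the full configuration of a reproducible run with documented
#' defaults. All randomness derives from the single `seed`.
#'
#' @param seed top-level integer seed.
#' @param design `"exp1"` (3 vs 6 training) or `"exp2"` (2 vs 3).
#' @param choices_csv optional path to an existing choice-table CSV; when
#'   given, simulation is skipped and the CSV is ingested (schema per
#'   [validate_choice_table()]).
#' @param stimulus stimulus generation parameters, see [pair_params()].
#' @param n_pairs_per_condition stimulus pairs generated per condition for the
#'   magnitude and spectral reports.
#' @param spectra_side_px rendered image side for spectral analysis.
#' @param recall_per_session rewarded recall trials per test day.
#' @param criterion_threshold learning-criterion accuracy.
#' @param max_sessions training session budget.
#' @param selection_criterion `"BIC"` or `"AIC"` for backward elimination.
#' @param dc_included,use_power_not_amplitude default spectral options.
#' @param out_dir optional output directory for CSV/JSON reports, stimulus
#'   PNGs and the run log.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, design = "exp1", choices_csv = NULL,
                            stimulus = pair_params(),
                            n_pairs_per_condition = 2,
                            spectra_side_px = 256,
                            recall_per_session = 32,
                            criterion_threshold = 0.75,
                            max_sessions = 30,
                            selection_criterion = "BIC",
                            dc_included = FALSE,
                            use_power_not_amplitude = FALSE,
                            out_dir = NULL) {
  cfg <- list(seed = seed, design = design, choices_csv = choices_csv,
              stimulus = stimulus,
              n_pairs_per_condition = n_pairs_per_condition,
              spectra_side_px = spectra_side_px,
              recall_per_session = recall_per_session,
              criterion_threshold = criterion_threshold,
              max_sessions = max_sessions,
              selection_criterion = selection_criterion,
              dc_included = dc_included,
              use_power_not_amplitude = use_power_not_amplitude,
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take their documented defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$stimulus)) raw$stimulus <- do.call(pair_params, raw$stimulus)
  do.call(pipeline_config, raw)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates generation, simulation (or CSV ingestion) and analysis:
#' simulates (or loads) the choice table; analyses training accuracy over the
#' last two sessions per fish with backward GLMM selection followed by a
#' pooled exact binomial test; analyses test-phase choices the same way;
#' runs the congruency-level analysis; generates stimulus pairs per condition
#' with their magnitude report; and computes per-condition total-power
#' indices under both DC policies and both amplitude/power options. When
#' `out_dir` is set, CSV/JSON reports, stimulus PNGs and a run log (seed and
#' effective config) are written.
#'
#' @param config a `pipeline_config`, or a path to a YAML config file.
#' @return A report list with elements `choices`, `training`, `test`,
#'   `congruency`, `stimuli`, `spectra`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$choices_csv) && !file.exists(config$choices_csv))
    stop("config error: choices_csv does not exist: ", config$choices_csv)

  choices <- pipeline_stage("data", {
    if (!is.null(config$choices_csv)) {
      tab <- utils::read.csv(config$choices_csv, stringsAsFactors = FALSE)
      validate_choice_table(tab)
      tab
    } else {
      simulate_study(config$design, seed = config$seed,
                     max_sessions = config$max_sessions)$choices
    }
  })

  training <- pipeline_stage("training-analysis", {
    tr <- choices[choices$phase == "training", , drop = FALSE]
    last2 <- do.call(rbind, lapply(split(tr, tr$fish_id), function(d) {
      keep <- sort(unique(d$session), decreasing = TRUE)[1:2]
      d[d$session %in% keep, , drop = FALSE]
    }))
    fit <- backward_select(last2, "geometry_control * spatial_control",
                           criterion = config$selection_criterion)
    resp <- last2[last2$responded == 1, ]
    pooled <- exact_binomial(sum(resp$chose_target), nrow(resp))
    list(glmm = fit, pooled = pooled,
         natural_units = inv_logit(fit$fixed_effects$estimate[1]))
  })

  test <- pipeline_stage("test-analysis", {
    te <- choices[choices$phase == "test", , drop = FALSE]
    fit <- backward_select(
      te, "comparison + geometry_control * spatial_control",
      criterion = config$selection_criterion)
    resp <- te[te$responded == 1, ]
    pooled <- exact_binomial(sum(resp$chose_target), nrow(resp))
    list(glmm = fit, pooled = pooled,
         natural_units = inv_logit(fit$fixed_effects$estimate[1]))
  })

  congruency <- pipeline_stage("congruency-analysis",
    congruency_analysis(choices[choices$phase == "test", , drop = FALSE]))

  cmp <- if (config$design == "exp1") c(3L, 6L) else c(2L, 3L)
  stimuli <- pipeline_stage("stimulus-generation", {
    conds <- all_conditions()
    pairs <- list()
    counter <- 0L
    for (cc in names(conds)) for (k in seq_len(config$n_pairs_per_condition)) {
      counter <- counter + 1L
      pairs[[length(pairs) + 1L]] <- generate_pair(
        cmp[1], cmp[2], conds[[cc]], config$stimulus,
        seed = (config$seed + 104729L * counter) %% .Machine$integer.max)
    }
    list(pairs = pairs, magnitudes = magnitude_report(pairs))
  })

  spectra <- pipeline_stage("spectral-analysis",
    power_index_report(cmp[1], cmp[2],
                       n_pairs = config$n_pairs_per_condition,
                       seed = config$seed, side_px = config$spectra_side_px,
                       params = config$stimulus))

  report <- list(choices = choices, training = training, test = test,
                 congruency = congruency, stimuli = stimuli,
                 spectra = spectra, config = config)
  if (!is.null(config$out_dir))
    pipeline_stage("report-output", write_pipeline_report(report))
  report
}

write_pipeline_report <- function(report) {
  out <- report$config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$choices, file.path(out, "choices.csv"),
                   row.names = FALSE)
  utils::write.csv(report$stimuli$magnitudes,
                   file.path(out, "magnitudes.csv"), row.names = FALSE)
  utils::write.csv(report$spectra, file.path(out, "power_index.csv"),
                   row.names = FALSE)
  for (i in seq_along(report$stimuli$pairs))
    write_stimulus_pair(report$stimuli$pairs[[i]],
                        file.path(out, "stimuli"),
                        prefix = sprintf("pair_%03d", i))
  summary_json <- list(
    seed = report$config$seed,
    design = report$config$design,
    training = list(
      selected_model = utils::tail(report$training$glmm$elimination_trace$model, 1),
      estimate_log_odds = report$training$glmm$fixed_effects$estimate[1],
      natural_units = report$training$natural_units,
      pooled = unclass(report$training$pooled)),
    test = list(
      selected_model = utils::tail(report$test$glmm$elimination_trace$model, 1),
      estimate_log_odds = report$test$glmm$fixed_effects$estimate[1],
      natural_units = report$test$natural_units,
      pooled = unclass(report$test$pooled)),
    congruency_contrasts = report$congruency$contrasts,
    congruency_levels = report$congruency$levels)
  jsonlite::write_json(summary_json, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- report$config
  cfg$stimulus <- as.list(cfg$stimulus)
  writeLines(c(
    paste0("run at: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("R version: ", R.version.string),
    "effective config:",
    yaml::as.yaml(unclass(cfg))), file.path(out, "run_log.txt"))
  invisible(out)
}
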
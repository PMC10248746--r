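#' Render a hazard-ratio table from a fit
#'
#' One row per model term: hazard ratio, 95 percent CI bounds, 2-sided
#' p-value and a significance flag at 0.05.  A non-converged fit is still
#' rendered, with a warning banner recorded in the `warning` attribute and
#' a `warning` column note.
#'
#' @param fit A `td_hazard_fit`.
#' @return data.frame with columns `term`, `hr`, `ci_lower`, `ci_upper`,
#'   `p`, `significant`.
#' @export
render_hr_table <- function(fit) {
  tab <- data.frame(term = fit$terms,
                    hr = unname(fit$hazard_ratio),
                    ci_lower = unname(fit$ci_lower),
                    ci_upper = unname(fit$ci_upper),
                    p = unname(fit$p_value),
                    significant = unname(fit$p_value < 0.05),
                    stringsAsFactors = FALSE)
  if (!fit$converged) {
    attr(tab, "warning") <- "model did not converge; estimates unreliable"
    warning("rendering HR table for a non-converged fit", call. = FALSE)
  }
  tab
}

#' Read and validate a pipeline configuration
#'
#' YAML (or list) with fields: either `preset` (+ optional `n_patients`,
#' `sim_seed`) or `inputs: {exposures, covariates, outcomes}` CSV paths;
#' optional `scheme: {window_start, window_end, n_intervals}`, `catalogue`,
#' `horizon`, `coding`, `ties`, `seed`, `out_dir`, `antibiotic_terms`
#' (restriction for the severe-grade endpoint), and `boruta:
#' {n_iter, ntree, alpha}`, `msm: {enabled, truncation}` blocks.
#'
#' @param config Path to a YAML file, or a list.
#' @return Validated config list with defaults filled in.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  defaults <- list(horizon = 180L, coding = "persistent", ties = "efron",
                   seed = 1L, sim_seed = 1L, n_patients = NULL,
                   antibiotic_terms = NULL, out_dir = NULL,
                   boruta = list(), msm = list())
  config <- utils::modifyList(defaults, config)
  config$boruta <- utils::modifyList(
    list(n_iter = 100L, ntree = 500L, alpha = 0.05), config$boruta)
  config$msm <- utils::modifyList(
    list(enabled = TRUE, truncation = NULL, select = FALSE), config$msm)
  has_preset <- !is.null(config$preset)
  has_inputs <- !is.null(config$inputs)
  if (!has_preset && !has_inputs)
    stop("config needs either 'preset' or 'inputs'", call. = FALSE)
  if (has_preset && !config$preset %in% names(preset_scenarios()))
    stop("unknown preset '", config$preset, "'; available: ",
         paste(names(preset_scenarios()), collapse = ", "), call. = FALSE)
  config
}

config_fingerprint <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Run the full three-model pipeline
#'
#' Loads (or simulates) a cohort, encodes the exposure design once, and
#' runs the three estimators independently on it: the Fine-Gray
#' time-dependent hazard model with separation handling and AIC backward
#' elimination; the marginal structural model with stabilized IPTW; and
#' the shadow-feature random-forest selector.  A failing stage is recorded
#' in the report and the remaining stages still run.
#'
#' @param config A config list or YAML path (see
#'   [read_pipeline_config()]).
#' @return A `run_report`: per-model HR tables, the selection trace,
#'   weight diagnostics, feature decisions, and a config fingerprint.  If
#'   `config$out_dir` is set, all artifacts are also written there.
#' @export
run_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  fingerprint <- config_fingerprint(config[setdiff(names(config),
                                                   "out_dir")])
  if (!is.null(config$preset)) {
    cfg <- preset_scenarios()[[config$preset]]
    if (!is.null(config$n_patients)) {
      cfg$n_patients <- as.integer(config$n_patients)
      validate_sim_config(cfg)
    }
    cohort <- simulate_cohort(cfg, seed = config$sim_seed)
    records <- cohort$records
    covariates <- cohort$covariates
    outcomes <- cohort$outcomes
    catalogue <- cfg$catalogue
    scheme <- cfg$scheme
    confounders <- NULL  # fever is treated as unmeasured unless exposed
  } else {
    records <- read_exposure_records(config$inputs$exposures)
    covariates <- read_covariates(config$inputs$covariates)
    outcomes <- read_outcomes(config$inputs$outcomes)
    catalogue <- config$catalogue %||% default_antibiotic_classes()
    scheme <- if (!is.null(config$scheme))
      build_interval_scheme(config$scheme$window_start,
                            config$scheme$window_end,
                            config$scheme$n_intervals)
    else build_interval_scheme()
    confounders <- if (!is.null(config$inputs$confounders))
      read.csv(config$inputs$confounders, stringsAsFactors = FALSE)
    else NULL
  }

  design <- encode_exposures(records, scheme, catalogue,
                             coding = config$coding,
                             patients = covariates$patient_id)
  if (!is.null(config$antibiotic_terms)) {
    keep <- design$columns$abx_class %in% config$antibiotic_terms |
      design$columns$name %in% config$antibiotic_terms
    for (nm in design$columns$name[!keep])
      design <- drop_design_column(design, nm)
  }

  report <- list(meta = list(fingerprint = fingerprint,
                             timestamp = format(Sys.time(), tz = "UTC"),
                             package_version =
                               as.character(utils::packageVersion("abxgvhd"))),
                 config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      list(error = conditionMessage(e))
    })
  }

  report$model1 <- stage("model1", {
    d1 <- resolve_separation(design, outcomes, config$horizon)
    sel <- backward_eliminate(d1, outcomes, covariates,
                              alpha = 0.05, horizon = config$horizon,
                              ties = config$ties)
    list(hr_table = render_hr_table(sel$fit),
         trace = sel$trace, fit = sel$fit, design = sel$design)
  })

  report$model2 <- if (isTRUE(config$msm$enabled)) stage("model2", {
    tm <- suppressWarnings(
      fit_treatment_models(design, covariates, confounders))
    ws <- stabilized_weights(tm, design, covariates, confounders)
    if (!is.null(config$msm$truncation))
      ws <- truncate_weights(ws, config$msm$truncation[1],
                             config$msm$truncation[2])
    d2 <- if (!is.null(report$model1$design)) report$model1$design else design
    ex <- msm_expand(d2, covariates, outcomes, config$horizon)
    ex <- fine_gray_extend(ex, outcomes)
    fit <- fit_msm(ex, ws, ties = config$ties)
    list(hr_table = render_hr_table(fit), fit = fit,
         weight_diagnostics = weight_diagnostics(ws))
  }) else NULL

  report$model3 <- stage("model3", {
    fm <- build_feature_matrix(design, covariates, outcomes,
                               config$horizon)
    br <- run_boruta(fm$X, fm$y, n_iter = config$boruta$n_iter,
                     alpha = config$boruta$alpha,
                     ntree = config$boruta$ntree, seed = config$seed)
    list(decisions = br$decision, hit_count = br$hit_count,
         z_scores = br$z_scores, result = br,
         n_excluded = fm$n_excluded)
  })

  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline report (fingerprint", x$meta$fingerprint, ")\n")
  for (m in c("model1", "model2", "model3")) {
    cat("--", m, "--\n")
    if (is.null(x[[m]])) { cat("  skipped\n"); next }
    if (!is.null(x[[m]]$error)) { cat("  ERROR:", x[[m]]$error, "\n"); next }
    if (!is.null(x[[m]]$hr_table)) {
      sig <- x[[m]]$hr_table[x[[m]]$hr_table$significant, , drop = FALSE]
      cat(sprintf("  %d terms, %d significant at 0.05\n",
                  nrow(x[[m]]$hr_table), nrow(sig)))
    }
    if (!is.null(x[[m]]$decisions))
      cat(sprintf("  features: %d important, %d tentative, %d unimportant\n",
                  sum(x[[m]]$decisions == "important"),
                  sum(x[[m]]$decisions == "tentative"),
                  sum(x[[m]]$decisions == "unimportant")))
  }
  invisible(x)
}

#' Write all report artifacts to a directory
#'
#' CSV for tabular outputs, JSON for model objects; the timestamp lives
#' only in `meta.json` so the analytic artifacts are byte-reproducible for
#' identical inputs and seed.
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(fingerprint = report$meta$fingerprint),
                       file.path(dir, "fingerprint.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$model1$hr_table))
    write.csv(report$model1$hr_table, file.path(dir, "model1_hr.csv"),
              row.names = FALSE)
  if (!is.null(report$model1$trace))
    write_trace_json(report$model1$trace,
                     file.path(dir, "model1_trace.json"))
  if (!is.null(report$model1$fit))
    write_fit_json(report$model1$fit, file.path(dir, "model1_fit.json"))
  if (!is.null(report$model2$hr_table)) {
    write.csv(report$model2$hr_table, file.path(dir, "model2_hr.csv"),
              row.names = FALSE)
    write_fit_json(report$model2$fit, file.path(dir, "model2_fit.json"))
    jsonlite::write_json(report$model2$weight_diagnostics,
                         file.path(dir, "model2_weights.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$model3$result))
    write_boruta_json(report$model3$result,
                      file.path(dir, "model3_boruta.json"))
  invisible(dir)
}
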
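## Orchestration of the two study workflows as plain functions writing
## text artifacts (CSV/JSON) plus a JSON run manifest. A thin command-line
## wrapper over these lives in exec/adews.

#' Assemble a pipeline configuration
#'
#' @param config A named list, or a path to a YAML file holding one.
#'   Recognised fields: `seed`, `outdir`, `covariates`, `controls`
#'   (minsplit/minbucket/cp/maxdepth), `cv` (v/seed/rule), `augmentation`
#'   (strategy/k), `bands` (low/high), `bootstrap` (B), `params`
#'   (trajectory-generator overrides).
#'
#' @return A list of class `"pipeline_config"` with defaults filled in.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- list(
    seed = config$seed %||% 1L,
    outdir = config$outdir %||% ".",
    covariates = config$covariates %||%
      c("sex", "education", "age", "mmse", "apoe4", "up53"),
    controls = do.call(rtree_control, config$controls %||% list()),
    cv = config$cv %||% list(v = 10L, seed = 1L, rule = "min"),
    augmentation = {
      aug <- do.call(augmentation_spec,
                     config$augmentation %||%
                       list(strategy = "synthetic-positive"))
      # tie the augmentation draw to the run seed so reruns of the same
      # manifest reproduce identical artifacts
      if (is.null(aug$seed)) aug$seed <- (config$seed %||% 1L) + 1000L
      aug
    },
    bands = do.call(risk_bands, config$bands %||% list()),
    bootstrap_B = config$bootstrap$B %||% 1000L,
    params = if (is.null(config$params)) trajectory_params()
             else do.call(trajectory_params, config$params))
  structure(cfg, class = "pipeline_config")
}

write_manifest <- function(cfg, outputs, path) {
  jsonlite::write_json(list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("adews")),
    r_version = as.character(getRversion()),
    controls = unclass(cfg$controls),
    cv = cfg$cv,
    augmentation = cfg$augmentation[c("strategy", "k")],
    bands = unclass(cfg$bands),
    bootstrap_B = cfg$bootstrap_B,
    covariates = cfg$covariates,
    outputs = outputs
  ), path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the longitudinal risk-stratification workflow
#'
#' Simulates (or loads) a three-visit cohort, runs the rolling-window
#' early-warning procedure, stratifies the final-window predictions into
#' risk zones, and writes `cohort.csv`, `predictions.csv`,
#' `stratification.json` and `manifest.json` into the output directory.
#'
#' @param config A [pipeline_config()] (or list/YAML path accepted by it).
#' @param cohort Optional pre-built cohort table; otherwise simulated from
#'   `config$params` with `config$seed`.
#'
#' @return Invisibly, a list with the cohort, the rolling-window result,
#'   the stratification report and the bootstrap CIs.
#' @export
run_longitudinal_pipeline <- function(config = pipeline_config(),
                                      cohort = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort))
    cohort <- generate_longitudinal_cohort(config$params, seed = config$seed)
  rw <- rolling_window(cohort, covariates = config$covariates,
                       controls = config$controls, cv = config$cv,
                       augmentation = config$augmentation)
  pr <- rw$predictions[rw$predictions$window ==
                         max(rw$predictions$window), , drop = FALSE]
  report <- agreement_report(zone_of(pr$score, config$bands), pr$outcome)
  ci <- bootstrap_predictions(rw, B = config$bootstrap_B,
                              seed = config$seed, bands = config$bands)

  paths <- file.path(config$outdir,
                     c("cohort.csv", "predictions.csv",
                       "stratification.json", "manifest.json"))
  write_cohort(cohort, paths[1])
  utils::write.csv(rw$predictions, paths[2], row.names = FALSE)
  jsonlite::write_json(list(
    counts = report$counts, agreement_pct = report$agreement,
    proportion_p = as.list(report$proportion_p),
    fisher_p = report$fisher_p, rule = report$rule,
    bootstrap = lapply(ci, as.list)
  ), paths[3], auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  write_manifest(config, basename(paths[1:3]), paths[4])
  invisible(list(cohort = cohort, rolling_window = rw, report = report,
                 bootstrap = ci, paths = paths))
}

#' Run the A/T classification workflow on an aMCI cohort
#'
#' Simulates (or loads) a cross-sectional aMCI cohort with CSF profiles,
#' applies the A/T classification, compares the plasma biomarker across
#' strata, computes the ROC of the biomarker for amyloid positivity, and
#' writes `at_cohort.csv`, `at_report.json` and `manifest.json`.
#'
#' @param config A [pipeline_config()]; its `seed`, `outdir` and
#'   `bootstrap_B` fields are used.
#' @param cohort Optional pre-built [generate_at_cohort()] table.
#'
#' @return Invisibly, a list with the cohort, the stratum table, the test
#'   p-values and the ROC.
#' @export
run_at_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort)) cohort <- generate_at_cohort(seed = config$seed)
  cls <- classify_at(cohort$abeta42, cohort$ptau)
  ok <- cls != "unclassifiable"
  tests <- classical_tests(cohort$up53[ok], droplevels(cls[ok]))
  abeta_pos <- cls %in% c("A+/T-", "A+/T+")
  r <- roc_curve(cohort$up53[ok], abeta_pos[ok])
  ci <- auc_ci(cohort$up53[ok], abeta_pos[ok], B = config$bootstrap_B,
               seed = config$seed)

  paths <- file.path(config$outdir,
                     c("at_cohort.csv", "at_report.json", "manifest.json"))
  utils::write.csv(as.data.frame(cohort), paths[1], row.names = FALSE)
  jsonlite::write_json(list(
    strata = as.list(table(cls)),
    kruskal_wallis_p = tests$kruskal_wallis,
    pairwise_wilcoxon_holm = as.data.frame(tests$pairwise),
    abeta_roc = list(auc = r$auc, sensitivity = r$sensitivity,
                     specificity = r$specificity,
                     ci = as.numeric(ci))
  ), paths[2], auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  write_manifest(config, basename(paths[1:2]), paths[3])
  invisible(list(cohort = cohort, strata = table(cls), tests = tests,
                 roc = r, auc_ci = ci, paths = paths))
}
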
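#' Configuration for an end-to-end pipeline run
#'
#' Bundles inputs and settings for [run_pipeline()]. Cohort inputs may be
#' in-memory tibbles or CSV paths (resolved at validation time). A seed is
#' mandatory whenever a stochastic stage (the survival bootstrap) is enabled.
#'
#' @param patients Patient tibble or CSV path.
#' @param markers Marker tibble or CSV path.
#' @param algorithm Cascade for classification (`"promise"`, `"who"`,
#'   `"pole_only"`).
#' @param selection Testing selection mode for the cost stage.
#' @param costs A [cost_config()] or YAML path.
#' @param rules A risk rule table or CSV path (used when the cohort lacks
#'   explicit risk labels).
#' @param pathogenic_list A [pathogenic_variants()] or variant-file path.
#' @param survival Either `NULL` (skip the survival stage) or a list with
#'   elements `endpoint` (`"pfs"`/`"os"`), `horizon`, `df`, `bootstrap_B`.
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(patients, markers, algorithm = "promise",
                            selection = "all", costs = cost_config(),
                            rules = default_risk_rules(),
                            pathogenic_list = pathogenic_variants(),
                            survival = list(endpoint = "pfs", horizon = 60,
                                            df = 3, bootstrap_B = 0),
                            seed = NULL) {
  if (is.character(patients)) patients <- read_cohort(patients, "patients")
  else patients <- validate_patients(patients)
  if (is.character(markers)) markers <- read_cohort(markers, "markers")
  else markers <- validate_markers(markers)
  if (is.character(costs)) costs <- read_cost_config(costs)
  if (is.character(rules)) rules <- read_risk_rules(rules)
  if (is.character(pathogenic_list)) {
    pathogenic_list <- read_variant_list(pathogenic_list)
  }
  if (!is.null(survival) && (survival$bootstrap_B %||% 0) > 0 &&
      is.null(seed)) {
    abort("seed is mandatory when the bootstrap stage is enabled",
          class = "endomol_config_error")
  }
  structure(list(patients = patients, markers = markers,
                 algorithm = algorithm, selection = selection, costs = costs,
                 rules = rules, pathogenic_list = pathogenic_list,
                 survival = survival, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order - DNA quality-control filter, molecular
#' classification, risk stratification and integration, early-stage cost
#' comparison, and (optionally) the CFS-adjusted RMST survival analysis -
#' and returns a manifest sufficient to re-run identically: stage outputs,
#' exclusion accounting (recruited = analyzed + excluded), the seed, and
#' collected warnings.
#'
#' @param config A [pipeline_config()].
#' @return An `endomol_manifest` list with elements `counts`, `calls`,
#'   `assignments`, `cost_report`, `rmst` (or `NULL`), `subgroup_counts`,
#'   `seed`, `warnings`, `package_version`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character()
  log_warn <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  withCallingHandlers({
    calls <- classify_cascade(config$markers, config$algorithm,
                              config$pathogenic_list)
    excluded <- sum(calls$subgroup == "excluded_qc")
    analyzed <- nrow(calls) - excluded
    joined <- dplyr::inner_join(config$patients, calls, by = "patient_id")
    conv <- if ("conventional_risk" %in% names(config$patients)) {
      joined$conventional_risk
    } else {
      conventional_risk(joined, config$rules)
    }
    assignments <- integrated_risk(joined, joined$subgroup, conv)
    analyzed_pat <- joined[joined$subgroup != "excluded_qc", ]
    early <- config$patients[config$patients$early_stage &
      config$patients$patient_id %in% analyzed_pat$patient_id, ]
    cost_report <- strategy_comparison(
      early, config$markers,
      strategies = tibble(algorithm = config$algorithm,
                          selection = config$selection),
      costs = config$costs, rules = config$rules,
      pathogenic_list = config$pathogenic_list)
    rmst <- NULL
    if (!is.null(config$survival)) {
      s <- config$survival
      rmst <- adjusted_rmst(
        analyzed_pat, analyzed_pat$subgroup,
        endpoint = s$endpoint %||% "pfs", horizon = s$horizon %||% 60,
        df = s$df %||% 3, bootstrap_B = s$bootstrap_B %||% 0,
        seed = config$seed)
    }
    structure(
      list(
        counts = list(recruited = nrow(calls), excluded_qc = excluded,
                      analyzed = analyzed),
        subgroup_counts = count_levels(
          calls$subgroup[calls$subgroup != "excluded_qc"], SUBGROUPS),
        calls = calls, assignments = assignments,
        cost_report = cost_report, rmst = rmst,
        algorithm = config$algorithm, selection = config$selection,
        seed = config$seed, warnings = warnings_log,
        package_version = as.character(utils::packageVersion("endomol"))),
      class = "endomol_manifest")
  }, warning = log_warn)
}

#' @export
print.endomol_manifest <- function(x, ...) {
  cat("endomol pipeline manifest\n")
  cat(sprintf("  recruited %d = analyzed %d + excluded at DNA QC %d\n",
              x$counts$recruited, x$counts$analyzed, x$counts$excluded_qc))
  cat("  subgroups:",
      paste(names(x$subgroup_counts), x$subgroup_counts, collapse = ", "),
      "\n")
  cat(sprintf("  algorithm %s / selection %s, seed %s\n", x$algorithm,
              x$selection, x$seed %||% "none"))
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

#' Write a pipeline manifest to JSON
#'
#' Serializes the manifest counts, subgroup tallies, cost summary, RMST table
#' and warnings (tabular stage outputs are written alongside as CSV when
#' `dir` is given).
#'
#' @param manifest An `endomol_manifest`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  payload <- list(
    counts = manifest$counts,
    subgroup_counts = as.list(manifest$subgroup_counts),
    algorithm = manifest$algorithm, selection = manifest$selection,
    seed = manifest$seed, warnings = manifest$warnings,
    package_version = manifest$package_version,
    cost = list(
      reference_total = attr(manifest$cost_report, "reference_total"),
      strategies = as_tibble(manifest$cost_report)[
        c("strategy_id", "testing_cost", "therapy_change_cost",
          "total_cost", "pct_change_vs_reference")]),
    rmst = if (!is.null(manifest$rmst)) as_tibble(manifest$rmst)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
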
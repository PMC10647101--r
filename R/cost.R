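#' Adjuvant therapy cost for a risk group
#'
#' Exact integer lookup in the configured treatment costs (Baht): nothing for
#' low risk, vaginal brachytherapy for intermediate, external beam
#' radiotherapy plus brachytherapy for high-intermediate, chemoradiation for
#' high.
#'
#' @param level Risk level(s).
#' @param costs A [cost_config()].
#' @return Integer Baht, vectorized over `level`.
#' @export
adjuvant_cost <- function(level, costs = cost_config()) {
  bad <- !(level %in% names(costs$treatment_costs))
  if (any(bad)) {
    abort(paste0("risk level missing from treatment costs: ",
                 paste(unique(level[bad]), collapse = ", ")),
          class = "endomol_config_error")
  }
  unname(costs$treatment_costs[level])
}

#' Total testing cost for a tally of tests performed
#'
#' @param tallies Named integer vector from [tally_test_usage()].
#' @param costs A [cost_config()].
#' @return Integer Baht.
#' @export
testing_cost <- function(tallies, costs = cost_config()) {
  if (length(tallies) == 0) return(0L)
  bad <- !(names(tallies) %in% names(costs$test_unit_costs))
  if (any(bad)) {
    abort(paste0("test missing from unit costs: ",
                 paste(names(tallies)[bad], collapse = ", ")),
          class = "endomol_config_error")
  }
  sum(as.integer(tallies) * costs$test_unit_costs[names(tallies)])
}

#' Net therapy-change cost of molecular integration
#'
#' For each patient whose adjuvant therapy is omitted (early-stage
#' POLE-mutant), the conventional adjuvant cost is subtracted. Escalations
#' (early-stage p53-abnormal moved to high risk) are priced by mode: in
#' `move_to_high` each escalated patient adds the difference between the
#' high-risk and the conventional adjuvant cost; in `explicit_override` a
#' strategy with any escalated patient reports the configured net override
#' instead of a computed amount (strategies with omissions only are always
#' computed).
#'
#' @param assignments A tibble from [integrated_risk()].
#' @param costs A [cost_config()].
#' @return Signed integer Baht.
#' @export
therapy_change_cost <- function(assignments, costs = cost_config()) {
  omitted <- assignments$therapy_action == "omit_adjuvant"
  added <- assignments$therapy_action == "add_chemoradiation"
  omit_part <- -sum(adjuvant_cost(assignments$conventional_risk[omitted], costs))
  if (costs$p53_upgrade_mode == "explicit_override" && any(added)) {
    if (is.null(costs$therapy_change_override)) {
      abort("explicit_override mode requires therapy_change_override",
            class = "endomol_config_error")
    }
    return(as.integer(costs$therapy_change_override))
  }
  add_part <- sum(adjuvant_cost("high", costs) * sum(added)) -
    sum(adjuvant_cost(assignments$conventional_risk[added], costs))
  as.integer(omit_part + add_part)
}

#' Strategies compared in the cost analysis
#'
#' The conventional reference plus the six molecular strategies: each cascade
#' (`who`, `promise`, `pole_only`) applied to all early-stage patients and to
#' the selective subset with at least intermediate conventional risk.
#'
#' @return A tibble with columns `algorithm` and `selection`.
#' @export
default_strategies <- function() {
  tidyr::expand_grid(algorithm = c("who", "promise", "pole_only"),
                     selection = c("all", "at_least_intermediate"))
}

#' Compare post-operative management costs across testing strategies
#'
#' Runs each strategy end to end on an early-stage cohort: select patients
#' for testing, classify them by the strategy's cascade, integrate molecular
#' results into risk groups, tally tests, and price testing and therapy
#' changes against the conventional reference (no testing, conventional risk
#' management for everyone). Total cost is the reference adjuvant total plus
#' the strategy's testing cost plus its net therapy change; percent change is
#' relative to the reference total, rounded half away from zero at one
#' decimal.
#'
#' If the cohort carries a `conventional_risk` column it is used as-is;
#' otherwise risks are assigned from `rules`.
#'
#' @param patients Validated patient tibble (early-stage; other rows are
#'   dropped with a warning).
#' @param markers Marker-profile tibble covering the cohort.
#' @param strategies Tibble with `algorithm` and `selection` columns;
#'   defaults to [default_strategies()].
#' @param costs A [cost_config()].
#' @param rules Risk rule table used only when `patients` lacks explicit
#'   conventional risk labels.
#' @param pathogenic_list Pathogenic POLE variant list.
#' @return A `strategy_comparison` tibble: one row per strategy (reference
#'   first) with risk-group counts, test tallies, testing cost, therapy-change
#'   cost, adjuvant total, total cost, and percent change versus reference.
#'   The reference total and any annotations are carried as attributes.
#' @export
strategy_comparison <- function(patients, markers,
                                strategies = default_strategies(),
                                costs = cost_config(),
                                rules = default_risk_rules(),
                                pathogenic_list = pathogenic_variants()) {
  if (nrow(patients) == 0) {
    abort("empty cohort", class = "endomol_cost_error")
  }
  if (!all(patients$early_stage)) {
    warn("dropping stage III-IV patients: the cost comparison is restricted to early stage")
    patients <- dplyr::filter(patients, .data$early_stage)
    if (nrow(patients) == 0) abort("empty cohort", class = "endomol_cost_error")
  }
  conv <- if ("conventional_risk" %in% names(patients)) {
    patients$conventional_risk
  } else {
    conventional_risk(patients, rules)
  }
  stopifnot(all(conv %in% RISK_LEVELS))
  cohort <- dplyr::mutate(patients, conventional_risk = conv)
  markers <- validate_markers(markers)
  reference_total <- sum(adjuvant_cost(conv, costs))
  annotations <- character()

  ref_row <- tibble(
    strategy_id = "conventional", algorithm = "conventional", selection = NA_character_,
    risk_group_counts = list(count_levels(conv, RISK_LEVELS)),
    test_tallies = list(setNames(integer(length(TESTS)), TESTS)),
    testing_cost = 0L, therapy_change_cost = 0L,
    adjuvant_cost_total = reference_total, total_cost = reference_total,
    pct_change_vs_reference = 0
  )

  rows <- purrr::pmap(strategies, function(algorithm, selection) {
    selected <- select_for_testing(cohort, selection)
    sel_markers <- dplyr::semi_join(markers, selected, by = "patient_id")
    calls <- classify_cascade(sel_markers, algorithm, pathogenic_list)
    tallies <- tally_test_usage(calls)
    subgroup <- dplyr::left_join(
      cohort["patient_id"],
      calls[c("patient_id", "subgroup")], by = "patient_id")$subgroup
    # pole_only pass-through patients keep conventional management: their
    # NSMP label is a "not tested further" marker, which integrated_risk
    # already treats as no modification.
    assignments <- integrated_risk(cohort, subgroup, conv)
    t_cost <- testing_cost(tallies, costs)
    change <- therapy_change_cost(assignments, costs)
    adjuvant_total <- reference_total + change
    total <- adjuvant_total + t_cost
    tibble(
      strategy_id = paste0(algorithm, "/", selection),
      algorithm = algorithm, selection = selection,
      risk_group_counts = list(count_levels(assignments$integrated_risk,
                                            RISK_LEVELS)),
      test_tallies = list(tallies),
      testing_cost = t_cost, therapy_change_cost = change,
      adjuvant_cost_total = as.integer(adjuvant_total),
      total_cost = as.integer(total),
      pct_change_vs_reference =
        round_half_up(100 * (total - reference_total) / reference_total, 1)
    )
  })
  out <- dplyr::bind_rows(ref_row, rows)
  if (any(out$algorithm == "who" &
          !is.na(out$selection) & out$selection == "at_least_intermediate")) {
    annotations <- c(annotations, paste(
      "WHO/selective testing cost is computed from unit costs; the",
      "originally reported figure (310,840 Baht) exceeds it by 2,000 Baht",
      "and cannot be reproduced from the printed counts."))
  }
  new_strategy_comparison(out, reference_total = reference_total,
                          annotations = annotations)
}

count_levels <- function(x, levels) {
  setNames(as.integer(table(factor(x, levels = levels))), levels)
}

new_strategy_comparison <- function(df, reference_total, annotations) {
  structure(df, class = c("strategy_comparison", class(tibble())),
            reference_total = as.integer(reference_total),
            annotations = annotations)
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(format_cost_table(x), sep = "\n")
  invisible(x)
}

#' Plot a strategy cost comparison
#'
#' Bar chart of total post-operative management cost per strategy, split into
#' the adjuvant and testing components, with percent change versus the
#' conventional reference printed above each bar.
#'
#' @param object A `strategy_comparison` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.strategy_comparison <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(strategy_id = factor(.data$strategy_id,
                                       levels = .data$strategy_id))
  long <- df |>
    dplyr::select("strategy_id", adjuvant = "adjuvant_cost_total",
                  testing = "testing_cost") |>
    tidyr::pivot_longer(c("adjuvant", "testing"),
                        names_to = "component", values_to = "baht")
  ggplot(long, aes(x = .data$strategy_id, y = .data$baht,
                   fill = .data$component)) +
    geom_col() +
    geom_text(data = df,
              aes(x = .data$strategy_id, y = .data$total_cost,
                  label = sprintf("%+.1f%%", .data$pct_change_vs_reference)),
              vjust = -0.4, inherit.aes = FALSE, size = 3) +
    scale_y_continuous(labels = fmt_baht) +
    labs(x = NULL, y = "Cost (Baht)", fill = NULL,
         title = "Post-operative management cost by testing strategy") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}
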
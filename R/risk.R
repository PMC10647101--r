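#' Default conventional risk rule table
#'
#' An ordered, first-match-wins rule table assigning adjuvant-therapy risk
#' groups from stage, histology and LVSI. The low-risk rule is fixed: FIGO
#' stage IA, low-grade endometrioid histology, and negative or focal LVSI.
#' The non-low tiers are a documented stand-in modeled on the
#' ESGO/ESTRO/ESMO prognostic groups (the source guideline does not reduce to
#' three printed criteria); cohorts whose risk labels are known should carry
#' them as data (see [table3_cohort()]) rather than rely on any default table.
#'
#' @return A `risk_rules` tibble with columns `figo_stage`, `histology`,
#'   `lvsi` (semicolon-joined level sets, `NA` = any) and `level`; a final
#'   unconditional rule guarantees totality.
#' @export
default_risk_rules <- function() {
  rules <- tibble::tribble(
    ~figo_stage, ~histology,                           ~lvsi,              ~level,
    "IA",        "endometrioid_low_grade",             "negative;focal",   "low",
    NA,          "non_endometrioid",                   NA,                 "high",
    "III;IV",    NA,                                   NA,                 "high",
    NA,          NA,                                   "substantial",      "high_intermediate",
    "II",        NA,                                   NA,                 "high_intermediate",
    "IB",        "endometrioid_high_grade",            NA,                 "high_intermediate",
    "IB",        "endometrioid_low_grade",             NA,                 "intermediate",
    "IA",        "endometrioid_high_grade",            NA,                 "intermediate",
    NA,          NA,                                   NA,                 "high_intermediate"
  )
  new_risk_rules(rules, provenance_label = "default-esgo-style (stand-in)")
}

new_risk_rules <- function(rules, provenance_label) {
  check_rules_total(rules)
  structure(as_tibble(rules), class = c("risk_rules", class(tibble())),
            provenance_label = provenance_label)
}

check_rules_total <- function(rules) {
  if (!all(c("figo_stage", "histology", "lvsi", "level") %in% names(rules))) {
    abort("risk rules need columns figo_stage, histology, lvsi, level",
          class = "endomol_config_error")
  }
  if (!all(rules$level %in% RISK_LEVELS)) {
    abort("risk rule level outside the four risk groups",
          class = "endomol_config_error")
  }
  cond <- rules[c("figo_stage", "histology", "lvsi")]
  if (!any(rowSums(!is.na(cond)) == 0)) {
    abort("risk rule table is not total: add an unconditional final rule",
          class = "endomol_config_error")
  }
  invisible(rules)
}

#' Read a risk rule table from CSV
#'
#' Columns `figo_stage`, `histology`, `lvsi` (semicolon-joined allowed levels,
#' empty = any) and `level`; rules apply in file order, first match wins. The
#' table must end with an unconditional rule (totality is checked at load).
#'
#' @param path CSV file of ordered rules.
#' @param provenance_label Label carried on the table.
#' @return A `risk_rules` tibble.
#' @export
read_risk_rules <- function(path, provenance_label = basename(path)) {
  rules <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  rules <- dplyr::mutate(rules, dplyr::across(
    dplyr::any_of(c("figo_stage", "histology", "lvsi")),
    ~ ifelse(is.na(.x) | .x == "", NA_character_, .x)))
  new_risk_rules(rules, provenance_label)
}

#' Assign conventional adjuvant-therapy risk groups
#'
#' Deterministic first-match assignment of each patient to one of the four
#' risk groups using an ordered rule table.
#'
#' @param patients A validated patient tibble ([validate_patients()]).
#' @param rules A `risk_rules` table; defaults to [default_risk_rules()].
#' @return Character vector of risk levels, one per patient.
#' @export
conventional_risk <- function(patients, rules = default_risk_rules()) {
  check_rules_total(rules)
  in_set <- function(value, set) {
    is.na(set) | value %in% strsplit(set, ";", fixed = TRUE)[[1]]
  }
  vapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    for (r in seq_len(nrow(rules))) {
      if (in_set(p$figo_stage, rules$figo_stage[r]) &&
          in_set(p$histology, rules$histology[r]) &&
          in_set(p$lvsi, rules$lvsi[r])) {
        return(rules$level[r])
      }
    }
    # unreachable: totality checked above
    rules$level[nrow(rules)]
  }, character(1))
}

#' Integrate molecular subgroups into risk assignments
#'
#' Applies the molecular treatment modifications to early-stage (FIGO I-II)
#' patients: POLE-mutant tumors de-escalate to low risk, with adjuvant therapy
#' omitted when the conventional group would have received any; p53-abnormal
#' tumors escalate to high risk, with chemoradiation added when the
#' conventional group was below high. Stage III-IV patients and patients
#' excluded at DNA quality control are never modified.
#'
#' @param patients Validated patient tibble (provides the early-stage flag).
#' @param subgroup Character vector of molecular subgroups aligned with
#'   `patients` (`NA` or `"excluded_qc"` leaves the assignment unchanged).
#' @param conventional Character vector of conventional risk levels.
#' @return A tibble with `patient_id`, `subgroup`, `conventional_risk`,
#'   `integrated_risk`, `therapy_action`
#'   (`unchanged`/`omit_adjuvant`/`add_chemoradiation`) and
#'   `eligible_for_modification`.
#' @export
integrated_risk <- function(patients, subgroup, conventional) {
  stopifnot(length(subgroup) == nrow(patients),
            length(conventional) == nrow(patients),
            all(conventional %in% RISK_LEVELS))
  eligible <- patients$early_stage & !is.na(subgroup) &
    subgroup %in% SUBGROUPS
  if (any(!is.na(subgroup) & subgroup == "excluded_qc")) {
    inform("patients excluded at DNA QC keep their conventional assignment")
  }
  integrated <- conventional
  action <- rep("unchanged", nrow(patients))
  demote <- eligible & subgroup == "POLE_mut"
  integrated[demote] <- "low"
  action[demote & conventional != "low"] <- "omit_adjuvant"
  promote <- eligible & subgroup == "p53_abn"
  integrated[promote] <- "high"
  action[promote & conventional != "high"] <- "add_chemoradiation"
  tibble(patient_id = patients$patient_id, subgroup = subgroup,
         conventional_risk = conventional, integrated_risk = integrated,
         therapy_action = action, eligible_for_modification = eligible)
}

#' Select patients for molecular testing
#'
#' `"all"` returns the cohort unchanged; `"at_least_intermediate"` keeps only
#' patients whose conventional risk is above low — the selective-testing
#' variant in which molecular results cannot change low-risk management.
#'
#' @param cohort A tibble containing a `conventional_risk` column.
#' @param mode `"all"` or `"at_least_intermediate"`.
#' @return The selected subset, row order preserved.
#' @export
select_for_testing <- function(cohort, mode = c("all", "at_least_intermediate")) {
  mode <- match.arg(mode)
  if (mode == "all") return(cohort)
  dplyr::filter(cohort, .data$conventional_risk != "low")
}
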
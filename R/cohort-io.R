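#' Read and validate a cohort table
#'
#' Reads a comma-separated cohort file (UTF-8, `.` decimal, header row) into a
#' validated tibble. Two schemas are supported: `"patients"` for
#' clinicopathological records with follow-up, and `"markers"` for marker-level
#' results (MMR/p53 immunohistochemistry, POLE variants, DNA quality control).
#'
#' Unknown columns are dropped with a warning; row order is preserved. A
#' two-level `lvsi` column coded `yes`/`no` is accepted and mapped to
#' `substantial`/`negative` with a warning, since the three-level coding is
#' what the low-risk rule needs.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema `"patients"` or `"markers"`.
#' @param col_map Optional named character vector mapping file headers to
#'   schema names, e.g. `c(stage = "figo_stage")`.
#' @return A validated tibble of patient records or marker profiles. Marker
#'   tables carry POLE variants in a `pole_variants` list-column of tibbles
#'   with columns `protein_change` and `exon`.
#' @seealso [validate_patients()], [validate_markers()], [write_cohort()]
#' @export
read_cohort <- function(path, schema = c("patients", "markers"),
                        col_map = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(paste0("cohort file not found: ", path), class = "endomol_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    hit <- names(col_map)[names(col_map) %in% names(df)]
    names(df)[match(hit, names(df))] <- unname(col_map[hit])
  }
  expected <- if (schema == "patients") patient_columns() else marker_columns()
  extra <- setdiff(names(df), names(expected))
  if (length(extra)) {
    warn(paste0("ignoring unknown column(s): ", paste(extra, collapse = ", ")))
    df <- df[setdiff(names(df), extra)]
  }
  if (schema == "patients") validate_patients(df) else validate_markers(df)
}

#' Write a cohort table
#'
#' Inverse of [read_cohort()]: serializes a validated cohort tibble to CSV so
#' that reading it back reproduces the input. Marker `pole_variants`
#' list-columns are flattened to `change:exon` pairs joined by `;`.
#'
#' @param cohort A tibble from [read_cohort()], [validate_patients()] or
#'   [validate_markers()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  if ("pole_variants" %in% names(out)) {
    out$pole_variants <- vapply(out$pole_variants, format_variants, character(1))
  }
  if ("early_stage" %in% names(out)) out$early_stage <- NULL
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# Required/optional schema columns. Values give the prototype class.
patient_columns <- function() {
  list(patient_id = "character", age = "numeric", figo_stage = "character",
       histology = "character", tumor_size = "numeric", invasion = "character",
       lvsi = "character", cervical_stromal_invasion = "logical",
       lymph_nodes = "character", pfs_months = "numeric",
       pfs_event = "logical", os_months = "numeric", os_event = "logical")
}
patient_required <- function() {
  setdiff(names(patient_columns()), "tumor_size")
}
marker_columns <- function() {
  list(patient_id = "character", pms2_status = "character",
       msh6_status = "character", ihc_internal_control_intact = "logical",
       p53_pct_strong_nuclear = "numeric", p53_any_nuclear_staining = "logical",
       p53_unequivocal_cytoplasmic = "logical",
       p53_pattern_override = "character", pole_variants = "list",
       gapdh_amplified = "logical", a260_280 = "numeric",
       a260_230 = "numeric")
}
marker_required <- function() {
  c("patient_id", "pms2_status", "msh6_status", "ihc_internal_control_intact",
    "pole_variants", "gapdh_amplified")
}

# All-NA CSV columns arrive typeless (logical); coerce to the schema class.
coerce_schema <- function(df, schema) {
  for (col in intersect(names(df), names(schema))) {
    df[[col]] <- switch(schema[[col]],
                        numeric = as.numeric(df[[col]]),
                        logical = as.logical(df[[col]]),
                        character = as.character(df[[col]]),
                        df[[col]])
  }
  df
}

row_error <- function(ids, what) {
  abort(paste0(what, " (patient_id: ",
               paste(unique(ids), collapse = ", "), ")"),
        class = "endomol_validation_error")
}

require_columns <- function(df, required) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "endomol_schema_error")
  }
}

check_levels <- function(df, col, levels) {
  bad <- !is.na(df[[col]]) & !(df[[col]] %in% levels)
  if (any(bad)) {
    row_error(df$patient_id[bad],
              paste0("invalid ", col, " value: ",
                     paste(unique(df[[col]][bad]), collapse = ", ")))
  }
}

check_unique_ids <- function(df) {
  dup <- duplicated(df$patient_id)
  if (any(dup)) row_error(df$patient_id[dup], "duplicate patient_id")
}

#' Validate a patient-record table
#'
#' Checks schema and record-level invariants: categorical levels, age within
#' 18-120 years, finite nonnegative follow-up times, and progression-free
#' survival never exceeding overall survival. Adds the derived `early_stage`
#' flag (TRUE for FIGO IA/IB/II).
#'
#' @param df A data frame of patient records.
#' @return The validated tibble with an `early_stage` column.
#' @export
validate_patients <- function(df) {
  df <- as_tibble(df)
  require_columns(df, patient_required())
  df$patient_id <- as.character(df$patient_id)
  check_unique_ids(df)
  if (!"tumor_size" %in% names(df)) df$tumor_size <- NA_real_
  df <- coerce_schema(df, patient_columns())
  df <- remap_binary_lvsi(df)
  check_levels(df, "figo_stage", FIGO_STAGES)
  check_levels(df, "histology", HISTOLOGIES)
  check_levels(df, "invasion", INVASIONS)
  check_levels(df, "lvsi", LVSI_LEVELS)
  check_levels(df, "lymph_nodes", NODE_LEVELS)
  bad_age <- is.na(df$age) | df$age < 18 | df$age > 120
  if (any(bad_age)) row_error(df$patient_id[bad_age], "age outside [18, 120]")
  for (col in c("pfs_months", "os_months")) {
    bad <- !is.finite(df[[col]]) | df[[col]] < 0
    if (any(bad)) row_error(df$patient_id[bad],
                            paste0(col, " must be finite and nonnegative"))
  }
  bad_ord <- df$pfs_months > df$os_months
  if (any(bad_ord)) {
    row_error(df$patient_id[bad_ord], "pfs_months exceeds os_months")
  }
  bad_sz <- !is.na(df$tumor_size) & df$tumor_size < 0
  if (any(bad_sz)) row_error(df$patient_id[bad_sz], "negative tumor_size")
  df$early_stage <- df$figo_stage %in% c("IA", "IB", "II")
  df[c(names(patient_columns()), "early_stage")]
}

# Two-level LVSI input (yes/no) is accepted but widened: "yes" cannot be
# assumed focal, so it maps to substantial; "no" maps to negative.
remap_binary_lvsi <- function(df) {
  if (any(df$lvsi %in% c("yes", "no"))) {
    warn("binary lvsi coding detected: mapping yes -> substantial, no -> negative")
    df$lvsi <- dplyr::recode(df$lvsi, yes = "substantial", no = "negative")
  }
  df
}

#' Validate a marker-profile table
#'
#' Checks marker categorical levels, POLE variant exons (9-14), p53 fields
#' (either a pattern override or the raw quantitative fields), and spectral
#' DNA-purity ratios. `pole_variants` may arrive as a `change:exon;...` string
#' column (the CSV encoding) or as a list-column of tibbles.
#'
#' @param df A data frame of marker profiles.
#' @return The validated tibble with `pole_variants` as a list-column.
#' @export
validate_markers <- function(df) {
  df <- as_tibble(df)
  if ("pole_variants" %in% names(df) && !is.list(df$pole_variants)) {
    df$pole_variants <- lapply(as.character(df$pole_variants), parse_variants)
  }
  require_columns(df, marker_required())
  df$patient_id <- as.character(df$patient_id)
  check_unique_ids(df)
  for (col in setdiff(names(marker_columns()), names(df))) {
    proto <- switch(marker_columns()[[col]],
                    numeric = NA_real_, logical = NA, character = NA_character_)
    df[[col]] <- proto
  }
  df <- coerce_schema(df, marker_columns()[names(marker_columns()) != "pole_variants"])
  check_levels(df, "pms2_status", c("intact", "lost", "not_evaluable"))
  check_levels(df, "msh6_status", c("intact", "lost", "not_evaluable"))
  check_levels(df, "p53_pattern_override",
               c("wildtype", "diffuse", "null", "cytoplasmic"))
  bad_pct <- !is.na(df$p53_pct_strong_nuclear) &
    (df$p53_pct_strong_nuclear < 0 | df$p53_pct_strong_nuclear > 1)
  if (any(bad_pct)) {
    row_error(df$patient_id[bad_pct], "p53_pct_strong_nuclear outside [0, 1]")
  }
  bad_exon <- vapply(df$pole_variants, function(v) {
    nrow(v) > 0 && any(v$exon < 9 | v$exon > 14)
  }, logical(1))
  if (any(bad_exon)) {
    row_error(df$patient_id[bad_exon], "POLE variant exon outside 9-14")
  }
  df[names(marker_columns())]
}

# "P286R:9;V411L:13" -> tibble(protein_change, exon); "" or NA -> empty.
parse_variants <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(tibble(protein_change = character(), exon = integer()))
  }
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  pieces <- strsplit(parts, ":", fixed = TRUE)
  tibble(
    protein_change = vapply(pieces, `[`, character(1), 1),
    exon = as.integer(vapply(pieces, function(p) p[2] %||% NA_character_,
                             character(1)))
  )
}

format_variants <- function(v) {
  if (is.null(v) || nrow(v) == 0) return("")
  paste(paste0(v$protein_change, ":", v$exon), collapse = ";")
}

#' Cost configuration for the strategy comparison
#'
#' Bundles per-test unit costs, per-risk-group adjuvant therapy costs, and the
#' p53-escalation pricing mode. Defaults carry the institutional adjuvant
#' costs (vaginal brachytherapy 53,400 Baht; external beam radiotherapy plus
#' brachytherapy 127,000 Baht; chemoradiation 151,722 Baht; no adjuvant
#' therapy for low risk) and unit test costs consistent with the published
#' strategy totals (POLE hotspot Sanger sequencing 4,500; two-marker MMR
#' immunohistochemistry 1,420; p53 immunohistochemistry 570 Baht).
#'
#' `p53_upgrade_mode` controls how adding chemoradiation for early-stage
#' p53-abnormal patients is priced: `"move_to_high"` charges the difference
#' between the high-risk and the conventional adjuvant cost per escalated
#' patient; `"explicit_override"` replaces the net therapy-change amount for
#' strategies that escalate anyone with `therapy_change_override` (the
#' published net, +12,288 Baht, is not decomposable into per-patient moves).
#'
#' @param test_unit_costs Named integer vector over `MMR`, `POLE`, `p53` (Baht).
#' @param treatment_costs Named integer vector over the four risk groups (Baht).
#' @param p53_upgrade_mode `"move_to_high"` or `"explicit_override"`.
#' @param therapy_change_override Signed integer Baht; required in
#'   `"explicit_override"` mode.
#' @return A `cost_config` list.
#' @export
cost_config <- function(test_unit_costs = c(POLE = 4500L, MMR = 1420L, p53 = 570L),
                        treatment_costs = c(low = 0L, intermediate = 53400L,
                                            high_intermediate = 127000L,
                                            high = 151722L),
                        p53_upgrade_mode = c("move_to_high", "explicit_override"),
                        therapy_change_override = NULL) {
  p53_upgrade_mode <- match.arg(p53_upgrade_mode)
  missing_t <- setdiff(TESTS, names(test_unit_costs))
  if (length(missing_t)) {
    abort(paste0("test_unit_costs missing: ", paste(missing_t, collapse = ", ")),
          class = "endomol_config_error")
  }
  missing_r <- setdiff(RISK_LEVELS, names(treatment_costs))
  if (length(missing_r)) {
    abort(paste0("treatment_costs missing: ", paste(missing_r, collapse = ", ")),
          class = "endomol_config_error")
  }
  if (any(test_unit_costs < 0) || any(treatment_costs < 0)) {
    abort("costs must be nonnegative", class = "endomol_config_error")
  }
  if (p53_upgrade_mode == "explicit_override" &&
      is.null(therapy_change_override)) {
    abort("explicit_override mode requires therapy_change_override",
          class = "endomol_config_error")
  }
  structure(
    list(test_unit_costs = as.integer(round(test_unit_costs[TESTS])) |>
           setNames(TESTS),
         treatment_costs = as.integer(round(treatment_costs[RISK_LEVELS])) |>
           setNames(RISK_LEVELS),
         p53_upgrade_mode = p53_upgrade_mode,
         therapy_change_override =
           if (is.null(therapy_change_override)) NULL
           else as.integer(therapy_change_override)),
    class = "cost_config")
}

#' Read a cost configuration from YAML
#'
#' @param path YAML file with keys `test_unit_costs`, `treatment_costs`, and
#'   optionally `p53_upgrade_mode` and `therapy_change_override`.
#' @return A [cost_config()] object.
#' @export
read_cost_config <- function(path) {
  y <- yaml::read_yaml(path)
  cost_config(
    test_unit_costs = unlist(y$test_unit_costs %||%
                               formals(cost_config)$test_unit_costs |> eval()),
    treatment_costs = unlist(y$treatment_costs %||%
                               formals(cost_config)$treatment_costs |> eval()),
    p53_upgrade_mode = y$p53_upgrade_mode %||% "move_to_high",
    therapy_change_override = y$therapy_change_override
  )
}

#' Read a pathogenic-variant list file
#'
#' One protein change per line; `#` starts a comment; blank lines ignored.
#'
#' @param path Text file of protein changes.
#' @param source_label Label recorded on the list.
#' @return A [pathogenic_variants()] object.
#' @export
read_variant_list <- function(path, source_label = basename(path)) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- stringr::str_trim(stringr::str_remove(lines, "#.*$"))
  pathogenic_variants(entries = lines[nzchar(lines)],
                      source_label = source_label)
}

#' Serialize strategy cost reports
#'
#' Writes a collection of strategy cost reports (the tibble returned by
#' [strategy_comparison()]) either as loss-free JSON or as an aligned text
#' table with one column per strategy: risk-group patient counts, tests
#' performed, testing costs, therapy-change costs, totals, and percent change
#' versus the reference. Currency prints with thousands separators and
#' percentages at one decimal.
#'
#' @param reports A `strategy_comparison` tibble (must include the reference
#'   strategy).
#' @param path Output file path.
#' @param format `"json"` or `"text-table"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path, format = c("json", "text-table")) {
  format <- match.arg(format)
  if (is.null(reports) || nrow(reports) == 0) {
    abort("empty report collection: no reference strategy",
          class = "endomol_report_error")
  }
  if (format == "json") {
    payload <- list(
      reference_total = attr(reports, "reference_total"),
      annotations = attr(reports, "annotations") %||% character(),
      strategies = purrr::pmap(reports, function(...) {
        row <- list(...)
        row$risk_group_counts <- as.list(row$risk_group_counts)
        row$test_tallies <- as.list(row$test_tallies)
        row
      })
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    writeLines(format_cost_table(reports), path)
  }
  invisible(path)
}

#' Read back a JSON strategy report
#'
#' @param path JSON file written by [write_report()].
#' @return A `strategy_comparison` tibble equal to the one serialized.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path)
  rows <- purrr::map_dfr(payload$strategies, function(s) {
    tibble(
      strategy_id = s$strategy_id,
      algorithm = s$algorithm,
      selection = s$selection %||% NA_character_,
      risk_group_counts = list(unlist(s$risk_group_counts)[RISK_LEVELS]),
      test_tallies = list(unlist(s$test_tallies)[TESTS]),
      testing_cost = as.integer(s$testing_cost),
      therapy_change_cost = as.integer(s$therapy_change_cost),
      adjuvant_cost_total = as.integer(s$adjuvant_cost_total),
      total_cost = as.integer(s$total_cost),
      pct_change_vs_reference = as.numeric(s$pct_change_vs_reference)
    )
  })
  new_strategy_comparison(rows,
                          reference_total = as.integer(payload$reference_total),
                          annotations = unlist(payload$annotations) %||%
                            character())
}

# Aligned text layout mirroring the published cost-comparison table.
format_cost_table <- function(reports) {
  cols <- purrr::pmap(reports, function(...) {
    row <- list(...)
    c(row$strategy_id,
      vapply(RISK_LEVELS,
             function(l) fmt_baht(row$risk_group_counts[[l]]), character(1)),
      {
        sel <- which(row$test_tallies > 0)
        if (length(sel)) {
          paste(names(row$test_tallies)[sel],
                paste0("(", row$test_tallies[sel], ")"), collapse = " ")
        } else "none"
      },
      fmt_baht(row$testing_cost),
      fmt_baht_signed(row$therapy_change_cost),
      fmt_baht(row$total_cost),
      paste0(ifelse(row$pct_change_vs_reference > 0, "+", ""),
             formatC(row$pct_change_vs_reference, format = "f", digits = 1),
             "%"))
  })
  labels <- c("Strategy", paste0("  ", RISK_LEVELS, " (n)"),
              "Tests performed", "Testing cost (Baht)",
              "Therapy change (Baht)", "Total cost (Baht)", "Change vs ref")
  widths <- vapply(cols, function(x) max(nchar(x)), integer(1))
  lines <- vapply(seq_along(labels), function(i) {
    paste0(formatC(labels[i], width = -24),
           paste(mapply(function(col, w) formatC(col[i], width = w),
                        cols, widths),
                 collapse = "  "))
  }, character(1))
  ann <- attr(reports, "annotations") %||% character()
  c(lines, if (length(ann)) c("", paste0("note: ", ann)))
}
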
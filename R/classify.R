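#' Pathogenic POLE variant list
#'
#' The default list carries the five exonuclease-domain hotspots assayed by
#' targeted Sanger sequencing (P286R, S297F, V411L, A456P, S459F); it can be
#' extended with additional recognized pathogenic changes via `entries` or a
#' variant file ([read_variant_list()]).
#'
#' @param entries Character vector of protein changes.
#' @param source_label Provenance label carried on reports.
#' @return A `pathogenic_variants` object.
#' @export
pathogenic_variants <- function(entries = c("P286R", "S297F", "V411L",
                                            "A456P", "S459F"),
                                source_label = "hotspot-5") {
  structure(list(entries = unique(as.character(entries)),
                 source_label = source_label),
            class = "pathogenic_variants")
}

#' Interpret two-marker MMR immunohistochemistry
#'
#' Mismatch-repair status from the PMS2/MSH6 panel. A tumor is deficient when
#' at least one marker shows complete loss of nuclear staining with an intact
#' internal (non-neoplastic) positive control. If the internal control fails,
#' or a marker is not evaluable while none is validly lost, the call is
#' indeterminate rather than an error.
#'
#' @param pms2_status,msh6_status `"intact"`, `"lost"` or `"not_evaluable"`
#'   (vectorized).
#' @param internal_control_intact Logical; nuclear positivity in internal
#'   non-neoplastic tissue.
#' @return Character vector: `"deficient"`, `"proficient"` or
#'   `"indeterminate"`.
#' @export
interpret_mmr <- function(pms2_status, msh6_status, internal_control_intact) {
  stopifnot(all(pms2_status %in% c("intact", "lost", "not_evaluable")),
            all(msh6_status %in% c("intact", "lost", "not_evaluable")))
  any_lost <- pms2_status == "lost" | msh6_status == "lost"
  any_ne <- pms2_status == "not_evaluable" | msh6_status == "not_evaluable"
  dplyr::case_when(
    !internal_control_intact ~ "indeterminate",
    any_lost ~ "deficient",
    any_ne ~ "indeterminate",
    TRUE ~ "proficient"
  )
}

#' Interpret p53 immunohistochemistry
#'
#' Assigns one of the wild-type or three abnormal staining patterns. A
#' `p53_pattern_override` column takes precedence; otherwise the raw fields
#' are evaluated in the order diffuse (strong nuclear positivity in at least
#' 80% of tumor nuclei, boundary inclusive), null (complete absence of tumor
#' nuclear staining), then unequivocal cytoplasmic staining; anything else is
#' wild-type.
#'
#' @param profile A marker-profile tibble ([validate_markers()]).
#' @return Character vector over rows of `profile`: `"wildtype"`,
#'   `"abnormal_diffuse"`, `"abnormal_null"` or `"abnormal_cytoplasmic"`.
#' @export
interpret_p53 <- function(profile) {
  ov <- profile$p53_pattern_override
  pct <- profile$p53_pct_strong_nuclear
  nuc <- profile$p53_any_nuclear_staining
  cyt <- profile$p53_unequivocal_cytoplasmic
  need_raw <- is.na(ov)
  # Raw interpretation needs quantitation plus the nuclear-staining flag.
  insufficient <- need_raw & (is.na(pct) | is.na(nuc))
  if (any(insufficient)) {
    missing_fields <- unique(unlist(lapply(which(insufficient), function(i) {
      c(if (is.na(pct[i])) "p53_pct_strong_nuclear",
        if (is.na(nuc[i])) "p53_any_nuclear_staining")
    })))
    abort(paste0("insufficient p53 fields and no override; missing: ",
                 paste(missing_fields, collapse = ", "),
                 " (patient_id: ",
                 paste(profile$patient_id[insufficient], collapse = ", "), ")"),
          class = "endomol_interpretation_error")
  }
  cyt <- ifelse(is.na(cyt), FALSE, cyt)
  dplyr::case_when(
    ov == "diffuse" ~ "abnormal_diffuse",
    ov == "null" ~ "abnormal_null",
    ov == "cytoplasmic" ~ "abnormal_cytoplasmic",
    ov == "wildtype" ~ "wildtype",
    pct >= 0.80 ~ "abnormal_diffuse",
    !nuc & !cyt ~ "abnormal_null",
    cyt ~ "abnormal_cytoplasmic",
    TRUE ~ "wildtype"
  )
}

#' DNA quality-control assessment
#'
#' The reference-gene (GAPDH) amplification is the only hard gate: samples
#' without amplification fail and are not sequenced. Spectrophotometric purity
#' ratios outside the expected 1.80-2.30 window downgrade a pass to
#' `pass_with_warning` but do not exclude.
#'
#' @param gapdh_amplified Logical.
#' @param a260_280,a260_230 Optional absorbance ratios.
#' @return `"pass"`, `"pass_with_warning"` or `"fail"` (vectorized).
#' @export
assess_dna_qc <- function(gapdh_amplified, a260_280 = NA_real_,
                          a260_230 = NA_real_) {
  out_of_range <- function(r) !is.na(r) & (r < 1.80 | r > 2.30)
  dplyr::case_when(
    !gapdh_amplified ~ "fail",
    out_of_range(a260_280) | out_of_range(a260_230) ~ "pass_with_warning",
    TRUE ~ "pass"
  )
}

#' Classify POLE mutation status
#'
#' Mutant if and only if at least one variant's protein change is on the
#' configured pathogenic list; co-occurring unlisted variants are ignored.
#'
#' @param variants A tibble with a `protein_change` column (one patient), or a
#'   list of such tibbles.
#' @param pathogenic_list A [pathogenic_variants()] object.
#' @return `"mutant"` or `"wildtype"` (vectorized over a list input).
#' @export
classify_pole <- function(variants, pathogenic_list = pathogenic_variants()) {
  one <- function(v) {
    if (!is.null(v) && nrow(v) > 0 &&
        any(v$protein_change %in% pathogenic_list$entries)) "mutant"
    else "wildtype"
  }
  if (is.data.frame(variants)) one(variants)
  else vapply(variants, one, character(1))
}

# Fixed test orders per cascade.
cascade_order <- function(algorithm) {
  switch(algorithm,
         promise = c("MMR", "POLE", "p53"),
         who = c("POLE", "MMR", "p53"),
         pole_only = "POLE")
}

#' Assign molecular subgroups by a classification cascade
#'
#' Runs the stepwise molecular classification over a marker-profile table and
#' returns one call per patient, recording which tests the cascade consumed.
#'
#' Orders: `promise` tests MMR immunohistochemistry first (deficient stops as
#' `MMR_d`), then POLE sequencing (`POLE_mut`), then p53 (`p53_abn` on any
#' abnormal pattern, otherwise `NSMP`). `who` runs POLE first, then MMR, then
#' p53, so tumors with both MMR loss and a pathogenic POLE variant resolve to
#' `POLE_mut` instead of `MMR_d`. `pole_only` performs only the POLE test;
#' non-mutant patients pass through labelled `NSMP` (reported as not tested
#' further) and keep their conventional management.
#'
#' Patients failing the GAPDH quality gate are excluded (`excluded_qc`) from
#' every POLE-requiring algorithm, mirroring the study's exclusion of
#' suboptimal-DNA cases; an indeterminate MMR call under an MMR-requiring
#' cascade is a hard error, since silently misrouting a patient would corrupt
#' downstream test tallies and costs.
#'
#' @param profiles A validated marker-profile tibble.
#' @param algorithm `"promise"`, `"who"` or `"pole_only"`.
#' @param pathogenic_list A [pathogenic_variants()] object.
#' @return A tibble with columns `patient_id`, `algorithm`, `subgroup`
#'   (`MMR_d`/`POLE_mut`/`p53_abn`/`NSMP`/`excluded_qc`), `tests_used`
#'   (list-column in cascade order), and the interpreted component calls
#'   `mmr_call`, `pole_call`, `p53_call`, `qc_result`.
#' @export
classify_cascade <- function(profiles, algorithm = c("promise", "who",
                                                     "pole_only"),
                             pathogenic_list = pathogenic_variants()) {
  algorithm <- match.arg(algorithm)
  profiles <- validate_markers(profiles)
  qc <- assess_dna_qc(profiles$gapdh_amplified, profiles$a260_280,
                      profiles$a260_230)
  n <- nrow(profiles)
  subgroup <- character(n)
  tests_used <- vector("list", n)
  mmr_call <- rep(NA_character_, n)
  pole_call <- rep(NA_character_, n)
  p53_call <- rep(NA_character_, n)

  excluded <- qc == "fail"
  subgroup[excluded] <- "excluded_qc"
  tests_used[excluded] <- list(character())

  idx <- which(!excluded)
  if (length(idx)) {
    prof <- profiles[idx, ]
    mmr <- interpret_mmr(prof$pms2_status, prof$msh6_status,
                         prof$ihc_internal_control_intact)
    pole <- classify_pole(prof$pole_variants, pathogenic_list)
    if (algorithm != "pole_only" && any(mmr == "indeterminate")) {
      row_error(prof$patient_id[mmr == "indeterminate"],
                "indeterminate MMR status: cannot classify under an MMR-requiring cascade")
    }
    for (k in seq_along(idx)) {
      i <- idx[k]
      used <- character()
      sg <- NA_character_
      for (test in cascade_order(algorithm)) {
        used <- c(used, test)
        if (test == "MMR") {
          mmr_call[i] <- mmr[k]
          if (mmr[k] == "deficient") { sg <- "MMR_d"; break }
        } else if (test == "POLE") {
          pole_call[i] <- pole[k]
          if (pole[k] == "mutant") { sg <- "POLE_mut"; break }
        } else {
          p53_call[i] <- interpret_p53(prof[k, ])
          sg <- if (p53_call[i] == "wildtype") "NSMP" else "p53_abn"
          break
        }
      }
      if (is.na(sg)) sg <- "NSMP"  # pole_only pass-through
      subgroup[i] <- sg
      tests_used[[i]] <- used
    }
  }
  tibble(patient_id = profiles$patient_id, algorithm = algorithm,
         subgroup = subgroup, tests_used = tests_used,
         mmr_call = mmr_call, pole_call = pole_call, p53_call = p53_call,
         qc_result = qc)
}

#' Tally test usage across a set of molecular calls
#'
#' Counts, for each test, how many patients' cascades consumed it. All calls
#' must come from one algorithm (mixing cascades would make the tally
#' meaningless for costing).
#'
#' @param calls A tibble from [classify_cascade()].
#' @return Named integer vector over `MMR`, `POLE`, `p53`.
#' @export
tally_test_usage <- function(calls) {
  if (nrow(calls) > 0 && dplyr::n_distinct(calls$algorithm) > 1) {
    abort("calls mix multiple algorithms", class = "endomol_tally_error")
  }
  used <- unlist(calls$tests_used)
  counts <- table(factor(used, levels = TESTS))
  setNames(as.integer(counts), TESTS)
}
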
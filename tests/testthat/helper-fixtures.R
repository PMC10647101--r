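# Tiny in-code fixtures shared across test files.

toy_patients <- function() {
  tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    age = c(55, 63, 48),
    figo_stage = c("IA", "IB", "III"),
    histology = c("endometrioid_low_grade", "endometrioid_high_grade",
                  "non_endometrioid"),
    tumor_size = c(3.2, NA, 6.1),
    invasion = c("lt_50", "ge_50", "serosa"),
    lvsi = c("negative", "focal", "substantial"),
    cervical_stromal_invasion = c(FALSE, FALSE, TRUE),
    lymph_nodes = c("negative", "not_removed", "positive"),
    pfs_months = c(60, 48.5, 12),
    pfs_event = c(FALSE, FALSE, TRUE),
    os_months = c(60, 48.5, 20),
    os_event = c(FALSE, FALSE, TRUE)
  )
}

toy_markers <- function() {
  tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    pms2_status = c("intact", "lost", "intact"),
    msh6_status = c("intact", "intact", "intact"),
    ihc_internal_control_intact = TRUE,
    p53_pct_strong_nuclear = c(0.10, 0.05, 0.95),
    p53_any_nuclear_staining = c(TRUE, TRUE, TRUE),
    p53_unequivocal_cytoplasmic = FALSE,
    p53_pattern_override = NA_character_,
    pole_variants = list(
      tibble::tibble(protein_change = character(), exon = integer()),
      tibble::tibble(protein_change = character(), exon = integer()),
      tibble::tibble(protein_change = "P286R", exon = 9L)
    ),
    gapdh_amplified = TRUE,
    a260_280 = 1.9,
    a260_230 = 2.0
  )
}

# One-row marker profile built from interpreted statuses, for enumeration
# tests: mmr in {intact, lost}x{intact, lost}, pole in {none, hotspot,
# benign}, p53 in {wildtype, diffuse, null, cytoplasmic}.
profile_row <- function(id, pms2, msh6, pole, p53) {
  variants <- switch(pole,
    none = tibble::tibble(protein_change = character(), exon = integer()),
    hotspot = tibble::tibble(protein_change = "V411L", exon = 13L),
    benign = tibble::tibble(protein_change = "E396G", exon = 11L))
  pct <- switch(p53, wildtype = 0.3, diffuse = 0.9, null = 0, cytoplasmic = 0.2)
  nuc <- p53 != "null"
  cyt <- p53 == "cytoplasmic"
  tibble::tibble(
    patient_id = id, pms2_status = pms2, msh6_status = msh6,
    ihc_internal_control_intact = TRUE,
    p53_pct_strong_nuclear = pct, p53_any_nuclear_staining = nuc,
    p53_unequivocal_cytoplasmic = cyt,
    p53_pattern_override = NA_character_,
    pole_variants = list(variants), gapdh_amplified = TRUE,
    a260_280 = 2.0, a260_230 = 2.0
  )
}
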
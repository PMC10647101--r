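# Deterministic reference fixtures: a 138-patient cohort reproducing the
# published subgroup/stage/histology/invasion/LVSI cross-tabulations, and its
# 80-patient early-stage subset carrying conventional risk labels consistent
# with the published risk-group counts. These are synthetic reconstructions:
# only the printed margins are fixed; joints beyond them are the package's
# own convention.

# One block of patients sharing a subgroup; attribute vectors are recycled
# elementwise by position (each must have length n or 1).
fixture_block <- function(subgroup, n, stage, histology, invasion, lvsi,
                          nodes, cervical, age) {
  tibble(subgroup = subgroup, figo_stage = rep_len(stage, n),
         histology = rep_len(histology, n), invasion = rep_len(invasion, n),
         lvsi = rep_len(lvsi, n), lymph_nodes = rep_len(nodes, n),
         cervical_stromal_invasion = rep_len(cervical, n),
         age = rep_len(age, n))
}

# Integer ages spread over the printed range, adjusted to the printed mean.
fixture_ages <- function(n, lo, hi, mean_target) {
  a <- round(seq(lo, hi, length.out = n))
  shift <- round(mean_target * n) - sum(a)
  # distribute the correction one year at a time without leaving the range
  k <- 1
  while (shift != 0 && k <= 10 * n) {
    j <- (k - 1) %% n + 1
    step <- sign(shift)
    if (a[j] + step >= lo && a[j] + step <= hi) {
      a[j] <- a[j] + step
      shift <- shift - step
    }
    k <- k + 1
  }
  a
}

#' The 138-patient reference cohort
#'
#' A deterministic synthetic cohort whose per-subgroup margins reproduce the
#' published cross-tabulations: 39 MMR-d, 7 POLE-mut, 19 p53-abn and 73 NSMP
#' patients; 80 early-stage (25/5/5/45 by subgroup); histology, depth of
#' invasion, LVSI, cervical stromal invasion and nodal margins per subgroup.
#' Marker profiles are the classifier's inverse image, so the ProMisE cascade
#' reproduces the subgroup labels exactly. Survival outcomes are drawn once
#' from the calibrated piecewise-exponential generator under a fixed internal
#' seed (POLE-mut patients are event-free with at least 60 months follow-up).
#'
#' @return A list of tibbles: `patients` (with `true_subgroup` column
#'   dropped into `true_labels`), `markers`, `true_labels`.
#' @export
table1_cohort <- function() {
  LG <- "endometrioid_low_grade"; HG <- "endometrioid_high_grade"
  NE <- "non_endometrioid"
  blocks <- dplyr::bind_rows(
    # --- MMR-d (39): early 25 = 8 low + 7 intermediate + 10 high-int
    fixture_block("MMR_d", 8, "IA", LG, "lt_50", "negative", "negative",
                  FALSE, 0),
    fixture_block("MMR_d", 7, "IB", LG, "ge_50", "negative", "negative",
                  FALSE, 0),
    fixture_block("MMR_d", 10, "IA", LG, "lt_50", "substantial",
                  c(rep("negative", 2), rep("not_removed", 8)), FALSE, 0),
    fixture_block("MMR_d", 14, c(rep("III", 10), rep("IV", 4)),
                  c(rep(HG, 12), rep(NE, 2)),
                  c(rep("lt_50", 2), rep("ge_50", 6), rep("serosa", 6)),
                  "substantial", c(rep("positive", 7), rep("negative", 7)),
                  c(rep(TRUE, 6), rep(FALSE, 8)), 0),
    # --- POLE-mut (7): early 5 = 2 low + 1 intermediate + 2 high-int
    fixture_block("POLE_mut", 2, "IA", LG, "lt_50", "negative", "negative",
                  FALSE, 0),
    fixture_block("POLE_mut", 1, "IB", LG, "ge_50", "negative", "negative",
                  FALSE, 0),
    fixture_block("POLE_mut", 2, "IB", HG, "ge_50", "substantial",
                  c("negative", "not_removed"), FALSE, 0),
    fixture_block("POLE_mut", 2, "III", c(LG, HG), c("lt_50", "ge_50"),
                  c("substantial", "negative"), c("positive", "negative"),
                  c(TRUE, FALSE), 0),
    # --- p53-abn (19): early 5 = 3 intermediate + 2 high
    fixture_block("p53_abn", 3, "IA", HG, "lt_50", "negative", "not_removed",
                  FALSE, 0),
    fixture_block("p53_abn", 2, "IA", NE, "lt_50", "negative", "negative",
                  FALSE, 0),
    fixture_block("p53_abn", 14, c(rep("III", 8), rep("IV", 6)),
                  c(rep(HG, 4), rep(NE, 10)),
                  c(rep("lt_50", 4), rep("ge_50", 2), rep("serosa", 8)),
                  c(rep("substantial", 12), rep("negative", 2)),
                  c(rep("positive", 6), rep("not_removed", 5),
                    rep("negative", 3)),
                  c(rep(TRUE, 2), rep(FALSE, 12)), 0),
    # --- NSMP (73): early 45 = 20 low + 7 intermediate + 17 high-int + 1 high
    fixture_block("NSMP", 20, "IA", LG, "lt_50", "negative", "negative",
                  FALSE, 0),
    fixture_block("NSMP", 7, "IB", LG, "ge_50", "negative", "negative",
                  FALSE, 0),
    fixture_block("NSMP", 13, "IA", LG, "lt_50", "substantial",
                  c(rep("negative", 4), rep("not_removed", 9)), FALSE, 0),
    fixture_block("NSMP", 4, "IB", HG, "ge_50", "substantial",
                  "not_removed", FALSE, 0),
    fixture_block("NSMP", 1, "IA", NE, "lt_50", "substantial", "not_removed",
                  FALSE, 0),
    fixture_block("NSMP", 28, c(rep("III", 20), rep("IV", 8)),
                  c(rep(LG, 12), rep(HG, 13), rep(NE, 3)),
                  c(rep("lt_50", 6), rep("ge_50", 16), rep("serosa", 6)),
                  c(rep("substantial", 21), rep("negative", 7)),
                  c(rep("positive", 16), rep("negative", 12)),
                  c(rep(TRUE, 10), rep(FALSE, 18)), 0)
  )
  ages <- c(fixture_ages(39, 37, 78, 58.46), fixture_ages(7, 42, 66, 57.29),
            fixture_ages(19, 29, 81, 60.79), fixture_ages(73, 25, 75, 55.49))
  blocks$age <- ages
  blocks$patient_id <- sprintf("EC%03d", seq_len(nrow(blocks)))

  surv <- generate_survival(blocks$subgroup, seed = 20151217L)
  patients <- tibble(
    patient_id = blocks$patient_id, age = blocks$age,
    figo_stage = blocks$figo_stage, histology = blocks$histology,
    tumor_size = rep_len(c(4.2, 5.6, 3.1, 6.4, 4.9), nrow(blocks)),
    invasion = blocks$invasion, lvsi = blocks$lvsi,
    cervical_stromal_invasion = blocks$cervical_stromal_invasion,
    lymph_nodes = blocks$lymph_nodes,
    pfs_months = surv$pfs_months, pfs_event = surv$pfs_event,
    os_months = surv$os_months, os_event = surv$os_event
  )
  markers <- fixture_markers(blocks$patient_id, blocks$subgroup)
  list(patients = validate_patients(patients),
       markers = validate_markers(markers),
       true_labels = tibble(patient_id = blocks$patient_id,
                            true_subgroup = blocks$subgroup,
                            qc_pass = TRUE))
}

# Deterministic inverse-image marker profiles for the fixtures.
fixture_markers <- function(id, sg) {
  n <- length(id)
  pms2 <- ifelse(sg == "MMR_d", "lost", "intact")
  msh6 <- rep("intact", n)
  msh6[sg == "MMR_d"][seq_len(sum(sg == "MMR_d")) %% 3 == 0] <- "lost"
  pct <- rep(0.10, n)
  nuc <- rep(TRUE, n)
  cyt <- rep(FALSE, n)
  variants <- vector("list", n)
  variants[] <- list(tibble(protein_change = character(), exon = integer()))
  i <- which(sg == "POLE_mut")
  hot <- rep_len(names(HOTSPOT_EXONS), length(i))
  variants[i] <- lapply(hot, function(h) {
    tibble(protein_change = h, exon = HOTSPOT_EXONS[[h]])
  })
  i <- which(sg == "p53_abn")
  pattern <- rep_len(c("diffuse", "null", "cytoplasmic"), length(i))
  pct[i] <- ifelse(pattern == "diffuse", 0.90, ifelse(pattern == "null", 0, 0.2))
  nuc[i] <- pattern != "null"
  cyt[i] <- pattern == "cytoplasmic"
  tibble(
    patient_id = id, pms2_status = pms2, msh6_status = msh6,
    ihc_internal_control_intact = TRUE,
    p53_pct_strong_nuclear = pct, p53_any_nuclear_staining = nuc,
    p53_unequivocal_cytoplasmic = cyt,
    p53_pattern_override = NA_character_, pole_variants = variants,
    gapdh_amplified = TRUE, a260_280 = 1.95, a260_230 = 2.05
  )
}

#' The 80-patient early-stage costing cohort
#'
#' The early-stage (FIGO I-II) subset of [table1_cohort()], carrying explicit
#' conventional risk labels as data (30 low, 18 intermediate, 29
#' high-intermediate, 3 high) consistent with the published cost table,
#' including the mover structure: of 5 early POLE-mut patients, 1
#' intermediate and 2 high-intermediate are de-escalated; of 5 early p53-abn
#' patients, 3 intermediate are escalated and 2 are already high. The shipped
#' default rule table reproduces these labels, but the labels travel with the
#' fixture so cost reproduction never depends on a rule table.
#'
#' @return A list of tibbles: `patients` (with `conventional_risk`),
#'   `markers`, `true_labels`.
#' @export
table3_cohort <- function() {
  full <- table1_cohort()
  patients <- dplyr::filter(full$patients, .data$early_stage)
  patients$conventional_risk <- conventional_risk(patients)
  markers <- dplyr::semi_join(full$markers, patients, by = "patient_id")
  labels <- dplyr::semi_join(full$true_labels, patients, by = "patient_id")
  list(patients = patients, markers = markers, true_labels = labels)
}
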
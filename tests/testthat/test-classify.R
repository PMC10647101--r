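test_that("MMR interpretation requires loss with an intact internal control", {
  expect_equal(interpret_mmr("intact", "intact", TRUE), "proficient")
  expect_equal(interpret_mmr("lost", "intact", TRUE), "deficient")
  expect_equal(interpret_mmr("intact", "lost", TRUE), "deficient")
  expect_equal(interpret_mmr("lost", "lost", FALSE), "indeterminate")
  expect_equal(interpret_mmr("not_evaluable", "intact", TRUE), "indeterminate")
  expect_equal(interpret_mmr("not_evaluable", "lost", TRUE), "deficient")
})

test_that("p53 patterns follow the diffuse/null/cytoplasmic rules", {
  p <- function(pct, nuc, cyt = FALSE, override = NA_character_) {
    profile_row("X", "intact", "intact", "none", "wildtype") |>
      dplyr::mutate(p53_pct_strong_nuclear = pct,
                    p53_any_nuclear_staining = nuc,
                    p53_unequivocal_cytoplasmic = cyt,
                    p53_pattern_override = override)
  }
  expect_equal(interpret_p53(p(0.85, TRUE)), "abnormal_diffuse")
  # the 80% boundary is inclusive
  expect_equal(interpret_p53(p(0.80, TRUE)), "abnormal_diffuse")
  expect_equal(interpret_p53(p(0, FALSE)), "abnormal_null")
  expect_equal(interpret_p53(p(0.30, TRUE)), "wildtype")
  expect_equal(interpret_p53(p(0.30, TRUE, cyt = TRUE)),
               "abnormal_cytoplasmic")
  # override takes precedence over raw fields
  expect_equal(interpret_p53(p(0.95, TRUE, override = "wildtype")), "wildtype")
  expect_error(interpret_p53(p(NA_real_, NA)),
               "p53_pct_strong_nuclear",
               class = "endomol_interpretation_error")
})

test_that("GAPDH amplification is the only hard DNA-QC gate", {
  expect_equal(assess_dna_qc(FALSE, 1.90, 2.00), "fail")
  expect_equal(assess_dna_qc(TRUE, 1.85, 2.10), "pass")
  expect_equal(assess_dna_qc(TRUE, 1.50, 2.00), "pass_with_warning")
  expect_equal(assess_dna_qc(TRUE, NA, NA), "pass")
  expect_equal(assess_dna_qc(TRUE, 2.0, 2.35), "pass_with_warning")
})

test_that("POLE status is an exact match against the pathogenic list", {
  v <- function(...) tibble::tibble(protein_change = c(...),
                                    exon = rep(9L, length(c(...))))
  expect_equal(classify_pole(v("P286R")), "mutant")
  expect_equal(classify_pole(v("V411L", "E396G")), "mutant")
  expect_equal(classify_pole(v("E396G")), "wildtype")
  expect_equal(classify_pole(v()), "wildtype")
  ext <- pathogenic_variants(c("P286R", "E396G"), "extended")
  expect_equal(classify_pole(v("E396G"), ext), "mutant")
})

test_that("cascades assign subgroups in their fixed test orders", {
  mmr_lost <- profile_row("A", "lost", "intact", "none", "wildtype")
  out <- classify_cascade(mmr_lost, "promise")
  expect_equal(out$subgroup, "MMR_d")
  expect_equal(out$tests_used[[1]], "MMR")

  pole_p53 <- profile_row("B", "intact", "intact", "hotspot", "null")
  out <- classify_cascade(pole_p53, "promise")
  expect_equal(out$subgroup, "POLE_mut")
  expect_equal(out$tests_used[[1]], c("MMR", "POLE"))

  both <- profile_row("C", "lost", "intact", "hotspot", "wildtype")
  expect_equal(classify_cascade(both, "promise")$subgroup, "MMR_d")
  expect_equal(classify_cascade(both, "who")$subgroup, "POLE_mut")

  normal <- profile_row("D", "intact", "intact", "none", "wildtype")
  out <- classify_cascade(normal, "promise")
  expect_equal(out$subgroup, "NSMP")
  expect_equal(out$tests_used[[1]], c("MMR", "POLE", "p53"))

  out <- classify_cascade(normal, "pole_only")
  expect_equal(out$subgroup, "NSMP")
  expect_equal(out$tests_used[[1]], "POLE")
})

test_that("QC failures are excluded; indeterminate MMR is a hard error", {
  failed <- profile_row("F", "lost", "intact", "hotspot", "wildtype") |>
    dplyr::mutate(gapdh_amplified = FALSE)
  out <- classify_cascade(failed, "promise")
  expect_equal(out$subgroup, "excluded_qc")
  expect_equal(out$tests_used[[1]], character())

  indet <- profile_row("G", "intact", "intact", "none", "wildtype") |>
    dplyr::mutate(ihc_internal_control_intact = FALSE)
  expect_error(classify_cascade(indet, "promise"), "indeterminate",
               class = "endomol_validation_error")
  # but an MMR-free cascade proceeds
  expect_equal(classify_cascade(indet, "pole_only")$subgroup, "NSMP")
})

test_that("test tallies count cascade consumption and refuse mixed input", {
  expect_equal(tally_test_usage(classify_cascade(toy_markers()[0, ], "promise")),
               c(MMR = 0L, POLE = 0L, p53 = 0L))
  mixed <- dplyr::bind_rows(
    classify_cascade(toy_markers(), "promise"),
    classify_cascade(toy_markers(), "who"))
  expect_error(tally_test_usage(mixed), "mix", class = "endomol_tally_error")
})

test_that("cascades are exhaustive and exclusive; orders disagree only on joint MMR-loss + pathogenic POLE", {
  combos <- tidyr::expand_grid(
    pms2 = c("intact", "lost"), msh6 = c("intact", "lost"),
    pole = c("none", "hotspot", "benign"),
    p53 = c("wildtype", "diffuse", "null", "cytoplasmic"))
  profiles <- purrr::pmap_dfr(combos, function(pms2, msh6, pole, p53) {
    profile_row(paste(pms2, msh6, pole, p53, sep = "_"), pms2, msh6, pole, p53)
  })
  promise <- classify_cascade(profiles, "promise")
  who <- classify_cascade(profiles, "who")
  expect_true(all(promise$subgroup %in% c("MMR_d", "POLE_mut", "p53_abn",
                                          "NSMP")))
  expect_true(all(who$subgroup %in% c("MMR_d", "POLE_mut", "p53_abn", "NSMP")))
  joint <- (combos$pms2 == "lost" | combos$msh6 == "lost") &
    combos$pole == "hotspot"
  disagree <- promise$subgroup != who$subgroup
  expect_equal(disagree, joint)
  expect_true(all(promise$subgroup[joint] == "MMR_d"))
  expect_true(all(who$subgroup[joint] == "POLE_mut"))
})

test_that("cascade test-count identities hold on the early-stage fixture", {
  t3 <- table3_cohort()
  n <- nrow(t3$patients)
  promise <- classify_cascade(t3$markers, "promise")
  tp <- tally_test_usage(promise)
  n_mmrd <- sum(promise$subgroup == "MMR_d")
  n_pole <- sum(promise$subgroup == "POLE_mut")
  expect_equal(unname(tp["MMR"]), n)
  expect_equal(unname(tp["POLE"]), n - n_mmrd)
  expect_equal(unname(tp["p53"]), n - n_mmrd - n_pole)

  who <- classify_cascade(t3$markers, "who")
  tw <- tally_test_usage(who)
  expect_equal(unname(tw["POLE"]), n)
  expect_equal(unname(tw["MMR"]), n - sum(who$subgroup == "POLE_mut"))
  expect_equal(unname(tw["p53"]),
               n - sum(who$subgroup %in% c("POLE_mut", "MMR_d")))
})
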
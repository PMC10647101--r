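test_that("cohort tables survive a write-read round trip", {
  dir <- withr::local_tempdir()
  pp <- file.path(dir, "patients.csv")
  mp <- file.path(dir, "markers.csv")

  pat <- validate_patients(toy_patients())
  write_cohort(pat, pp)
  expect_equal(read_cohort(pp, "patients"), pat)

  mk <- validate_markers(toy_markers())
  write_cohort(mk, mp)
  expect_equal(read_cohort(mp, "markers"), mk)
})

test_that("validation rejects records violating declared invariants", {
  bad_stage <- toy_patients()
  bad_stage$figo_stage[2] <- "V"
  expect_error(validate_patients(bad_stage), "figo_stage.*P2",
               class = "endomol_validation_error")

  bad_order <- toy_patients()
  bad_order$pfs_months[1] <- 70
  expect_error(validate_patients(bad_order), "pfs_months exceeds os_months",
               class = "endomol_validation_error")

  expect_error(validate_patients(toy_patients()[-2]),
               "missing required column", class = "endomol_schema_error")

  dup <- dplyr::bind_rows(toy_patients(), toy_patients()[1, ])
  expect_error(validate_patients(dup), "duplicate patient_id",
               class = "endomol_validation_error")

  bad_age <- toy_patients()
  bad_age$age[3] <- 130
  expect_error(validate_patients(bad_age), "age outside",
               class = "endomol_validation_error")

  bad_exon <- toy_markers()
  bad_exon$pole_variants[[1]] <- tibble::tibble(protein_change = "X", exon = 8L)
  expect_error(validate_markers(bad_exon), "exon outside 9-14",
               class = "endomol_validation_error")
})

test_that("unknown columns are dropped with a warning, row order preserved", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "p.csv")
  df <- toy_patients()
  df$extraneous <- 1:3
  readr::write_csv(df, path)
  expect_warning(out <- read_cohort(path, "patients"), "extraneous")
  expect_false("extraneous" %in% names(out))
  expect_equal(out$patient_id, df$patient_id)
})

test_that("binary LVSI input is widened with a warning", {
  df <- toy_patients()
  df$lvsi <- c("no", "yes", "no")
  expect_warning(out <- validate_patients(df), "substantial")
  expect_equal(out$lvsi, c("negative", "substantial", "negative"))
})

test_that("derived early-stage flag follows FIGO stage", {
  out <- validate_patients(toy_patients())
  expect_equal(out$early_stage, c(TRUE, TRUE, FALSE))
})

test_that("cost configuration validates and round-trips through YAML", {
  expect_error(cost_config(test_unit_costs = c(MMR = 1, p53 = 1)),
               "POLE", class = "endomol_config_error")
  expect_error(cost_config(treatment_costs = c(low = -1, intermediate = 1,
                                               high_intermediate = 1, high = 1)),
               "nonnegative", class = "endomol_config_error")
  expect_error(cost_config(p53_upgrade_mode = "explicit_override"),
               "override", class = "endomol_config_error")

  dir <- withr::local_tempdir()
  path <- file.path(dir, "costs.yaml")
  yaml::write_yaml(list(
    test_unit_costs = list(POLE = 4500, MMR = 1420, p53 = 570),
    treatment_costs = list(low = 0, intermediate = 53400,
                           high_intermediate = 127000, high = 151722),
    p53_upgrade_mode = "explicit_override",
    therapy_change_override = 12288), path)
  cfg <- read_cost_config(path)
  expect_equal(cfg$test_unit_costs[["POLE"]], 4500L)
  expect_equal(cfg$therapy_change_override, 12288L)
})

test_that("strategy reports serialize losslessly to JSON and format as text", {
  t3 <- table3_cohort()
  rep <- strategy_comparison(
    t3$patients, t3$markers,
    costs = cost_config(p53_upgrade_mode = "explicit_override",
                        therapy_change_override = 12288L))
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "report.json")
  write_report(rep, jp, "json")
  back <- read_report(jp)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(rep))
  expect_equal(attr(back, "reference_total"), attr(rep, "reference_total"))

  tp <- file.path(dir, "report.txt")
  write_report(rep, tp, "text-table")
  text <- paste(readLines(tp), collapse = "\n")
  expect_match(text, "5,099,366", fixed = TRUE)
  expect_match(text, "\\+9\\.9%")

  expect_error(write_report(rep[0, ], file.path(dir, "x.json")),
               "reference", class = "endomol_report_error")
})

test_that("shipped configuration files load into their objects", {
  costs <- read_cost_config(system.file("extdata", "costs.yaml",
                                        package = "endomol"))
  expect_equal(costs$test_unit_costs[c("POLE", "MMR", "p53")],
               c(POLE = 4500L, MMR = 1420L, p53 = 570L))
  expect_equal(costs$therapy_change_override, 12288L)

  vl <- read_variant_list(system.file("extdata",
                                      "pathogenic_pole_variants.txt",
                                      package = "endomol"))
  expect_setequal(vl$entries, pathogenic_variants()$entries)

  rules <- read_risk_rules(system.file("extdata", "risk_rules.csv",
                                       package = "endomol"))
  t3 <- table3_cohort()
  expect_equal(conventional_risk(t3$patients, rules),
               t3$patients$conventional_risk)
})

test_that("variant list files parse with comments and extend the default set", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "variants.txt")
  writeLines(c("# recognized pathogenic changes", "P286R", "V411L",
               "F367S  # rare", ""), path)
  vl <- read_variant_list(path)
  expect_setequal(vl$entries, c("P286R", "V411L", "F367S"))
  expect_equal(classify_pole(tibble::tibble(protein_change = "F367S",
                                            exon = 9L), vl), "mutant")
})
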
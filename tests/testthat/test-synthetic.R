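test_that("piecewise-exponential RMST closed form matches numeric integration", {
  cases <- list(
    list(rates = 0.02, breaks = 0),
    list(rates = c(0.05, 0.01), breaks = c(0, 24)),
    list(rates = c(0, 0.03), breaks = c(0, 60)),
    list(rates = c(0.04, 0, 0.08), breaks = c(0, 12, 48)))
  for (cs in cases) {
    surv <- function(t) {
      vapply(t, function(ti) {
        ends <- c(cs$breaks[-1], Inf)
        exp(-sum(cs$rates * pmax(pmin(ti, ends) - cs$breaks, 0)))
      }, numeric(1))
    }
    expect_equal(piecewise_exp_rmst(cs$rates, cs$breaks, 60),
                 integrate(surv, 0, 60, rel.tol = 1e-10)$value,
                 tolerance = 1e-8)
  }
})

test_that("rate calibration inverts the closed-form RMST", {
  expect_equal(calibrate_rates(60, 60), 0)
  lam <- 0.027
  target <- (1 - exp(-lam * 60)) / lam
  expect_equal(calibrate_rates(target), lam, tolerance = 1e-6)
  for (target in c(10, 29.5, 45, 53.2, 59.5)) {
    r <- calibrate_rates(target, 60, breaks = c(0, 24), weights = c(1, 0.5))
    expect_equal(piecewise_exp_rmst(r, c(0, 24), 60), target,
                 tolerance = 1e-6)
  }
  expect_error(calibrate_rates(61, 60), "exceeds",
               class = "endomol_sim_error")
})

test_that("piecewise-exponential draws reproduce their survival curve", {
  set.seed(500)
  lam <- 0.03
  x <- endomol:::rpiecewise_exp(1e5, lam, 0)
  expect_equal(mean(x), 1 / lam, tolerance = 0.02)
  km <- km_estimate(pmin(x, 120), x <= 120)
  expect_lt(max(abs(km$surv - exp(-lam * km$time))), 0.01)

  # two-segment: empirical RMST matches the closed form
  rates <- c(0.05, 0.01); breaks <- c(0, 20)
  y <- endomol:::rpiecewise_exp(1e5, rates, breaks)
  emp_rmst <- mean(pmin(y, 60))
  expect_equal(emp_rmst, piecewise_exp_rmst(rates, breaks, 60),
               tolerance = 0.2)
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- generate_cohort(cohort_spec(seed = 77))
  b <- generate_cohort(cohort_spec(seed = 77))
  expect_identical(a, b)
  c <- generate_cohort(cohort_spec(seed = 78))
  expect_false(identical(a$patients, c$patients))
})

test_that("marker profiles are the classifier's inverse image", {
  spec <- cohort_spec(seed = 15)
  coh <- generate_cohort(spec)
  calls <- classify_cascade(coh$markers, "promise")
  merged <- dplyr::inner_join(calls, coh$true_labels, by = "patient_id")
  expect_equal(merged$subgroup[!merged$qc_pass],
               rep("excluded_qc", sum(!merged$qc_pass)))
  passes <- merged[merged$qc_pass, ]
  expect_equal(passes$subgroup, passes$true_subgroup)

  # degenerate spec: everyone NSMP
  nsmp <- generate_cohort(cohort_spec(
    subgroup_probs = c(MMR_d = 0, POLE_mut = 0, p53_abn = 0, NSMP = 1),
    seed = 4))
  cc <- classify_cascade(nsmp$markers, "promise")
  expect_true(all(cc$subgroup[cc$subgroup != "excluded_qc"] == "NSMP"))
})

test_that("the default specification emulates the recruitment and QC process", {
  spec <- cohort_spec(seed = 8)
  expect_equal(spec$n_recruited, 186)
  expect_equal(spec$qc_failure_rate, 0.258)
  expect_equal(sum(spec$subgroup_probs), 1)
  coh <- generate_cohort(spec)
  expect_equal(nrow(coh$patients), 186)
  n_fail <- sum(!coh$true_labels$qc_pass)
  # binomial(186, 0.258): mean 48, sd ~6; stay within 3 standard errors
  expect_true(abs(n_fail - 48) < 3 * sqrt(186 * 0.258 * 0.742) + 1)
  # POLE-mut patients are event-free before month 60 by construction
  pole <- coh$true_labels$true_subgroup == "POLE_mut"
  expect_false(any(coh$patients$pfs_event[pole] &
                     coh$patients$pfs_months[pole] < 60))
  expect_true(all(coh$patients$pfs_months <= coh$patients$os_months))
})

test_that("empirical subgroup frequencies converge to the specification", {
  spec <- cohort_spec(n_recruited = 20000, seed = 60)
  coh <- generate_cohort(spec)
  freq <- table(coh$true_labels$true_subgroup) / 20000
  for (g in names(spec$subgroup_probs)) {
    p <- spec$subgroup_probs[[g]]
    se <- sqrt(p * (1 - p) / 20000)
    expect_lt(abs(freq[[g]] - p), 3 * se + 1e-9)
  }
})

test_that("invalid specifications are rejected", {
  expect_error(cohort_spec(subgroup_probs = c(MMR_d = 0.5, POLE_mut = 0.5,
                                              p53_abn = 0.5, NSMP = 0.5)),
               "sum to 1", class = "endomol_sim_error")
  expect_error(generate_survival("NSMP", list(NSMP = list(breaks = 0,
                                                          rates = -1))),
               "negative", class = "endomol_sim_error")
})

test_that("the reference fixtures reproduce the published margins", {
  t1 <- table1_cohort()
  expect_equal(nrow(t1$patients), 138)
  counts <- table(t1$true_labels$true_subgroup)
  expect_equal(unname(counts[c("MMR_d", "POLE_mut", "p53_abn", "NSMP")]),
               array(c(39L, 7L, 19L, 73L)))
  expect_equal(sum(t1$patients$early_stage), 80)
  early_sub <- table(t1$true_labels$true_subgroup[t1$patients$early_stage])
  expect_equal(unname(early_sub[c("MMR_d", "POLE_mut", "p53_abn", "NSMP")]),
               array(c(25L, 5L, 5L, 45L)))
  expect_equal(unname(table(t1$patients$histology)[
    c("endometrioid_low_grade", "endometrioid_high_grade",
      "non_endometrioid")]), array(c(81L, 39L, 18L)))
  expect_equal(unname(table(t1$patients$invasion)[
    c("lt_50", "ge_50", "serosa")]), array(c(72L, 46L, 20L)))
  expect_equal(sum(t1$patients$lvsi != "negative"), 78)
  # fixtures are deterministic
  expect_identical(table1_cohort(), t1)
  # POLE-mut fixture patients are event-free with >= 60 months follow-up
  pole <- t1$true_labels$true_subgroup == "POLE_mut"
  expect_false(any(t1$patients$pfs_event[pole]))
  expect_true(all(t1$patients$os_months[pole] >= 60))
})
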
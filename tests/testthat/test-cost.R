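override_costs <- function() {
  cost_config(p53_upgrade_mode = "explicit_override",
              therapy_change_override = 12288L)
}

test_that("adjuvant costs are exact integer lookups", {
  expect_equal(adjuvant_cost("low"), 0L)
  expect_equal(adjuvant_cost("intermediate"), 53400L)
  expect_equal(adjuvant_cost("high_intermediate"), 127000L)
  expect_equal(adjuvant_cost("high"), 151722L)
  expect_error(adjuvant_cost("very_high"), "missing",
               class = "endomol_config_error")
})

test_that("testing cost is the tally-weighted sum of unit costs", {
  expect_equal(testing_cost(c(POLE = 80L)), 360000L)
  expect_equal(testing_cost(c(MMR = 80L, POLE = 55L, p53 = 50L)), 389600L)
  expect_equal(testing_cost(c(POLE = 80L, MMR = 75L, p53 = 50L)), 495000L)
  expect_equal(testing_cost(integer()), 0L)
  expect_error(testing_cost(c(NGS = 1L)), "unit costs",
               class = "endomol_config_error")
})

test_that("therapy-change pricing follows the omission/escalation rules", {
  asg <- tibble::tibble(
    therapy_action = c("omit_adjuvant", "omit_adjuvant", "omit_adjuvant"),
    conventional_risk = c("intermediate", "high_intermediate",
                          "high_intermediate"))
  expect_equal(therapy_change_cost(asg), -307400L)

  none <- tibble::tibble(therapy_action = "unchanged",
                         conventional_risk = "low")
  expect_equal(therapy_change_cost(none), 0L)

  esc <- dplyr::bind_rows(asg, tibble::tibble(
    therapy_action = rep("add_chemoradiation", 3),
    conventional_risk = rep("intermediate", 3)))
  # principled mode prices each escalation at high minus conventional
  expect_equal(therapy_change_cost(esc),
               -307400L + 3L * (151722L - 53400L))
  # override mode reports the configured net for escalating strategies
  expect_equal(therapy_change_cost(esc, override_costs()), 12288L)
  # ... but computes omission-only strategies
  expect_equal(therapy_change_cost(asg, override_costs()), -307400L)
})

test_that("strategy comparison reproduces every internally consistent cost cell", {
  t3 <- table3_cohort()
  rep <- strategy_comparison(t3$patients, t3$markers, costs = override_costs())
  df <- tibble::as_tibble(rep)
  expect_equal(attr(rep, "reference_total"), 5099366L)

  get <- function(id, col) df[[col]][df$strategy_id == id]
  expect_equal(get("conventional", "total_cost"), 5099366L)
  expect_equal(get("who/all", "total_cost"), 5606654L)
  expect_equal(get("promise/all", "total_cost"), 5501254L)
  expect_equal(get("pole_only/all", "total_cost"), 5151966L)
  expect_equal(get("promise/at_least_intermediate", "total_cost"), 5348254L)
  expect_equal(get("pole_only/at_least_intermediate", "total_cost"), 5016966L)

  expect_equal(get("who/all", "testing_cost"), 495000L)
  expect_equal(get("promise/all", "testing_cost"), 389600L)
  expect_equal(get("pole_only/all", "testing_cost"), 360000L)
  expect_equal(get("promise/at_least_intermediate", "testing_cost"), 236600L)
  expect_equal(get("pole_only/at_least_intermediate", "testing_cost"), 225000L)
  # the WHO-selective testing cost computes to 308,840 and is annotated
  expect_equal(get("who/at_least_intermediate", "testing_cost"), 308840L)
  expect_match(attr(rep, "annotations"), "2,000")

  expect_equal(get("promise/all", "therapy_change_cost"), 12288L)
  expect_equal(get("pole_only/all", "therapy_change_cost"), -307400L)

  expect_equal(get("who/all", "pct_change_vs_reference"), 9.9)
  expect_equal(get("promise/all", "pct_change_vs_reference"), 7.9)
  expect_equal(get("pole_only/all", "pct_change_vs_reference"), 1.0)
  expect_equal(get("promise/at_least_intermediate",
                   "pct_change_vs_reference"), 4.9)
  expect_equal(get("pole_only/at_least_intermediate",
                   "pct_change_vs_reference"), -1.6)
})

test_that("report totals satisfy the cost identity and sign property", {
  t3 <- table3_cohort()
  rep <- tibble::as_tibble(
    strategy_comparison(t3$patients, t3$markers, costs = override_costs()))
  ref <- rep$total_cost[rep$strategy_id == "conventional"]
  expect_equal(rep$total_cost,
               ref + rep$testing_cost + rep$therapy_change_cost)
  expect_equal(rep$adjuvant_cost_total + rep$testing_cost, rep$total_cost)
  expect_equal(sign(rep$pct_change_vs_reference),
               sign(rep$testing_cost + rep$therapy_change_cost))
})

test_that("testing and adjuvant components are additive over disjoint subsets", {
  t3 <- table3_cohort()
  idx <- seq_len(nrow(t3$patients)) %% 2 == 0
  strategies <- tibble::tibble(algorithm = "promise", selection = "all")
  whole <- tibble::as_tibble(strategy_comparison(
    t3$patients, t3$markers, strategies, override_costs()))
  parts <- lapply(list(idx, !idx), function(i) {
    suppressWarnings(tibble::as_tibble(strategy_comparison(
      t3$patients[i, ], dplyr::semi_join(t3$markers, t3$patients[i, ],
                                         by = "patient_id"),
      strategies, cost_config())))  # move_to_high: additive by construction
  })
  whole_m <- tibble::as_tibble(strategy_comparison(
    t3$patients, t3$markers, strategies, cost_config()))
  for (col in c("testing_cost", "adjuvant_cost_total", "total_cost")) {
    expect_equal(parts[[1]][[col]] + parts[[2]][[col]],
                 whole_m[[col]])
  }
  expect_equal(whole$testing_cost, whole_m$testing_cost)
})

test_that("zero unit costs and zero override leave every total at the reference", {
  t3 <- table3_cohort()
  zero <- cost_config(
    test_unit_costs = c(POLE = 0L, MMR = 0L, p53 = 0L),
    treatment_costs = c(low = 0L, intermediate = 0L,
                        high_intermediate = 0L, high = 0L))
  rep <- tibble::as_tibble(strategy_comparison(t3$patients, t3$markers,
                                               costs = zero))
  expect_true(all(rep$total_cost == rep$total_cost[1]))
  expect_true(all(rep$therapy_change_cost == 0L))
})

test_that("the comparison rejects empty cohorts and drops late-stage rows", {
  t1 <- table1_cohort()
  expect_error(strategy_comparison(t1$patients[0, ], t1$markers),
               "empty", class = "endomol_cost_error")
  expect_warning(
    rep <- strategy_comparison(
      t1$patients, t1$markers,
      tibble::tibble(algorithm = "promise", selection = "all"),
      override_costs()),
    "early stage")
  expect_equal(sum(tibble::as_tibble(rep)$risk_group_counts[[1]]), 80L)
})
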
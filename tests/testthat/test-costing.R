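test_that("discount factors follow the booking conventions", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(0:20, 0), rep(1, 21))
  expect_equal(discount_factor(4, 0.05), 1 / 1.05)
  expect_equal(discount_factor(4, 0.05), 0.952381, tolerance = 1e-6)
  # annual-boundary convention discounts by completed years only
  expect_equal(discount_factor(0:7, 0.05, convention = "annual"),
               c(rep(1, 4), rep(1 / 1.05, 4)))
  expect_error(discount_factor(-1, 0.05), "non-negative")
})

test_that("ILR device acquisition books the whole cohort at entry", {
  tr <- base_run("ILR", 3)
  led <- accrue_costs(tr, costs = base_inputs$costs,
                      workup_cost_per_event = 164.32)
  expect_equal(led$totals_undiscounted[["device_acquisition"]], 394000)
  expect_equal(led$totals_discounted[["device_acquisition"]], 394000)
  expect_equal(unname(led$cycle_undiscounted[1, "device_acquisition"]), 394000)
  expect_true(all(led$cycle_undiscounted[-1, "device_acquisition"] == 0))
  # no diagnostic-test costs within the ILR battery life
  expect_equal(led$totals_discounted[["workup"]], 0)
})

test_that("zero unit costs produce an all-zero ledger", {
  zero <- cost_parameters(device_acquisition = 0, implantation = 0,
                          explantation = 0, followup_visit = 0,
                          minor_trauma_tariff = 0, major_trauma_tariff = 0,
                          trauma_cost_per_event = 0)
  led <- accrue_costs(base_run("ILR", 3), costs = zero,
                      workup_cost_per_event = 0)
  expect_equal(led$total_discounted, 0)
  expect_true(all(led$cycle_discounted == 0))
})

test_that("a single-cycle toy cohort accrues trauma and workup arithmetically", {
  clin <- clinical_parameters(cohort_size = 100, annual_syncope_rate = 0.4,
                              horizon_years = 0.25)
  costs <- cost_parameters(trauma_cost_per_event = 1000,
                           annual_discount_rate = 0)
  tr <- run_cohort(clin, "CDP", lt_zero)
  led <- accrue_costs(tr, clin, costs, workup_cost_per_event = 100)
  # 100 patients x 0.1 per-cycle syncope probability = 10 expected episodes
  expect_equal(led$totals_discounted[["trauma"]], 10000)
  expect_equal(led$totals_discounted[["workup"]], 1000)
  expect_equal(led$total_discounted, 11000)
})

test_that("zero discount rate equates discounted and undiscounted streams", {
  costs0 <- cost_parameters(annual_discount_rate = 0)
  for (arm in c("ILR", "CDP")) {
    led <- accrue_costs(base_run(arm, 30), costs = costs0,
                        workup_cost_per_event = 164.32)
    expect_equal(led$totals_discounted, led$totals_undiscounted)
  }
  # and with a positive rate every component is weakly cheaper discounted
  led5 <- accrue_costs(base_run("ILR", 30), costs = base_inputs$costs,
                       workup_cost_per_event = 164.32)
  expect_true(all(led5$totals_discounted <= led5$totals_undiscounted + 1e-9))
})

test_that("grand total equals the sum of its components", {
  for (arm in c("ILR", "CDP")) for (h in c(3, 30)) {
    led <- accrue_costs(base_run(arm, h), costs = base_inputs$costs,
                        workup_cost_per_event = 164.32)
    expect_equal(led$total_discounted, sum(led$totals_discounted),
                 tolerance = 1e-6)
    expect_equal(led$total_undiscounted, sum(led$totals_undiscounted),
                 tolerance = 1e-6)
  }
})

test_that("every ILR device has exactly one explantation or death", {
  # diagnosed during battery life + survivors at expiry + deaths with the
  # device = cohort size
  tr <- base_run("ILR", 30)
  in_batt <- tr$cycle < 12
  accounted <- sum(tr$new_diagnosed[in_batt]) + sum(tr$new_dead[in_batt]) +
    tr$undiagnosed[13]
  expect_equal(accounted, 197, tolerance = 1e-9)
  led <- accrue_costs(tr, costs = base_inputs$costs,
                      workup_cost_per_event = 164.32)
  expect_equal(led$totals_undiscounted[["explantation"]] / 127.8 +
                 sum(tr$new_dead[in_batt]), 197, tolerance = 1e-9)
})

test_that("the CDP ledger ignores device-cost parameters", {
  tr <- base_run("CDP", 30)
  a <- accrue_costs(tr, costs = cost_parameters(),
                    workup_cost_per_event = 164.32)
  b <- accrue_costs(tr, costs = cost_parameters(device_acquisition = 9999,
                                                implantation = 999,
                                                followup_visit = 99),
                    workup_cost_per_event = 164.32)
  expect_equal(a$total_discounted, b$total_discounted)
})

test_that("ILR total cost falls as the diagnostic yield rises", {
  totals <- vapply(c(0.2, 0.4, 0.628, 0.8), function(d) {
    clin <- clinical_parameters(diagnosis_prob_ilr = d)
    accrue_costs(run_cohort(clin, "ILR", lt_default), clin,
                 base_inputs$costs,
                 workup_cost_per_event = 164.32)$total_discounted
  }, numeric(1))
  expect_true(all(diff(totals) < 0))
})

test_that("arm comparison reports savings on the CDP base", {
  tr_i <- base_run("ILR", 30); tr_c <- base_run("CDP", 30)
  li <- accrue_costs(tr_i, costs = base_inputs$costs,
                     workup_cost_per_event = 164.32)
  lc <- accrue_costs(tr_c, costs = base_inputs$costs,
                     workup_cost_per_event = 164.32)
  cmp <- compare_costs(li, lc, 197)
  expect_equal(cmp$savings, cmp$cdp_total - cmp$ilr_total)
  expect_equal(cmp$per_patient_savings, cmp$savings / 197)
  expect_equal(cmp$pct_reduction, 100 * cmp$savings / cmp$cdp_total)
  same <- compare_costs(li, li, 197)
  expect_equal(same$savings, 0)
  # matches the fast evaluation path used by the sensitivity analyses
  fast <- evaluate_savings(base_inputs)
  expect_equal(fast$savings, cmp$savings, tolerance = 1e-9)
})

test_that("per-event cost range across scenarios rounds to the nearest 10", {
  expect_equal(average_event_cost_range(base_scenarios(), 1687.57),
               c(1760, 2800))
  one <- base_scenarios()["Sousa Pedro"]
  expect_equal(average_event_cost_range(one, 1687.57),
               rep(round(164.32 + 1687.57, -1), 2))
  flat <- list(scenario_profile("flat", data.frame(
    test = "a", unit_price = 100, fraction = 1)))
  expect_equal(average_event_cost_range(flat, 0), c(100, 100))
})
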
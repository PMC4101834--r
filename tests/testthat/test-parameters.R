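test_that("cohort size derivation rounds half away from zero", {
  expect_identical(derive_cohort_size(population_source(1010, 0.195)), 197L)
  expect_identical(derive_cohort_size(population_source(100, 0)), 0L)
  expect_identical(derive_cohort_size(population_source(1000, 0.5)), 500L)
})

test_that("parameter validators reject out-of-support values", {
  expect_error(clinical_parameters(diagnosis_prob_ilr = 1.2), "probability")
  expect_error(clinical_parameters(annual_syncope_rate = 5),
               "cycle_length_years")
  expect_error(clinical_parameters(cohort_size = 0), "at least 1")
  expect_error(clinical_parameters(horizon_years = 1.1), "multiple")
  expect_error(cost_parameters(annual_discount_rate = 1), "< 1")
  expect_error(cost_parameters(device_acquisition = -1), "non-negative")
  expect_error(scenario_profile("x", data.frame(test = "a", unit_price = 1,
                                                fraction = 1.5)),
               "fractions")
})

test_that("expected trauma cost matches two-outcome enumeration", {
  # brute-force oracle: enumerate {minor, major} outcomes explicitly
  enum <- function(minor, major, p, s)
    sum(c(minor, major) * c(p * (1 - s), p * s))
  cases <- list(c(2684.83, 6058.25, 0.522, 0.1616),
                c(1000, 2000, 0.3, 0.5),
                c(500, 9000, 1, 1),
                c(100, 200, 0, 0.4))
  for (cs in cases)
    expect_equal(expected_trauma_cost(cs[1], cs[2], cs[3], cs[4]),
                 enum(cs[1], cs[2], cs[3], cs[4]))
  # frozen value of the base-case tariffs (direct arithmetic):
  # 2684.83*0.522*0.8384 + 6058.25*0.522*0.1616 = 1686.05 unrounded
  expect_equal(expected_trauma_cost(2684.83, 6058.25, 0.522, 0.1616),
               1686.0468, tolerance = 1e-5)
  # boundary: certain severe injury pays exactly the major tariff
  expect_equal(expected_trauma_cost(100, 6058.25, 1, 1), 6058.25)
  # bounded by the larger tariff
  set.seed(11)
  for (i in 1:50) {
    minor <- runif(1, 0, 5000); major <- runif(1, 0, 9000)
    v <- expected_trauma_cost(minor, major, runif(1), runif(1))
    expect_gte(v, 0); expect_lte(v, max(minor, major))
  }
})

test_that("weighted workup cost is the fraction-weighted price sum", {
  empty <- scenario_profile("empty", data.frame(
    test = character(), unit_price = numeric(), fraction = numeric()))
  expect_equal(weighted_workup_cost(empty), 0)
  one <- scenario_profile("one", data.frame(test = "ecg", unit_price = 6.5,
                                            fraction = 1))
  expect_equal(weighted_workup_cost(one), 6.5)
  # hand-summed from the published items: 88.5996 (printed total is 88.51)
  baron <- base_scenarios()[["Baron-Esquivias"]]
  expect_equal(weighted_workup_cost(baron, warn = FALSE), 88.5996,
               tolerance = 1e-4)
  expect_equal(canonical_workup_cost(baron), 88.51)
})

test_that("recomputed-vs-printed discrepancies above 1 EUR are warned about", {
  expect_warning(weighted_workup_cost(base_scenarios()[["Edvardsson"]]),
                 "canonical")
  # Sousa Pedro recomputes within 1 EUR of its printed total: silent
  expect_silent(weighted_workup_cost(base_scenarios()[["Sousa Pedro"]]))
})

test_that("workup cost is linear in prices and monotone in fractions", {
  set.seed(21)
  for (i in 1:20) {
    k <- nrow0 <- sample(1:8, 1)
    items <- data.frame(test = paste0("t", 1:k),
                        unit_price = runif(k, 0, 500),
                        fraction = runif(k))
    p <- scenario_profile("fuzz", items)
    lambda <- runif(1, 0, 3)
    scaled <- items; scaled$unit_price <- scaled$unit_price * lambda
    expect_equal(weighted_workup_cost(scenario_profile("s", scaled)),
                 lambda * weighted_workup_cost(p))
    bumped <- items
    j <- sample(k, 1)
    bumped$fraction[j] <- min(1, bumped$fraction[j] + runif(1, 0, 1 - bumped$fraction[j]))
    expect_gte(weighted_workup_cost(scenario_profile("b", bumped)),
               weighted_workup_cost(p) - 1e-12)
  }
})

test_that("configuration files round-trip bit-identically", {
  f1 <- tempfile(fileext = ".yaml"); f2 <- tempfile(fileext = ".yaml")
  write_model_config(base_inputs, f1)
  reread <- read_model_config(f1)
  write_model_config(reread, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(reread$clinical, base_inputs$clinical)
  expect_equal(reread$costs, base_inputs$costs)
  expect_equal(reread$workup_cost_per_event, base_inputs$workup_cost_per_event)
  expect_equal(canonical_workup_cost(reread$scenarios[["Farwell"]]), 72.41)
})
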
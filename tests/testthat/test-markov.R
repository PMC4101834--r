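test_that("annual-to-cycle syncope conversion follows the linear rule", {
  expect_equal(cycle_syncope_prob(0.6, 0.25), 0.15)
  expect_equal(cycle_syncope_prob(0, 0.25), 0)
  expect_equal(cycle_syncope_prob(0.81, 0.25), 0.2025)
  expect_error(cycle_syncope_prob(5, 0.25), "probability")
  expect_equal(cycle_syncope_prob(0.6, 0.25, method = "exponential"),
               1 - exp(-0.15))
})

test_that("cycle death probability applies the hazard ratio on the annual scale", {
  lt <- life_table(data.frame(age = c(60, 62), annual_death_prob = c(0.010, 0.010)))
  expect_equal(cycle_death_prob(61, lt, 1.32, 0.25),
               1 - (1 - 0.0132)^0.25)
  expect_equal(cycle_death_prob(61, lt, 1.32, 0.25), 0.0033164,
               tolerance = 1e-4)
  # hr = 1 reproduces the unadjusted conversion
  expect_equal(cycle_death_prob(61, lt, 1, 0.25), 1 - 0.990^0.25)
  # q = 0 stays 0 under any hazard ratio
  expect_equal(cycle_death_prob(50, lt_zero, 7, 0.25), 0)
  # adjusted annual probability is capped at 1
  hi <- life_table(data.frame(age = c(60, 62), annual_death_prob = c(0.9, 0.9)))
  expect_equal(cycle_death_prob(61, hi, 5, 1), 1)
})

test_that("one cohort step does the expected bookkeeping", {
  st <- cohort_step(197, 0.15, 0.628, 0)
  expect_equal(st$episodes, 197 * 0.15)
  expect_equal(st$new_diagnosed, 197 * 0.15 * 0.628)
  expect_equal(st$new_diagnosed, 18.5574, tolerance = 1e-4)
  expect_equal(st$episodes, 29.55)
  # sigma = 0: only deaths
  st0 <- cohort_step(100, 0, 0.5, 0.02)
  expect_equal(st0$episodes, 0)
  expect_equal(st0$new_diagnosed, 0)
  expect_equal(st0$new_dead, 2)
  # absorbing limit: certain event + certain diagnosis empties the pool
  st1 <- cohort_step(100, 1, 1, 0)
  expect_equal(st1$new_diagnosed, 100)
  expect_equal(st1$undiagnosed_end, 0)
  # zero pool propagates zeros
  stz <- cohort_step(0, 0.15, 0.628, 0.003, injury_prob = 0.5)
  expect_true(all(unlist(stz) == 0))
  expect_error(cohort_step(10, 1, 1, 0.5), "exceeds 1")
})

test_that("occupancy is conserved at every cycle", {
  for (arm in c("ILR", "CDP")) for (h in c(3, 30)) {
    tr <- base_run(arm, h)
    balance <- tr$undiagnosed_end + tr$cum_diagnosed + tr$cum_dead
    expect_lt(max(abs(balance - 197)), 1e-9)
    expect_true(all(as.matrix(tr[, -1]) >= 0))
    expect_true(all(diff(tr$cum_diagnosed) >= 0))
    expect_true(all(diff(tr$cum_episodes) >= 0))
  }
})

test_that("zero-mortality trace matches the geometric closed form exactly", {
  for (delta in c(0.125, 0.4, 0.628)) {
    clin <- clinical_parameters(diagnosis_prob_cdp = delta, horizon_years = 3)
    tr <- run_cohort(clin, "CDP", lt_zero)
    tcyc <- seq_len(nrow(tr))
    expect_equal(tr$cum_diagnosed,
                 197 * (1 - (1 - 0.15 * delta)^tcyc), tolerance = 1e-12)
    expect_equal(tr$undiagnosed_end,
                 197 * (1 - 0.15 * delta)^tcyc, tolerance = 1e-12)
  }
})

test_that("cumulative diagnoses rise and episodes fall with the yield", {
  deltas <- seq(0.1, 0.9, by = 0.2)
  traces <- lapply(deltas, function(d)
    run_cohort(clinical_parameters(diagnosis_prob_ilr = d, horizon_years = 3),
               "ILR", lt_default))
  for (i in seq_along(deltas)[-1]) {
    expect_true(all(traces[[i]]$cum_diagnosed >=
                      traces[[i - 1]]$cum_diagnosed - 1e-12))
    expect_true(all(traces[[i]]$cum_episodes <=
                      traces[[i - 1]]$cum_episodes + 1e-12))
  }
})

test_that("arms are interchangeable when the yields coincide", {
  clin <- clinical_parameters(diagnosis_prob_ilr = 0.125)
  ilr <- run_cohort(clin, "ILR", lt_default)
  cdp <- run_cohort(clin, "CDP", lt_default)
  expect_equal(as.data.frame(ilr), as.data.frame(cdp), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the vectorised recursion agrees with repeated single steps", {
  clin <- clinical_parameters(horizon_years = 2)
  tr <- run_cohort(clin, "ILR", lt_default)
  u <- 197
  for (t in seq_len(nrow(tr))) {
    st <- cohort_step(u, 0.15,
                      arm_spec("ILR", clin)$yield_at(t - 1),
                      cycle_death_prob(61 + (t - 1) * 0.25, lt_default,
                                       1.32, 0.25),
                      injury_prob = 0.522)
    expect_equal(tr$new_diagnosed[t], st$new_diagnosed, tolerance = 1e-12)
    expect_equal(tr$episodes[t], st$episodes, tolerance = 1e-12)
    expect_equal(tr$new_dead[t], st$new_dead, tolerance = 1e-12)
    u <- st$undiagnosed_end
  }
})

test_that("the ILR yield schedule reverts to the conventional yield after battery life", {
  clin <- clinical_parameters()
  arm <- arm_spec("ILR", clin)
  expect_equal(arm$yield_at(c(0, 11, 12, 119)),
               c(0.628, 0.628, 0.125, 0.125))
  expect_equal(arm_spec("CDP", clin)$yield_at(c(0, 50)), c(0.125, 0.125))
})

test_that("summaries report the published rounding convention", {
  s <- summarize_trace(base_run("ILR", 3))
  expect_identical(unname(s$counts[c("diagnosed_total", "diagnosed_year1")]),
                   c(135, 64))
  expect_equal(s$raw[["diagnosed_total"]], 134.6, tolerance = 0.01)
  expect_equal(round_half_up(c(39.5, -2.5, 196.95)), c(40, -3, 197))
})
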
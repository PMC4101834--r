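test_that("one-way analysis brackets the base and reports both ends", {
  # degenerate range: zero-width bar
  e <- one_way(base_inputs, "diagnosis_prob_ilr", 0.628, 0.628)
  expect_equal(e$width, 0)
  expect_equal(e$savings_low, e$savings_high)
  expect_error(one_way(base_inputs, "diagnosis_prob_ilr", 0.7, 0.9),
               "bracket")
  expect_error(one_way(base_inputs, "no_such_param", 0, 1), "unknown")
})

test_that("the two published non-saving one-way scenarios are negative", {
  # injury probability reduced to 0.25 makes ILR no longer cost-saving
  inj <- one_way(base_inputs, "injury_prob_per_event", 0.25, 1)
  expect_lt(inj$savings_low, 0)
  expect_gt(inj$savings_high, 0)
  # ILR yield forced down to the conventional yield: device costs dominate
  eq <- evaluate_savings(set_param(base_inputs, "diagnosis_prob_ilr", 0.125))
  expect_lt(eq$savings, 0)
})

test_that("trauma drivers rederive the per-event trauma cost", {
  bumped <- set_param(base_inputs, "minor_trauma_tariff", 5369.66)
  expect_equal(bumped$costs$trauma_cost_per_event,
               expected_trauma_cost(5369.66, 6058.25, 0.522, 0.1616))
  # non-driver parameters leave the canonical value untouched
  other <- set_param(base_inputs, "device_acquisition", 1000)
  expect_equal(other$costs$trauma_cost_per_event, 1687.57)
  expect_equal(get_param(set_param(base_inputs, "workup_cost_per_event", 88.51),
                         "workup_cost_per_event"), 88.51)
})

test_that("tornado bars are sorted by width with a stable name tie-break", {
  ranges <- default_tornado_ranges(base_inputs)
  tor <- tornado(base_inputs, ranges)
  expect_true(all(diff(tor$width) <= 1e-9))
  # input order must not matter
  shuffled <- ranges[rev(seq_len(nrow(ranges))), ]
  expect_equal(tornado(base_inputs, shuffled), tor)
  # degenerate ranges: all widths zero, alphabetical order
  degen <- data.frame(parameter = c("followup_visit", "device_acquisition"),
                      low = c(31, 2000), high = c(31, 2000))
  td <- tornado(base_inputs, degen)
  expect_equal(td$width, c(0, 0))
  expect_equal(td$parameter, c("device_acquisition", "followup_visit"))
  single <- tornado(base_inputs, data.frame(parameter = "implantation",
                                            low = 63.9, high = 255.6))
  expect_identical(nrow(single), 1L)
})

test_that("the influential tornado parameters are the clinically expected ones", {
  tor <- tornado(base_inputs)
  key <- c("diagnosis_prob_ilr", "minor_trauma_tariff",
           "injury_prob_per_event", "annual_syncope_rate")
  expect_true(tor$parameter[1] %in% key)
  expect_true(all(key %in% tor$parameter[1:6]))
})

test_that("threshold sweep is monotone with one break-even inside the bracket", {
  th <- threshold_sweep(base_inputs, grid = seq(0.1, 0.78, by = 0.02))
  expect_true(all(diff(th$curve$savings) > 0))
  sgn <- sign(th$curve$savings)
  expect_identical(sum(diff(sgn > 0) != 0), 1L)
  expect_gt(th$break_even, 0.125)
  expect_lt(th$break_even, 0.628)
  expect_equal(th$break_even_increment, th$break_even - 0.125)
  # the base-case and equal-yield ends have the published signs
  expect_gt(evaluate_savings(base_inputs)$savings, 0)
  expect_lt(th$curve$savings[1], 0)
})

test_that("parameter draws are reproducible and respect their support", {
  specs <- default_psa_specs(base_inputs)
  set.seed(123); d1 <- draw_parameters(specs, 500)
  set.seed(123); d2 <- draw_parameters(specs, 500)
  expect_identical(d1, d2)
  expect_true(all(d1$diagnosis_prob_ilr >= 0 & d1$diagnosis_prob_ilr <= 1))
  expect_true(all(d1$injury_prob_per_event >= 0 & d1$injury_prob_per_event <= 1))
  expect_true(all(d1$minor_trauma_tariff >= 0))
  expect_true(all(d1$mortality_hazard_ratio > 0))
  # dispersion calibration: 95% interval of gamma and lognormal ~ [b/2, 2b]
  expect_equal(unname(quantile(d1$mortality_hazard_ratio, 0.5)), 1.32,
               tolerance = 0.1)
  s <- specs[["device_acquisition"]]
  expect_equal(qgamma(0.975, s$pars$shape, s$pars$rate) /
                 qgamma(0.025, s$pars$shape, s$pars$rate), 4, tolerance = 1e-6)
  expect_equal(s$pars$shape / s$pars$rate, 2000)
  # degenerate family returns the base value exactly
  dg <- draw_parameters(degenerate_specs(), 3)
  expect_equal(unique(dg$diagnosis_prob_ilr), 0.628)
  expect_error(uncertainty_spec("diagnosis_prob_ilr", "beta", mean = 1.2),
               "probabilities")
})

test_that("PSA with degenerate distributions reproduces the deterministic result", {
  det <- evaluate_savings(base_inputs)
  # degenerate tariffs rederive the trauma cost, as any sampled tariff would
  det_inp <- set_param(base_inputs, "minor_trauma_tariff", 2684.83)
  det2 <- evaluate_savings(det_inp)
  res <- psa(base_inputs, degenerate_specs(), n_draws = 5, seed = 9)
  expect_equal(unique(res$savings), det2$savings, tolerance = 1e-9)
  expect_equal(res$mean_savings, det2$savings, tolerance = 1e-9)
  # the rederived-vs-canonical trauma difference is well under a euro/event
  expect_lt(abs(det$savings - det2$savings) / det$savings, 0.01)
  # single draw: mean equals the draw
  one <- psa(base_inputs, degenerate_specs(), n_draws = 1, seed = 9)
  expect_equal(one$mean_savings, one$savings[1])
})

test_that("PSA mean stabilises and most draws are cost-saving", {
  small <- psa(base_inputs, n_draws = 300, seed = 101)
  big <- psa(base_inputs, n_draws = 3000, seed = 101)
  se <- sd(small$savings) / sqrt(small$n_draws)
  expect_lt(abs(small$mean_savings - big$mean_savings), 3 * se)
  expect_gt(big$fraction_cost_saving, 0.6)
  expect_equal(big$fraction_cost_saving, mean(big$savings > 0))
  expect_equal(big$mean_savings, mean(big$savings))
  # same seed, same result
  again <- psa(base_inputs, n_draws = 300, seed = 101)
  expect_identical(again$savings, small$savings)
})
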
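# Report generation: the deterministic results table across scenarios and
# horizons, and file-based outputs for the sensitivity analyses. Costs are
# formatted to whole euro and probabilities to 4 decimals at this layer
# only; all computation upstream is unrounded.

log_run <- function(inputs, what, horizon, seed = NULL) {
  message(sprintf(
    "[syncopeBIA] %s: horizon=%gy scenario='%s' conventions=%s/%s/%s%s",
    what, horizon, inputs$base_scenario, inputs$rate_conversion,
    inputs$event_order, inputs$discount_convention,
    if (is.null(seed)) "" else sprintf(" seed=%d", seed)))
}

arm_run <- function(inputs, arm, horizon, workup) {
  tr <- run_cohort(inputs$clinical, arm, inputs$life_table,
                   horizon_years = horizon,
                   rate_conversion = inputs$rate_conversion,
                   event_order = inputs$event_order)
  ledger <- accrue_costs(tr, inputs$clinical, inputs$costs, workup,
                         convention = inputs$discount_convention)
  list(trace = tr, summary = summarize_trace(tr), ledger = ledger)
}

#' Deterministic results table across scenarios and horizons
#'
#' Runs both arms at each horizon and assembles the standard results table:
#' counts (diagnosed, undiagnosed alive, episodes, injuries), the four cost
#' component rows, and one total-cost row per workup scenario, with an
#' overall-savings (CDP minus ILR) column per horizon. Count rows and the
#' device/admission cost rows are scenario-independent; only the
#' diagnostic-test row and the totals vary with the scenario's per-event
#' workup cost.
#'
#' @param inputs a [model_inputs()].
#' @param horizons model horizons, years.
#' @return `data.frame` with columns `output`, then
#'   `<ARM>_<horizon>y` and `savings_<horizon>y`.
#' @export
base_case_table <- function(inputs, horizons = c(30, 3)) {
  stopifnot(inherits(inputs, "model_inputs"))
  cols <- list()
  for (h in horizons) {
    runs <- lapply(c(ILR = "ILR", CDP = "CDP"), function(a)
      arm_run(inputs, a, h, inputs$workup_cost_per_event))
    for (a in c("ILR", "CDP")) {
      r <- runs[[a]]
      cnt <- r$summary$counts
      led <- r$ledger$totals_discounted
      vals <- c(patients_diagnosed = unname(cnt["diagnosed_total"]),
                patients_undiagnosed_alive = unname(cnt["undiagnosed_alive"]),
                total_syncope_episodes = unname(cnt["episodes"]),
                injuries = unname(cnt["injuries"]),
                cost_device_acquisition = unname(led["device_acquisition"]),
                cost_device_related = unname(led["implantation"] +
                                               led["followup"] + led["explantation"]),
                cost_syncope_admissions = unname(led["trauma"]))
      # per-scenario diagnostic-test cost and totals
      disc_episodes_workup <- led["workup"] / inputs$workup_cost_per_event
      for (sn in names(inputs$scenarios)) {
        w <- canonical_workup_cost(inputs$scenarios[[sn]])
        test_cost <- unname(disc_episodes_workup * w)
        vals[paste0("cost_diagnostic_tests (", sn, ")")] <- test_cost
        vals[paste0("cost_total (", sn, ")")] <-
          unname(vals["cost_device_acquisition"] + vals["cost_device_related"] +
                   vals["cost_syncope_admissions"] + test_cost)
      }
      cols[[sprintf("%s_%gy", a, h)]] <- vals
    }
    cols[[sprintf("savings_%gy", h)]] <-
      cols[[sprintf("CDP_%gy", h)]] - cols[[sprintf("ILR_%gy", h)]]
  }
  out <- data.frame(output = names(cols[[1]]), cols, check.names = FALSE)
  rownames(out) <- NULL
  out
}

fmt_cost <- function(x) sprintf("%.0f", x)

write_report_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x)
    ifelse(abs(x) >= 10 | x == round(x), sprintf("%.0f", x),
           sprintf("%.4f", x)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Write the deterministic base-case report
#'
#' CSV and JSON renderings of [base_case_table()] for both horizons, plus
#' the headline comparison (totals, absolute and relative savings, saving
#' per patient) for the base scenario.
#'
#' @param inputs a [model_inputs()].
#' @param out_dir output directory (created if missing).
#' @param horizons horizons to tabulate, years.
#' @return paths of the files written, invisibly.
#' @export
run_base_case_report <- function(inputs, out_dir, horizons = c(30, 3)) {
  ensure_dir(out_dir)
  for (h in horizons) log_run(inputs, "base-case", h)
  tab <- base_case_table(inputs, horizons)
  csv <- file.path(out_dir, "base_case.csv")
  write_report_csv(tab, csv)
  cmp <- evaluate_savings(inputs, horizon_years = max(horizons))
  js <- file.path(out_dir, "base_case.json")
  jsonlite::write_json(
    list(table = tab, headline = cmp,
         cohort_size = inputs$clinical$cohort_size,
         base_scenario = inputs$base_scenario,
         conventions = list(rate_conversion = inputs$rate_conversion,
                            event_order = inputs$event_order,
                            discount_convention = inputs$discount_convention)),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, js))
}

#' Write the tornado (one-way sensitivity) report
#'
#' @inheritParams run_base_case_report
#' @param ranges optional `data.frame(parameter, low, high)`.
#' @return path of the CSV written, invisibly.
#' @export
run_tornado_report <- function(inputs, out_dir, ranges = NULL) {
  ensure_dir(out_dir)
  log_run(inputs, "tornado", inputs$clinical$horizon_years)
  tor <- tornado(inputs, ranges)
  csv <- file.path(out_dir, "tornado.csv")
  write_report_csv(tor, csv)
  invisible(csv)
}

#' Write the threshold-sweep report
#'
#' Curve of lifetime savings against the ILR diagnostic yield, with the
#' interpolated break-even yield and its increment over the conventional
#' yield as an annotation file.
#'
#' @inheritParams run_base_case_report
#' @param grid yields to evaluate.
#' @return paths written, invisibly.
#' @export
run_threshold_report <- function(inputs, out_dir,
                                 grid = seq(0.1, 0.78, by = 0.01)) {
  ensure_dir(out_dir)
  log_run(inputs, "threshold", inputs$clinical$horizon_years)
  th <- threshold_sweep(inputs, grid)
  csv <- file.path(out_dir, "threshold_curve.csv")
  write_report_csv(th$curve, csv)
  js <- file.path(out_dir, "threshold_break_even.json")
  jsonlite::write_json(list(break_even = th$break_even,
                            break_even_increment = th$break_even_increment),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Write the probabilistic sensitivity analysis report
#'
#' Runs the PSA for each requested scenario (same seed and draw order per
#' scenario so results are comparable), writes a summary CSV across
#' scenarios and, for the base scenario, the per-draw savings dump and
#' histogram bins.
#'
#' @inheritParams run_base_case_report
#' @param n_draws Monte-Carlo draws per scenario.
#' @param seed RNG seed.
#' @param scenarios scenario names; default all bundled scenarios.
#' @return paths written, invisibly.
#' @export
run_psa_report <- function(inputs, out_dir,
                           n_draws = inputs$psa_settings$n_draws %||% 10000,
                           seed = 1,
                           scenarios = names(inputs$scenarios)) {
  ensure_dir(out_dir)
  rows <- list(); dump <- NULL
  for (sn in scenarios) {
    inp <- inputs
    inp$base_scenario <- sn
    inp$workup_cost_per_event <- canonical_workup_cost(inp$scenarios[[sn]])
    log_run(inp, "psa", inp$clinical$horizon_years, seed)
    res <- psa(inp, default_psa_specs(inp), n_draws = n_draws, seed = seed)
    rows[[sn]] <- data.frame(scenario = sn, n_draws = n_draws, seed = seed,
                             mean_savings = res$mean_savings,
                             mean_per_patient = res$mean_per_patient,
                             fraction_cost_saving = res$fraction_cost_saving,
                             q2.5 = unname(res$quantiles[1]),
                             median = unname(res$quantiles[3]),
                             q97.5 = unname(res$quantiles[5]))
    if (sn == inputs$base_scenario) dump <- res
  }
  csv <- file.path(out_dir, "psa_summary.csv")
  write_report_csv(do.call(rbind, rows), csv)
  paths <- csv
  if (!is.null(dump)) {
    dcsv <- file.path(out_dir, "psa_draws.csv")
    utils::write.csv(data.frame(draw = seq_along(dump$savings),
                                savings = sprintf("%.6f", dump$savings)),
                     dcsv, row.names = FALSE, quote = FALSE)
    paths <- c(paths, dcsv)
  }
  invisible(paths)
}

#' Write the model validation report
#'
#' Cross-checks the cohort engine against its independent oracles and
#' writes the outcomes as JSON: (1) state-occupancy conservation at every
#' cycle; (2) the zero-mortality geometric closed form; (3) microsimulation
#' agreement of the battery-life diagnosed fraction for both arms within
#' three binomial standard errors.
#'
#' @inheritParams run_base_case_report
#' @param n simulated patients for the microsimulation check.
#' @param seed RNG seed for the microsimulation.
#' @return the validation list, invisibly (also written as JSON).
#' @export
run_validation_report <- function(inputs, out_dir, n = 100000, seed = 1) {
  ensure_dir(out_dir)
  log_run(inputs, "validate", inputs$clinical$battery_life_years, seed)
  clin <- inputs$clinical
  clin3 <- do.call(clinical_parameters, utils::modifyList(
    unclass(clin), list(horizon_years = clin$battery_life_years)))
  checks <- list()
  # conservation
  tr <- run_cohort(clin3, "ILR", inputs$life_table)
  bal <- abs(tr$undiagnosed_end + tr$cum_diagnosed + tr$cum_dead -
               clin3$cohort_size)
  checks$conservation <- list(max_abs_error = max(bal),
                              pass = max(bal) < 1e-9)
  # zero-mortality closed form
  lt0 <- life_table(data.frame(age = c(0, 120), annual_death_prob = c(0, 0)))
  tr0 <- run_cohort(clin3, "CDP", lt0)
  sc <- cycle_syncope_prob(clin3$annual_syncope_rate, clin3$cycle_length_years)
  expect0 <- clin3$cohort_size *
    (1 - (1 - sc * clin3$diagnosis_prob_cdp)^nrow(tr0))
  checks$closed_form <- list(
    engine = sum(tr0$new_diagnosed), expected = expect0,
    pass = abs(sum(tr0$new_diagnosed) - expect0) < 1e-9)
  # microsimulation agreement
  for (a in c("ILR", "CDP")) {
    tra <- run_cohort(clin3, a, inputs$life_table,
                      rate_conversion = inputs$rate_conversion,
                      event_order = inputs$event_order)
    p_exp <- sum(tra$new_diagnosed) / clin3$cohort_size
    ph <- simulate_patients(clin3, a, inputs$life_table, n = n, seed = seed,
                            rate_conversion = inputs$rate_conversion,
                            event_order = inputs$event_order)
    p_obs <- summarize_patients(ph)$counts[["diagnosed"]] / n
    se <- sqrt(p_exp * (1 - p_exp) / n)
    checks[[paste0("microsim_", a)]] <- list(
      expected_fraction = p_exp, observed_fraction = p_obs,
      standard_error = se, pass = abs(p_obs - p_exp) <= 3 * se)
  }
  js <- file.path(out_dir, "validation.json")
  jsonlite::write_json(checks, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(checks)
}
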
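# Cost accrual over a cohort trace. Components:
#   device_acquisition, implantation  - ILR arm, whole cohort, cycle 0
#   followup     - ILR arm, per undiagnosed-alive patient, battery period
#   explantation - ILR arm, at diagnosis or battery expiry; waived on death
#   trauma       - expected injury/trauma cost per syncope episode, both arms
#   workup       - diagnostic-test cost per episode: every cycle in CDP,
#                  post-battery only in ILR (the device replaces the workup)

COST_COMPONENTS <- c("device_acquisition", "implantation", "followup",
                     "explantation", "trauma", "workup")

#' Discount factor at a model cycle
#'
#' Costs are booked at cycle start and discounted at a constant annual rate.
#' Under the default per-cycle convention the factor is
#' `(1 + rate)^(-cycle * cycle_length)` (cycle 0 undiscounted); the
#' annual-boundary alternative discounts by completed years,
#' `(1 + rate)^(-floor(cycle * cycle_length))`.
#'
#' @param cycle cycle index from 0 (vector allowed).
#' @param annual_rate annual discount rate.
#' @param cycle_length cycle length, years.
#' @param convention `"per-cycle"` (default) or `"annual"`.
#' @return discount factor(s) in (0, 1].
#' @examples
#' discount_factor(4, 0.05) # one year out: 1/1.05
#' @export
discount_factor <- function(cycle, annual_rate, cycle_length = 0.25,
                            convention = c("per-cycle", "annual")) {
  convention <- match.arg(convention)
  stop_if(any(cycle < 0), "'cycle' must be non-negative")
  years <- cycle * cycle_length
  if (convention == "annual") years <- floor(years + 1e-12)
  (1 + annual_rate)^(-years)
}

accrue_core <- function(trace, arm_id, battery_cycles, clin, costs,
                        workup_cost_per_event, convention) {
  n <- length(trace$cycle)
  df <- discount_factor(trace$cycle, costs$annual_discount_rate,
                        clin$cycle_length_years, convention)
  m <- matrix(0, nrow = n, ncol = length(COST_COMPONENTS),
              dimnames = list(NULL, COST_COMPONENTS))
  m[, "trauma"] <- trace$episodes * costs$trauma_cost_per_event
  if (arm_id == "ILR") {
    in_battery <- trace$cycle < battery_cycles
    m[1, "device_acquisition"] <- clin$cohort_size * costs$device_acquisition
    m[1, "implantation"] <- clin$cohort_size * costs$implantation
    per_cycle_fu <- costs$followup_visit * costs$followup_visits_per_year *
      clin$cycle_length_years
    m[in_battery, "followup"] <- trace$undiagnosed[in_battery] * per_cycle_fu
    # explantation at diagnosis during battery life ...
    m[in_battery, "explantation"] <-
      trace$new_diagnosed[in_battery] * costs$explantation
    # ... plus survivors still undiagnosed at battery expiry (booked at the
    # battery-boundary cycle); never for patients who died with the device
    surv_at_expiry <- if (n > battery_cycles) trace$undiagnosed[battery_cycles + 1L]
                      else trace$undiagnosed_end[n]
    expiry_df <- discount_factor(battery_cycles, costs$annual_discount_rate,
                                 clin$cycle_length_years, convention)
    if (n > battery_cycles)
      m[battery_cycles + 1L, "explantation"] <-
        m[battery_cycles + 1L, "explantation"] + surv_at_expiry * costs$explantation
    m[, "workup"] <- ifelse(in_battery, 0,
                            trace$episodes * workup_cost_per_event)
  } else {
    m[, "workup"] <- trace$episodes * workup_cost_per_event
    surv_at_expiry <- 0; expiry_df <- 1
  }
  disc <- m * df
  totals_undisc <- colSums(m)
  totals_disc <- colSums(disc)
  if (arm_id == "ILR" && n == battery_cycles) {
    # horizon ends exactly at battery expiry: the boundary has no cycle row
    expiry_cost <- surv_at_expiry * costs$explantation
    totals_undisc["explantation"] <- totals_undisc["explantation"] + expiry_cost
    totals_disc["explantation"] <- totals_disc["explantation"] +
      expiry_cost * expiry_df
  }
  list(cycle_undiscounted = m, cycle_discounted = disc, df = df,
       totals_undiscounted = totals_undisc, totals_discounted = totals_disc,
       explant_survivors = surv_at_expiry)
}

#' Accrue discounted cost streams over a cohort trace
#'
#' @param trace a `cohort_trace` from [run_cohort()].
#' @param clin the [clinical_parameters()] used for the trace.
#' @param costs a [cost_parameters()].
#' @param workup_cost_per_event average diagnostic-test cost per syncope
#'   event, EUR (typically [canonical_workup_cost()] of a scenario).
#' @param convention discounting convention, see [discount_factor()].
#' @return A `cost_ledger`: list with per-cycle component matrices
#'   (`cycle_undiscounted`, `cycle_discounted`), per-component totals
#'   (`totals_undiscounted`, `totals_discounted`), grand totals
#'   (`total_undiscounted`, `total_discounted`), the arm and conventions.
#' @export
accrue_costs <- function(trace, clin = attr(trace, "clinical"),
                         costs = cost_parameters(),
                         workup_cost_per_event,
                         convention = c("per-cycle", "annual")) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(costs, "cost_parameters"))
  convention <- match.arg(convention)
  check_nonneg(workup_cost_per_event, "workup_cost_per_event")
  arm_id <- attr(trace, "arm")
  core <- accrue_core(trace, arm_id, attr(trace, "battery_cycles"),
                      clin, costs, workup_cost_per_event, convention)
  stop_if(any(!is.finite(core$totals_discounted)) ||
            any(core$totals_discounted < 0),
          "non-finite or negative cost stream")
  structure(
    list(arm = arm_id,
         convention = convention,
         workup_cost_per_event = workup_cost_per_event,
         cycle_undiscounted = core$cycle_undiscounted,
         cycle_discounted = core$cycle_discounted,
         discount_factors = core$df,
         explant_survivors = core$explant_survivors,
         totals_undiscounted = core$totals_undiscounted,
         totals_discounted = core$totals_discounted,
         total_undiscounted = sum(core$totals_undiscounted),
         total_discounted = sum(core$totals_discounted)),
    class = "cost_ledger")
}

#' @export
print.cost_ledger <- function(x, ...) {
  cat(sprintf("Cost ledger, %s arm (%s discounting):\n", x$arm, x$convention))
  for (comp in COST_COMPONENTS)
    cat(sprintf("  %-18s %12.0f EUR (undiscounted %12.0f)\n", comp,
                x$totals_discounted[comp], x$totals_undiscounted[comp]))
  cat(sprintf("  %-18s %12.0f EUR (undiscounted %12.0f)\n", "total",
              x$total_discounted, x$total_undiscounted))
  invisible(x)
}

#' Compare the two arms' cost ledgers
#'
#' @param ilr,cdp `cost_ledger`s for the ILR and CDP arms, built from the
#'   same parameter set and horizon.
#' @param cohort_size patients per arm.
#' @return list with `ilr_total`, `cdp_total` (discounted EUR), `savings`
#'   (CDP minus ILR), `pct_reduction` (percent of the CDP total) and
#'   `per_patient_savings`.
#' @export
compare_costs <- function(ilr, cdp, cohort_size) {
  stopifnot(inherits(ilr, "cost_ledger"), inherits(cdp, "cost_ledger"))
  savings <- cdp$total_discounted - ilr$total_discounted
  list(ilr_total = ilr$total_discounted,
       cdp_total = cdp$total_discounted,
       savings = savings,
       pct_reduction = if (cdp$total_discounted > 0)
         100 * savings / cdp$total_discounted else NA_real_,
       per_patient_savings = savings / cohort_size)
}

#' Range of the average all-in cost of a syncope event across scenarios
#'
#' For each workup scenario, the canonical workup total plus the expected
#' trauma cost per event, rounded to the nearest 10 EUR; returns the
#' minimum and maximum over scenarios.
#'
#' @param profiles list of [scenario_profile()]s.
#' @param trauma_cost expected trauma cost per syncope event, EUR.
#' @return numeric vector `c(min, max)`, EUR.
#' @examples
#' average_event_cost_range(base_scenarios(), 1687.57) # 1760 to 2800
#' @export
average_event_cost_range <- function(profiles = base_scenarios(),
                                     trauma_cost = cost_parameters()$trauma_cost_per_event) {
  stop_if(length(profiles) < 1, "at least one scenario profile is required")
  per_event <- vapply(profiles,
                      function(p) canonical_workup_cost(p) + trauma_cost,
                      numeric(1))
  rounded <- round_half_up(per_event / 10) * 10
  c(min(rounded), max(rounded))
}

#' Export a cost ledger as a delimited cycle-by-component table
#'
#' @param ledger a `cost_ledger`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_ledger_csv <- function(ledger, path) {
  stopifnot(inherits(ledger, "cost_ledger"))
  n <- nrow(ledger$cycle_discounted)
  out <- data.frame(cycle = rep(0:(n - 1), times = length(COST_COMPONENTS)),
                    component = rep(COST_COMPONENTS, each = n),
                    undiscounted = sprintf("%.6f", as.vector(ledger$cycle_undiscounted)),
                    discounted = sprintf("%.6f", as.vector(ledger$cycle_discounted)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
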
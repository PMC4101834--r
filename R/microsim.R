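# Individual-level microsimulation with the exact statistical structure the
# cohort model assumes. The cohort recursion is the expectation of this
# process: per cycle, an undiagnosed-alive patient has a syncope event with
# probability sigma_c, a diagnosis with probability delta_t given the event,
# an injury with probability p_injury given the event, and dies with
# marginal probability q_c. Under the simultaneous competing-risk
# convention, diagnosis and death exits are mutually exclusive with
# additive marginals (U * sigma_c * delta + U * q_c patients exit), so
# death is applied to the not-diagnosed with conditional probability
# q_c / (1 - sigma_c * delta).

#' Simulate individual patient histories
#'
#' Monte-Carlo realisation of the cohort model's transition structure,
#' patient by patient; used as the statistical oracle for the expected
#' counts and costs of [run_cohort()] and [accrue_costs()].
#'
#' @param clin a [clinical_parameters()].
#' @param arm `"ILR"`, `"CDP"`, or an [arm_spec()].
#' @param lt a [life_table()].
#' @param n number of simulated patients.
#' @param seed RNG seed; `NULL` continues the session RNG stream.
#' @param horizon_years simulated horizon.
#' @param rate_conversion,event_order as in [run_cohort()].
#' @param keep_history also record per-cycle event flags for every patient
#'   (memory-heavy; intended for small `n`).
#' @return An object of class `patient_histories`: `patients`
#'   (`data.frame`: `id`, `exit_cycle`, `exit_reason` in
#'   diagnosed/died/horizon, `episodes`, `injuries`), `cycles` (per-cycle
#'   aggregates: `at_risk`, `episodes`, `injuries`, `new_diagnosed`,
#'   `new_dead`) and, with `keep_history`, `history` (long format:
#'   `patient`, `cycle`, `syncope`, `injury`, `diagnosis`, `death`).
#' @examples
#' ph <- simulate_patients(clinical_parameters(horizon_years = 3), "ILR",
#'                         default_life_table(), n = 500, seed = 1)
#' table(ph$patients$exit_reason)
#' @export
simulate_patients <- function(clin, arm = c("ILR", "CDP"),
                              lt = default_life_table(), n, seed = NULL,
                              horizon_years = clin$horizon_years,
                              rate_conversion = c("linear", "exponential"),
                              event_order = c("simultaneous", "death-first"),
                              keep_history = FALSE) {
  stopifnot(inherits(clin, "clinical_parameters"), inherits(lt, "life_table"))
  stop_if(n < 1, "'n' must be at least 1")
  event_order <- match.arg(event_order)
  if (!inherits(arm, "arm_spec")) arm <- arm_spec(match.arg(arm), clin)
  if (!is.null(seed)) set.seed(seed)
  n_cycles <- round(horizon_years / clin$cycle_length_years)
  ci <- cycle_inputs(clin, arm, lt, n_cycles, rate_conversion)
  sc <- ci$sigma_c
  p_inj <- clin$injury_prob_per_event

  active <- rep(TRUE, n)
  exit_cycle <- rep(NA_integer_, n)
  exit_reason <- rep(NA_character_, n)
  episodes <- integer(n); injuries <- integer(n)
  agg <- matrix(0, nrow = n_cycles, ncol = 5,
                dimnames = list(NULL, c("at_risk", "episodes", "injuries",
                                        "new_diagnosed", "new_dead")))
  hist_rows <- if (keep_history) vector("list", n_cycles)

  for (t in seq_len(n_cycles)) {
    idx <- which(active)
    m <- length(idx)
    agg[t, "at_risk"] <- m
    if (m == 0) next
    dl <- ci$delta[t]; qc <- ci$q_c[t]
    # fixed draw order per cycle: syncope, diagnosis, death, injury
    u_syn <- stats::runif(m); u_diag <- stats::runif(m)
    u_die <- stats::runif(m); u_inj <- stats::runif(m)
    if (event_order == "simultaneous") {
      syn <- u_syn < sc
      diag <- syn & (u_diag < dl)
      q_cond <- qc / (1 - sc * dl)
      stop_if(q_cond > 1,
              "per-cycle diagnosis + death probability exceeds 1")
      die <- !diag & (u_die < q_cond)
    } else {
      die <- u_die < qc
      syn <- !die & (u_syn < sc)
      diag <- syn & (u_diag < dl)
    }
    inj <- syn & (u_inj < p_inj)
    episodes[idx] <- episodes[idx] + syn
    injuries[idx] <- injuries[idx] + inj
    agg[t, "episodes"] <- sum(syn)
    agg[t, "injuries"] <- sum(inj)
    agg[t, "new_diagnosed"] <- sum(diag)
    agg[t, "new_dead"] <- sum(die)
    out <- diag | die
    exit_cycle[idx[out]] <- t - 1L
    exit_reason[idx[diag]] <- "diagnosed"
    exit_reason[idx[die]] <- "died"
    active[idx[out]] <- FALSE
    if (keep_history && any(syn | out))
      hist_rows[[t]] <- data.frame(patient = idx[syn | out], cycle = t - 1L,
                                   syncope = syn[syn | out],
                                   injury = inj[syn | out],
                                   diagnosis = diag[syn | out],
                                   death = die[syn | out])
  }
  exit_reason[active] <- "horizon"
  structure(
    list(patients = data.frame(id = seq_len(n), exit_cycle = exit_cycle,
                               exit_reason = exit_reason,
                               episodes = episodes, injuries = injuries),
         cycles = data.frame(cycle = ci$t, agg),
         history = if (keep_history)
           do.call(rbind, hist_rows[!vapply(hist_rows, is.null, logical(1))]),
         n = n, arm = arm$arm_id, battery_cycles = arm$battery_cycles,
         clinical = clin, event_order = event_order),
    class = "patient_histories")
}

#' Summarise simulated patient histories
#'
#' @param ph a `patient_histories` object.
#' @return list with `counts` (diagnosed/died/alive-undiagnosed, episodes,
#'   injuries) and `diagnosed_by_year` (cumulative diagnoses by model
#'   year).
#' @export
summarize_patients <- function(ph) {
  stopifnot(inherits(ph, "patient_histories"))
  p <- ph$patients
  per_year <- round(1 / ph$clinical$cycle_length_years)
  cum_diag <- cumsum(ph$cycles$new_diagnosed)
  yr_idx <- seq_len(nrow(ph$cycles) %/% per_year) * per_year
  list(counts = c(diagnosed = sum(p$exit_reason == "diagnosed"),
                  died = sum(p$exit_reason == "died"),
                  undiagnosed_alive = sum(p$exit_reason == "horizon"),
                  episodes = sum(p$episodes),
                  injuries = sum(p$injuries)),
       diagnosed_by_year = stats::setNames(cum_diag[yr_idx],
                                           seq_along(yr_idx)))
}

#' Per-patient cost accounting over simulated histories
#'
#' Applies the same booking rules as [accrue_costs()] to the empirical
#' per-cycle counts of a microsimulation (acquisition and implantation at
#' entry, follow-up per undiagnosed-alive patient-cycle during battery
#' life, explantation at diagnosis or battery expiry and never on death,
#' trauma per episode, workup per episode in the applicable cycles). As the
#' number of simulated patients grows, the per-patient total converges to
#' the cohort ledger's per-patient total.
#'
#' @param ph a `patient_histories` object.
#' @param costs a [cost_parameters()].
#' @param workup_cost_per_event per-event diagnostic cost, EUR.
#' @param convention discounting convention, see [discount_factor()].
#' @return list with `totals_discounted` per component, `total_discounted`
#'   and `per_patient` (discounted EUR).
#' @export
microsim_costs <- function(ph, costs = cost_parameters(),
                           workup_cost_per_event,
                           convention = c("per-cycle", "annual")) {
  stopifnot(inherits(ph, "patient_histories"))
  convention <- match.arg(convention)
  cy <- ph$cycles
  n_cy <- nrow(cy)
  final_at_risk <- cy$at_risk[n_cy] - cy$new_diagnosed[n_cy] - cy$new_dead[n_cy]
  trace <- list(cycle = cy$cycle, undiagnosed = cy$at_risk,
                episodes = cy$episodes, new_diagnosed = cy$new_diagnosed,
                undiagnosed_end = c(cy$at_risk[-1], final_at_risk))
  clin_n <- ph$clinical
  clin_n$cohort_size <- ph$n
  core <- accrue_core(trace, ph$arm, ph$battery_cycles, clin_n, costs,
                      workup_cost_per_event, convention)
  list(totals_discounted = core$totals_discounted,
       total_discounted = sum(core$totals_discounted),
       per_patient = sum(core$totals_discounted) / ph$n)
}

#' Export simulated histories as long-format delimited text
#'
#' Requires a simulation run with `keep_history = TRUE`.
#'
#' @param ph a `patient_histories` object.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_patient_histories <- function(ph, path) {
  stopifnot(inherits(ph, "patient_histories"))
  stop_if(is.null(ph$history),
          "simulation was run without keep_history = TRUE")
  utils::write.table(ph$history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Random valid parameter sets for property testing
#'
#' Draws a [clinical_parameters()] / [cost_parameters()] pair uniformly
#' from a broad region of the supported space, guaranteeing every type
#' invariant (probabilities in \[0, 1\], at most one syncope event per
#' cycle, non-negative costs).
#'
#' @param seed RNG seed; `NULL` continues the session stream.
#' @param horizon_years horizon for the drawn clinical set.
#' @return list with elements `clinical` and `costs`.
#' @export
random_parameter_set <- function(seed = NULL, horizon_years = 3) {
  if (!is.null(seed)) set.seed(seed)
  r <- function(lo, hi) stats::runif(1, lo, hi)
  clin <- clinical_parameters(
    start_age = r(45, 70),
    cohort_size = round(r(50, 500)),
    annual_syncope_rate = r(0, 3.5),
    diagnosis_prob_ilr = r(0, 1),
    diagnosis_prob_cdp = r(0, 1),
    battery_life_years = 3,
    mortality_hazard_ratio = r(0.5, 3),
    injury_prob_per_event = r(0, 1),
    severe_injury_fraction = r(0, 1),
    horizon_years = horizon_years)
  costs <- cost_parameters(
    device_acquisition = r(0, 5000),
    implantation = r(0, 500),
    followup_visit = r(0, 100),
    minor_trauma_tariff = r(0, 5000),
    major_trauma_tariff = r(0, 10000),
    trauma_cost_per_event = r(0, 3000),
    annual_discount_rate = r(0, 0.12))
  list(clinical = clin, costs = costs)
}
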
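#' Clinical parameters of the syncope diagnosis model
#'
#' Bundles every transition-driving quantity of the three-state cohort model:
#' the quarterly syncope process, the per-event diagnostic yields of the two
#' arms, the mortality adjustment, and the cohort/horizon geometry.
#'
#' @param start_age cohort age at model entry, years.
#' @param cohort_size number of patients entering each arm.
#' @param annual_syncope_rate expected syncope events per undiagnosed
#'   person-year (sigma).
#' @param diagnosis_prob_ilr probability that a syncope event yields a
#'   diagnosis in the ILR arm while the device battery lasts (delta_ILR).
#' @param diagnosis_prob_cdp per-event diagnostic yield of the conventional
#'   pathway (delta_CDP); also the ILR-arm yield after battery exhaustion.
#' @param battery_life_years ILR battery life, years; the high yield applies
#'   only to cycles within this window.
#' @param mortality_hazard_ratio multiplier on the life-table annual death
#'   probability, reflecting the excess all-cause mortality observed in
#'   unexplained syncope.
#' @param injury_prob_per_event probability that a syncope event causes an
#'   injury/trauma.
#' @param severe_injury_fraction fraction of injuries that are severe (major
#'   trauma tariff applies).
#' @param horizon_years model horizon, years (3 for the battery-life view,
#'   30 for the lifetime view); any positive multiple of the cycle length is
#'   accepted.
#' @param cycle_length_years model cycle length, years (0.25: quarterly).
#'
#' @return An object of class `clinical_parameters` (a validated list).
#' @examples
#' clinical_parameters() # base case: 197 patients starting at age 61
#' @export
clinical_parameters <- function(start_age = 61,
                                cohort_size = 197,
                                annual_syncope_rate = 0.6,
                                diagnosis_prob_ilr = 0.628,
                                diagnosis_prob_cdp = 0.125,
                                battery_life_years = 3,
                                mortality_hazard_ratio = 1.32,
                                injury_prob_per_event = 0.522,
                                severe_injury_fraction = 0.1616,
                                horizon_years = 30,
                                cycle_length_years = 0.25) {
  check_nonneg(start_age, "start_age")
  check_nonneg(cohort_size, "cohort_size")
  stop_if(cohort_size < 1, "'cohort_size' must be at least 1")
  check_nonneg(annual_syncope_rate, "annual_syncope_rate")
  check_prob(diagnosis_prob_ilr, "diagnosis_prob_ilr")
  check_prob(diagnosis_prob_cdp, "diagnosis_prob_cdp")
  check_nonneg(battery_life_years, "battery_life_years")
  check_nonneg(mortality_hazard_ratio, "mortality_hazard_ratio")
  check_prob(injury_prob_per_event, "injury_prob_per_event")
  check_prob(severe_injury_fraction, "severe_injury_fraction")
  check_nonneg(horizon_years, "horizon_years")
  stop_if(cycle_length_years <= 0, "'cycle_length_years' must be positive")
  stop_if(annual_syncope_rate * cycle_length_years > 1,
          "annual_syncope_rate x cycle_length_years exceeds 1: ",
          "the per-cycle event probability would not be a valid probability")
  stop_if(abs(horizon_years / cycle_length_years -
                round(horizon_years / cycle_length_years)) > 1e-9,
          "'horizon_years' must be a multiple of 'cycle_length_years'")
  structure(
    list(start_age = start_age,
         cohort_size = cohort_size,
         annual_syncope_rate = annual_syncope_rate,
         diagnosis_prob_ilr = diagnosis_prob_ilr,
         diagnosis_prob_cdp = diagnosis_prob_cdp,
         battery_life_years = battery_life_years,
         mortality_hazard_ratio = mortality_hazard_ratio,
         injury_prob_per_event = injury_prob_per_event,
         severe_injury_fraction = severe_injury_fraction,
         horizon_years = horizon_years,
         cycle_length_years = cycle_length_years),
    class = "clinical_parameters")
}

#' @export
print.clinical_parameters <- function(x, ...) {
  cat("Clinical parameters (", x$cohort_size, " patients, start age ",
      x$start_age, ")\n", sep = "")
  cat(sprintf("  syncope rate %.3g/yr; yield ILR %.3f / CDP %.3f; battery %g y\n",
              x$annual_syncope_rate, x$diagnosis_prob_ilr,
              x$diagnosis_prob_cdp, x$battery_life_years))
  cat(sprintf("  mortality HR %.2f; injury prob %.3f (severe %.4f)\n",
              x$mortality_hazard_ratio, x$injury_prob_per_event,
              x$severe_injury_fraction))
  cat(sprintf("  horizon %g y, cycle %g y\n", x$horizon_years,
              x$cycle_length_years))
  invisible(x)
}

#' Unit costs and the discounting rate
#'
#' All device and episode unit costs, in euro. `trauma_cost_per_event` is the
#' canonical per-episode injury/trauma cost applied by the engine; it is a
#' probability-weighted blend of the two trauma tariffs (see
#' [expected_trauma_cost()]), carried here as a direct input because the
#' published weighted value does not exactly equal either the rounded or
#' unrounded recomputation.
#'
#' @param device_acquisition ILR purchase price, EUR.
#' @param implantation implantation procedure tariff, EUR.
#' @param explantation explantation tariff, EUR; by convention equal to the
#'   implantation tariff.
#' @param followup_visit device-check consultation tariff, EUR.
#' @param followup_visits_per_year scheduled device checks per year.
#' @param minor_trauma_tariff DRG tariff for minor injury/trauma, EUR.
#' @param major_trauma_tariff DRG tariff for major injury/trauma, EUR.
#' @param trauma_cost_per_event expected injury/trauma cost booked per
#'   syncope episode, EUR.
#' @param annual_discount_rate annual discount rate applied to all cost
#'   streams (0.05 = 5 percent).
#'
#' @return An object of class `cost_parameters`.
#' @export
cost_parameters <- function(device_acquisition = 2000,
                            implantation = 127.80,
                            explantation = implantation,
                            followup_visit = 31,
                            followup_visits_per_year = 2,
                            minor_trauma_tariff = 2684.83,
                            major_trauma_tariff = 6058.25,
                            trauma_cost_per_event = 1687.57,
                            annual_discount_rate = 0.05) {
  for (nm in c("device_acquisition", "implantation", "explantation",
               "followup_visit", "followup_visits_per_year",
               "minor_trauma_tariff", "major_trauma_tariff",
               "trauma_cost_per_event"))
    check_nonneg(get(nm), nm)
  check_nonneg(annual_discount_rate, "annual_discount_rate")
  stop_if(annual_discount_rate >= 1, "'annual_discount_rate' must be < 1")
  structure(
    list(device_acquisition = device_acquisition,
         implantation = implantation,
         explantation = explantation,
         followup_visit = followup_visit,
         followup_visits_per_year = followup_visits_per_year,
         minor_trauma_tariff = minor_trauma_tariff,
         major_trauma_tariff = major_trauma_tariff,
         trauma_cost_per_event = trauma_cost_per_event,
         annual_discount_rate = annual_discount_rate),
    class = "cost_parameters")
}

#' @export
print.cost_parameters <- function(x, ...) {
  cat("Cost parameters (EUR):\n")
  cat(sprintf("  device %0.2f + implantation %0.2f, explantation %0.2f\n",
              x$device_acquisition, x$implantation, x$explantation))
  cat(sprintf("  follow-up %0.2f x %g/yr; trauma/event %0.2f (tariffs %0.2f / %0.2f)\n",
              x$followup_visit, x$followup_visits_per_year,
              x$trauma_cost_per_event, x$minor_trauma_tariff,
              x$major_trauma_tariff))
  cat(sprintf("  discount rate %.1f%%/yr\n", 100 * x$annual_discount_rate))
  invisible(x)
}

#' National admission counts used to size the model cohort
#'
#' @param annual_syncope_admissions syncope hospital admissions per year in
#'   the health system (inpatient plus ambulatory).
#' @param unexplained_recurrent_fraction fraction of those admissions due to
#'   unexplained and recurrent syncope.
#' @return An object of class `population_source`.
#' @export
population_source <- function(annual_syncope_admissions = 1010,
                              unexplained_recurrent_fraction = 0.195) {
  check_nonneg(annual_syncope_admissions, "annual_syncope_admissions")
  check_prob(unexplained_recurrent_fraction, "unexplained_recurrent_fraction")
  structure(list(annual_syncope_admissions = annual_syncope_admissions,
                 unexplained_recurrent_fraction = unexplained_recurrent_fraction),
            class = "population_source")
}

#' Derive the modelled cohort size from national admission counts
#'
#' Multiplies the annual syncope admissions by the unexplained-recurrent
#' fraction and rounds half away from zero (1010 x 0.195 = 196.95 -> 197).
#'
#' @param src a [population_source()].
#' @return integer number of patients.
#' @examples
#' derive_cohort_size(population_source(1010, 0.195)) # 197
#' @export
derive_cohort_size <- function(src = population_source()) {
  stopifnot(inherits(src, "population_source"))
  as.integer(round_half_up(src$annual_syncope_admissions *
                             src$unexplained_recurrent_fraction))
}

#' Expected injury/trauma cost per syncope episode
#'
#' Probability-weighted blend of the minor and major trauma tariffs:
#' `minor * p_injury * (1 - severe_frac) + major * p_injury * severe_frac`.
#' This recomputation is provided for transparency; the engine's base case
#' uses the canonical `trauma_cost_per_event` carried in
#' [cost_parameters()], which differs from the recomputed value by well
#' under one euro per episode.
#'
#' @param minor minor-trauma tariff, EUR.
#' @param major major-trauma tariff, EUR.
#' @param p_injury probability of injury per syncope event.
#' @param severe_frac fraction of injuries that are severe.
#' @return expected cost, EUR.
#' @examples
#' expected_trauma_cost(2684.83, 6058.25, 0.522, 0.1616)
#' @export
expected_trauma_cost <- function(minor, major, p_injury, severe_frac) {
  check_nonneg(minor, "minor"); check_nonneg(major, "major")
  check_prob(p_injury, "p_injury"); check_prob(severe_frac, "severe_frac")
  minor * p_injury * (1 - severe_frac) + major * p_injury * severe_frac
}
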
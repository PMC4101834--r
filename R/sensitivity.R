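# One-way (tornado), threshold and probabilistic sensitivity analysis.
# All analyses are driven through evaluate_savings(), which runs both arms
# over the lifetime horizon for a (possibly perturbed) input set.

CLINICAL_FIELDS <- c("start_age", "cohort_size", "annual_syncope_rate",
                     "diagnosis_prob_ilr", "diagnosis_prob_cdp",
                     "battery_life_years", "mortality_hazard_ratio",
                     "injury_prob_per_event", "severe_injury_fraction",
                     "horizon_years", "cycle_length_years")
COST_FIELDS <- c("device_acquisition", "implantation", "explantation",
                 "followup_visit", "followup_visits_per_year",
                 "minor_trauma_tariff", "major_trauma_tariff",
                 "trauma_cost_per_event", "annual_discount_rate")
# Varying any of these invalidates the canonical per-event trauma cost, so
# it is rederived from the tariffs (see expected_trauma_cost)
TRAUMA_DRIVERS <- c("minor_trauma_tariff", "major_trauma_tariff",
                    "injury_prob_per_event", "severe_injury_fraction")

#' Read a named parameter from a model-inputs object
#'
#' Parameters are addressed by their field name in [clinical_parameters()]
#' or [cost_parameters()], or as `"workup_cost_per_event"`.
#'
#' @param inputs a [model_inputs()].
#' @param parameter parameter name.
#' @return the current (base) value.
#' @export
get_param <- function(inputs, parameter) {
  stopifnot(inherits(inputs, "model_inputs"))
  if (parameter %in% CLINICAL_FIELDS) inputs$clinical[[parameter]]
  else if (parameter %in% COST_FIELDS) inputs$costs[[parameter]]
  else if (parameter == "workup_cost_per_event") inputs$workup_cost_per_event
  else stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE)
}

#' Return a copy of the inputs with one parameter changed
#'
#' When a trauma-tariff driver (`minor_trauma_tariff`,
#' `major_trauma_tariff`, `injury_prob_per_event`,
#' `severe_injury_fraction`) is changed, the per-event trauma cost is
#' rederived from the tariffs via [expected_trauma_cost()]; otherwise the
#' canonical per-event value is left untouched.
#'
#' @inheritParams get_param
#' @param value new value.
#' @return modified [model_inputs()].
#' @export
set_param <- function(inputs, parameter, value) {
  stopifnot(inherits(inputs, "model_inputs"))
  if (parameter %in% CLINICAL_FIELDS) {
    cl <- unclass(inputs$clinical); cl[[parameter]] <- value
    inputs$clinical <- do.call(clinical_parameters, cl)
  } else if (parameter %in% COST_FIELDS) {
    co <- unclass(inputs$costs); co[[parameter]] <- value
    inputs$costs <- do.call(cost_parameters, co)
  } else if (parameter == "workup_cost_per_event") {
    check_nonneg(value, parameter)
    inputs$workup_cost_per_event <- value
  } else stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE)
  if (parameter %in% TRAUMA_DRIVERS) {
    inputs$costs$trauma_cost_per_event <- expected_trauma_cost(
      inputs$costs$minor_trauma_tariff, inputs$costs$major_trauma_tariff,
      inputs$clinical$injury_prob_per_event,
      inputs$clinical$severe_injury_fraction)
  }
  inputs
}

# Fast both-arm evaluation without building data.frames (hot path for PSA).
savings_core <- function(inputs, horizon_years) {
  clin <- inputs$clinical
  n_cycles <- round(horizon_years / clin$cycle_length_years)
  totals <- c(ILR = NA_real_, CDP = NA_real_)
  for (arm_id in c("ILR", "CDP")) {
    arm <- arm_spec(arm_id, clin)
    ci <- cycle_inputs(clin, arm, inputs$life_table, n_cycles,
                       inputs$rate_conversion)
    core <- run_core(clin$cohort_size, ci$sigma_c, ci$delta, ci$q_c,
                     clin$injury_prob_per_event, inputs$event_order)
    trace <- list(cycle = ci$t, undiagnosed = core$undiagnosed,
                  episodes = core$episodes,
                  new_diagnosed = core$new_diagnosed,
                  undiagnosed_end = c(core$undiagnosed[-1],
                                      core$undiagnosed_end))
    acc <- accrue_core(trace, arm_id, arm$battery_cycles, clin, inputs$costs,
                       inputs$workup_cost_per_event,
                       inputs$discount_convention)
    totals[arm_id] <- sum(acc$totals_discounted)
  }
  savings <- totals[["CDP"]] - totals[["ILR"]]
  list(ilr_total = totals[["ILR"]], cdp_total = totals[["CDP"]],
       savings = savings,
       pct_reduction = if (totals[["CDP"]] > 0)
         100 * savings / totals[["CDP"]] else NA_real_,
       per_patient_savings = savings / clin$cohort_size)
}

#' Run both arms and compare their discounted totals
#'
#' Convenience wrapper running the cohort model for the ILR and CDP arms
#' under the given inputs and returning the cost comparison.
#'
#' @param inputs a [model_inputs()].
#' @param horizon_years model horizon; defaults to the inputs' clinical
#'   horizon (30 years for the lifetime view).
#' @return list as from [compare_costs()]: `ilr_total`, `cdp_total`,
#'   `savings`, `pct_reduction`, `per_patient_savings`.
#' @export
evaluate_savings <- function(inputs,
                             horizon_years = inputs$clinical$horizon_years) {
  stopifnot(inherits(inputs, "model_inputs"))
  savings_core(inputs, horizon_years)
}

#' One-way sensitivity of the lifetime savings to a single parameter
#'
#' Runs the full lifetime model with the parameter at its lower and upper
#' bound (everything else at base) and records the per-patient savings at
#' each.
#'
#' @inheritParams get_param
#' @param low,high bounds; must bracket the base value.
#' @return one-row `data.frame`: `parameter`, `base`, `low`, `high`,
#'   `savings_low`, `savings_high` (per-patient EUR), `width`.
#' @export
one_way <- function(inputs, parameter, low, high) {
  base <- get_param(inputs, parameter)
  stop_if(!is.numeric(low) || !is.numeric(high) || low > high,
          "'low' must not exceed 'high'")
  stop_if(base < low - 1e-9 || base > high + 1e-9,
          sprintf("bounds [%g, %g] do not bracket the base value %g of '%s'",
                  low, high, base, parameter))
  s_low <- evaluate_savings(set_param(inputs, parameter, low))$per_patient_savings
  s_high <- evaluate_savings(set_param(inputs, parameter, high))$per_patient_savings
  data.frame(parameter = parameter, base = base, low = low, high = high,
             savings_low = s_low, savings_high = s_high,
             width = abs(s_high - s_low))
}

halve_double <- function(x) c(x / 2, x * 2)

#' Default one-way ranges for the tornado analysis
#'
#' Bounds follow the published convention: halving and doubling the base
#' value, except where an alternative source fixes a bound (ILR yield upper
#' bound 0.78 from the PICTURE population, syncope rate upper bound 0.81
#' from the early EaSyAS report, injury probability explored down to 0.25)
#' or where the support caps it (probabilities at 1).
#'
#' @param inputs a [model_inputs()].
#' @return `data.frame(parameter, low, high)`.
#' @export
default_tornado_ranges <- function(inputs = base_case_inputs()) {
  hd <- function(p) {
    b <- halve_double(get_param(inputs, p))
    data.frame(parameter = p, low = b[1], high = b[2])
  }
  rbind(
    data.frame(parameter = "diagnosis_prob_ilr",
               low = get_param(inputs, "diagnosis_prob_ilr") / 2, high = 0.78),
    data.frame(parameter = "annual_syncope_rate",
               low = get_param(inputs, "annual_syncope_rate") / 2, high = 0.81),
    data.frame(parameter = "injury_prob_per_event", low = 0.25, high = 1),
    within(hd("diagnosis_prob_cdp"), high <- pmin(high, 1)),
    within(hd("severe_injury_fraction"), high <- pmin(high, 1)),
    hd("mortality_hazard_ratio"),
    hd("minor_trauma_tariff"),
    hd("major_trauma_tariff"),
    hd("workup_cost_per_event"),
    hd("device_acquisition"),
    hd("implantation"),
    hd("followup_visit"),
    hd("annual_discount_rate"))
}

#' Tornado (one-way) sensitivity analysis
#'
#' Evaluates [one_way()] for every parameter range and orders the entries
#' by descending bar width (ties broken alphabetically by parameter name),
#' the order in which a tornado diagram stacks its bars.
#'
#' @param inputs a [model_inputs()].
#' @param ranges `data.frame(parameter, low, high)`; defaults to the
#'   inputs' `sensitivity_ranges` or [default_tornado_ranges()].
#' @return `data.frame` of [one_way()] rows, widest first.
#' @export
tornado <- function(inputs, ranges = NULL) {
  if (is.null(ranges)) ranges <- inputs$sensitivity_ranges
  if (is.null(ranges)) ranges <- default_tornado_ranges(inputs)
  stop_if(nrow(ranges) < 1, "at least one range is required")
  rows <- lapply(seq_len(nrow(ranges)), function(i)
    one_way(inputs, ranges$parameter[i], ranges$low[i], ranges$high[i]))
  out <- do.call(rbind, rows)
  out <- out[order(-out$width, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Threshold sweep over the ILR diagnostic yield
#'
#' Evaluates the lifetime cohort savings over a grid of ILR per-event
#' diagnostic yields (everything else at base) and locates the break-even
#' yield by linear interpolation between the bracketing grid points. The
#' incremental yield over the conventional pathway at break-even is
#' reported alongside, the two quantities in which the published
#' cost-saving condition is stated.
#'
#' @param inputs a [model_inputs()].
#' @param grid yields to evaluate, each in \[0, 1\].
#' @return list with `curve` (`data.frame(delta_ilr, savings,
#'   per_patient_savings)`), `break_even` (yield at zero savings, `NA` if
#'   no sign change on the grid) and `break_even_increment` (break-even
#'   yield minus the CDP yield).
#' @export
threshold_sweep <- function(inputs, grid = seq(0.1, 0.78, by = 0.01)) {
  stop_if(any(grid < 0 | grid > 1), "grid values must be probabilities")
  grid <- sort(grid)
  sav <- vapply(grid, function(d)
    evaluate_savings(set_param(inputs, "diagnosis_prob_ilr", d))$savings,
    numeric(1))
  be <- NA_real_
  sgn <- sign(sav)
  flip <- which(sgn[-1] > 0 & sgn[-length(sgn)] < 0)
  if (length(flip) > 0) {
    i <- flip[1]
    be <- grid[i] + (0 - sav[i]) * (grid[i + 1] - grid[i]) / (sav[i + 1] - sav[i])
  }
  list(curve = data.frame(delta_ilr = grid, savings = sav,
                          per_patient_savings = sav / inputs$clinical$cohort_size),
       break_even = be,
       break_even_increment = be - inputs$clinical$diagnosis_prob_cdp)
}

#' Uncertainty specification for one parameter
#'
#' Families follow the standard assignment in probabilistic sensitivity
#' analysis: lognormal for ratios and rates, gamma for costs, beta for
#' probabilities, degenerate (point mass) to switch a parameter off. The
#' distribution is parameterised from the base value plus one dispersion
#' descriptor:
#' * lognormal: median at the base value, `sdlog` chosen so the 95 percent
#'   central interval is `[base/interval_factor, base*interval_factor]`;
#' * gamma: mean at the base value, shape solved so the ratio of the 97.5
#'   to the 2.5 percentile equals `interval_factor^2`;
#' * beta: mean at the base value with the given effective sample size
#'   (`alpha + beta = ess`).
#'
#' @param parameter parameter name (see [get_param()]).
#' @param family `"lognormal"`, `"gamma"`, `"beta"` or `"degenerate"`.
#' @param mean base value.
#' @param interval_factor half-width factor of the 95 percent interval for
#'   lognormal/gamma (default 2: interval `[base/2, 2*base]`).
#' @param ess effective sample size for beta (default 100).
#' @return An object of class `uncertainty_spec` carrying the resolved
#'   distribution parameters.
#' @export
uncertainty_spec <- function(parameter,
                             family = c("lognormal", "gamma", "beta",
                                        "degenerate"),
                             mean, interval_factor = 2, ess = 100) {
  family <- match.arg(family)
  check_nonneg(mean, "mean")
  stop_if(family == "beta" && mean > 1,
          "beta family is only admissible for probabilities")
  pars <- switch(family,
    degenerate = list(value = mean),
    lognormal = {
      stop_if(mean <= 0, "lognormal requires a positive base value")
      list(meanlog = log(mean),
           sdlog = log(interval_factor) / stats::qnorm(0.975))
    },
    gamma = {
      if (mean == 0) list(value = 0)
      else {
        ratio <- interval_factor^2
        shape <- stats::uniroot(function(k)
          stats::qgamma(0.975, k) / stats::qgamma(0.025, k) - ratio,
          c(0.5, 500), tol = 1e-10)$root
        list(shape = shape, rate = shape / mean)
      }
    },
    beta = {
      if (mean <= 0 || mean >= 1) list(value = mean)
      else list(alpha = mean * ess, beta = (1 - mean) * ess)
    })
  structure(list(parameter = parameter, family = family, mean = mean,
                 pars = pars),
            class = "uncertainty_spec")
}

#' Default PSA distribution set
#'
#' One [uncertainty_spec()] per uncertain parameter, in the fixed draw
#' order used by [draw_parameters()]: hazard ratio and syncope rate
#' (lognormal); the two diagnostic yields, injury probability and severe
#' fraction (beta); workup cost, trauma tariffs, device, implantation and
#' follow-up costs (gamma). Dispersion defaults: 95 percent interval
#' `[base/2, 2*base]` for lognormal/gamma, effective sample size 100 for
#' beta; both overridable.
#'
#' @param inputs a [model_inputs()].
#' @param interval_factor,ess dispersion defaults, see
#'   [uncertainty_spec()].
#' @return named list of `uncertainty_spec`s.
#' @export
default_psa_specs <- function(inputs = base_case_inputs(),
                              interval_factor = 2, ess = 100) {
  if (!is.null(inputs$psa_settings)) {
    interval_factor <- inputs$psa_settings$interval_factor %||% interval_factor
    ess <- inputs$psa_settings$effective_sample_size %||% ess
  }
  spec <- function(p, fam) uncertainty_spec(p, fam, get_param(inputs, p),
                                            interval_factor, ess)
  specs <- list(
    spec("mortality_hazard_ratio", "lognormal"),
    spec("annual_syncope_rate", "lognormal"),
    spec("diagnosis_prob_ilr", "beta"),
    spec("diagnosis_prob_cdp", "beta"),
    spec("injury_prob_per_event", "beta"),
    spec("severe_injury_fraction", "beta"),
    spec("workup_cost_per_event", "gamma"),
    spec("minor_trauma_tariff", "gamma"),
    spec("major_trauma_tariff", "gamma"),
    spec("device_acquisition", "gamma"),
    spec("implantation", "gamma"),
    spec("followup_visit", "gamma"))
  names(specs) <- vapply(specs, `[[`, character(1), "parameter")
  specs
}

#' Draw parameter sets from uncertainty specifications
#'
#' Independent draws, consumed spec by spec in the order given, from the
#' session RNG (seed it, or use [psa()] which seeds for you). Draws outside
#' the model's admissible support are truncated to it (syncope rate to one
#' event per cycle, probabilities to \[0, 1\]); with the default
#' dispersions truncation is a measure-zero event.
#'
#' @param specs list of [uncertainty_spec()]s.
#' @param n number of draws.
#' @return `data.frame`, one column per parameter, one row per draw.
#' @export
draw_parameters <- function(specs, n = 1) {
  stop_if(n < 1, "'n' must be at least 1")
  cols <- lapply(specs, function(s) {
    x <- switch(s$family,
      degenerate = rep(s$pars$value, n),
      lognormal = stats::rlnorm(n, s$pars$meanlog, s$pars$sdlog),
      gamma = if (!is.null(s$pars$value)) rep(s$pars$value, n)
              else stats::rgamma(n, shape = s$pars$shape, rate = s$pars$rate),
      beta = if (!is.null(s$pars$value)) rep(s$pars$value, n)
             else stats::rbeta(n, s$pars$alpha, s$pars$beta))
    if (s$family == "beta") x <- pmin(1, pmax(0, x))
    x
  })
  names(cols) <- vapply(specs, `[[`, character(1), "parameter")
  as.data.frame(cols, check.names = FALSE)
}

#' Probabilistic sensitivity analysis
#'
#' Samples `n_draws` parameter sets from the uncertainty specifications,
#' runs the lifetime model for each, and summarises the distribution of
#' cohort cost savings (CDP minus ILR). When a draw perturbs a trauma
#' driver, the per-event trauma cost is rederived from the drawn tariffs
#' and probabilities, as in [set_param()].
#'
#' @param inputs a [model_inputs()].
#' @param specs list of [uncertainty_spec()]s; default
#'   [default_psa_specs()].
#' @param n_draws number of Monte-Carlo draws.
#' @param seed RNG seed (one seeded generator drives all draws).
#' @param horizon_years evaluation horizon (lifetime by default).
#' @return An object of class `psa_result`: `n_draws`, `seed`, per-draw
#'   `savings` (cohort EUR), `mean_savings`, `mean_per_patient`,
#'   `fraction_cost_saving`, `quantiles`, `histogram` and the sampled
#'   `draws`.
#' @export
psa <- function(inputs, specs = default_psa_specs(inputs), n_draws = 10000,
                seed = NULL, horizon_years = inputs$clinical$horizon_years) {
  stopifnot(inherits(inputs, "model_inputs"))
  stop_if(n_draws < 1, "'n_draws' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  draws <- draw_parameters(specs, n_draws)
  nms <- names(draws)
  max_rate <- 1 / inputs$clinical$cycle_length_years - 1e-9
  savings <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    inp <- inputs
    cl <- unclass(inp$clinical); co <- unclass(inp$costs)
    for (p in nms) {
      v <- draws[[p]][i]
      if (p == "annual_syncope_rate") v <- min(v, max_rate)
      if (p %in% CLINICAL_FIELDS) cl[[p]] <- v
      else if (p %in% COST_FIELDS) co[[p]] <- v
      else if (p == "workup_cost_per_event") inp$workup_cost_per_event <- v
    }
    if (any(nms %in% TRAUMA_DRIVERS))
      co$trauma_cost_per_event <- expected_trauma_cost(
        co$minor_trauma_tariff, co$major_trauma_tariff,
        cl$injury_prob_per_event, cl$severe_injury_fraction)
    inp$clinical <- structure(cl, class = "clinical_parameters")
    inp$costs <- structure(co, class = "cost_parameters")
    res <- tryCatch(savings_core(inp, horizon_years), error = function(e)
      stop(sprintf("PSA draw %d failed: %s", i, conditionMessage(e)),
           call. = FALSE))
    savings[i] <- res$savings
  }
  structure(
    list(n_draws = n_draws, seed = seed, savings = savings, draws = draws,
         mean_savings = mean(savings),
         mean_per_patient = mean(savings) / inputs$clinical$cohort_size,
         fraction_cost_saving = mean(savings > 0),
         quantiles = stats::quantile(savings,
                                     c(0.025, 0.25, 0.5, 0.75, 0.975)),
         histogram = graphics::hist(savings, breaks = 30, plot = FALSE)),
    class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d draws%s\n", x$n_draws,
              if (!is.null(x$seed)) sprintf(" (seed %s)", x$seed) else ""))
  cat(sprintf("  mean cohort savings %.0f EUR (%.0f EUR per patient)\n",
              x$mean_savings, x$mean_per_patient))
  cat(sprintf("  cost-saving in %.1f%% of draws\n",
              100 * x$fraction_cost_saving))
  invisible(x)
}
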
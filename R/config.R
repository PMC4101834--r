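#' Bundle every model input into a single run configuration
#'
#' A `model_inputs` object carries the clinical and cost parameters, the
#' workup scenarios, the life table, and the three run conventions (rate
#' conversion, within-cycle event order, discounting). The per-event workup
#' cost defaults to the canonical total of the selected base scenario.
#'
#' @param clinical a [clinical_parameters()].
#' @param costs a [cost_parameters()].
#' @param scenarios named list of [scenario_profile()]s.
#' @param base_scenario name of the scenario driving the base case.
#' @param life_table a [life_table()].
#' @param workup_cost_per_event per-event diagnostic cost, EUR; default the
#'   base scenario's canonical total.
#' @param rate_conversion `"linear"` or `"exponential"`, see
#'   [cycle_syncope_prob()].
#' @param event_order `"simultaneous"` or `"death-first"`, see
#'   [run_cohort()].
#' @param discount_convention `"per-cycle"` or `"annual"`, see
#'   [discount_factor()].
#' @param sensitivity_ranges optional `data.frame(parameter, low, high)`
#'   overriding [default_tornado_ranges()].
#' @param psa_settings optional list of PSA settings (`n_draws`,
#'   `effective_sample_size`, `interval_factor`).
#' @return An object of class `model_inputs`.
#' @export
model_inputs <- function(clinical = clinical_parameters(),
                         costs = cost_parameters(),
                         scenarios = base_scenarios(),
                         base_scenario = "Sousa Pedro",
                         life_table = default_life_table(),
                         workup_cost_per_event = NULL,
                         rate_conversion = c("linear", "exponential"),
                         event_order = c("simultaneous", "death-first"),
                         discount_convention = c("per-cycle", "annual"),
                         sensitivity_ranges = NULL,
                         psa_settings = NULL) {
  stopifnot(inherits(clinical, "clinical_parameters"),
            inherits(costs, "cost_parameters"),
            inherits(life_table, "life_table"))
  stop_if(!base_scenario %in% names(scenarios),
          sprintf("base scenario '%s' not among the scenarios", base_scenario))
  if (is.null(workup_cost_per_event))
    workup_cost_per_event <- canonical_workup_cost(scenarios[[base_scenario]])
  structure(
    list(clinical = clinical, costs = costs, scenarios = scenarios,
         base_scenario = base_scenario, life_table = life_table,
         workup_cost_per_event = workup_cost_per_event,
         rate_conversion = match.arg(rate_conversion),
         event_order = match.arg(event_order),
         discount_convention = match.arg(discount_convention),
         sensitivity_ranges = sensitivity_ranges,
         psa_settings = psa_settings),
    class = "model_inputs")
}

#' The base-case run configuration
#'
#' All published base-case values, the bundled synthetic life table, the
#' Sousa Pedro workup scenario, and the default conventions (linear rate
#' conversion, simultaneous competing risks, per-cycle discounting).
#'
#' @return a [model_inputs()] object.
#' @export
base_case_inputs <- function() model_inputs()

#' @export
print.model_inputs <- function(x, ...) {
  cat(sprintf("Model inputs: base scenario '%s' (workup %.2f EUR/event)\n",
              x$base_scenario, x$workup_cost_per_event))
  cat(sprintf("  conventions: %s rate conversion, %s events, %s discounting\n",
              x$rate_conversion, x$event_order, x$discount_convention))
  print(x$clinical); print(x$costs); print(x$life_table)
  invisible(x)
}

scenario_to_list <- function(p) {
  list(name = p$name,
       printed_total = p$printed_total,
       items = lapply(seq_len(nrow(p$items)), function(i)
         list(test = p$items$test[i],
              unit_price = p$items$unit_price[i],
              fraction = p$items$fraction[i])))
}

scenario_from_list <- function(l) {
  items <- if (length(l$items) == 0)
    data.frame(test = character(), unit_price = numeric(), fraction = numeric())
  else
    data.frame(test = vapply(l$items, `[[`, character(1), "test"),
               unit_price = vapply(l$items, `[[`, numeric(1), "unit_price"),
               fraction = vapply(l$items, `[[`, numeric(1), "fraction"))
  scenario_profile(l$name, items, l$printed_total)
}

#' Read / write a model configuration file
#'
#' The configuration is one YAML document with sections `clinical`,
#' `costs`, `scenarios`, `base_scenario`, `life_table_path`, `conventions`,
#' `sensitivity` and `psa`. `life_table_path` is resolved relative to the
#' configuration file; when absent the bundled synthetic table is used.
#' `write_model_config()` emits the same structure, so a configuration
#' round-trips losslessly through read and write.
#'
#' @param path configuration file path.
#' @return `read_model_config()` returns a [model_inputs()];
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  stop_if(!file.exists(path), sprintf("config file '%s' does not exist", path))
  cfg <- yaml::read_yaml(path)
  lt <- if (is.null(cfg$life_table_path)) default_life_table()
  else {
    lt_path <- cfg$life_table_path
    if (!file.exists(lt_path))
      lt_path <- file.path(dirname(path), cfg$life_table_path)
    stop_if(!file.exists(lt_path),
            sprintf("life-table file '%s' does not exist", cfg$life_table_path))
    read_life_table(lt_path)
  }
  scen <- if (is.null(cfg$scenarios)) base_scenarios()
  else {
    s <- lapply(cfg$scenarios, scenario_from_list)
    names(s) <- vapply(s, `[[`, character(1), "name")
    s
  }
  conv <- cfg$conventions
  ranges <- if (!is.null(cfg$sensitivity$ranges))
    do.call(rbind, lapply(cfg$sensitivity$ranges, function(r)
      data.frame(parameter = r$parameter, low = r$low, high = r$high)))
  inp <- model_inputs(
    clinical = do.call(clinical_parameters, cfg$clinical %||% list()),
    costs = do.call(cost_parameters, cfg$costs %||% list()),
    scenarios = scen,
    base_scenario = cfg$base_scenario %||% "Sousa Pedro",
    life_table = lt,
    workup_cost_per_event = cfg$workup_cost_per_event,
    rate_conversion = conv$rate_conversion %||% "linear",
    event_order = conv$event_order %||% "simultaneous",
    discount_convention = conv$discount_convention %||% "per-cycle",
    sensitivity_ranges = ranges,
    psa_settings = cfg$psa)
  attr(inp, "life_table_path") <- cfg$life_table_path
  inp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_model_config
#' @param inputs a [model_inputs()].
#' @param life_table_path path recorded in the file (the life table itself
#'   is not embedded); defaults to the path the inputs were read with, if
#'   any.
#' @export
write_model_config <- function(inputs, path,
                               life_table_path = attr(inputs, "life_table_path")) {
  stopifnot(inherits(inputs, "model_inputs"))
  cfg <- list(
    clinical = unclass(inputs$clinical),
    costs = unclass(inputs$costs),
    scenarios = unname(lapply(inputs$scenarios, scenario_to_list)),
    base_scenario = inputs$base_scenario,
    life_table_path = life_table_path,
    workup_cost_per_event = inputs$workup_cost_per_event,
    conventions = list(rate_conversion = inputs$rate_conversion,
                       event_order = inputs$event_order,
                       discount_convention = inputs$discount_convention),
    sensitivity = if (!is.null(inputs$sensitivity_ranges))
      list(ranges = lapply(seq_len(nrow(inputs$sensitivity_ranges)), function(i)
        as.list(inputs$sensitivity_ranges[i, c("parameter", "low", "high")]))),
    psa = inputs$psa_settings)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, path, precision = 12L)
  invisible(path)
}
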
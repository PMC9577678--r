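# Secondary and sensitivity analyses: restricted populations, partial
# coverage, effect-percentile sweeps, and break-even threshold solvers.

#' Scenario configuration
#'
#' @param name Scenario label. Shipped names: `"primary"`,
#'   `"food_insecure"`, `"diabetes_only"`, `"chf_only"`, `"coverage50"`.
#' @param population Optional [population_spec()] override; by default the
#'   spec matching `name` (primary for `"coverage50"`).
#' @param criteria Optional [eligibility_criteria()] applied to the
#'   generated population before simulation.
#' @param coverage_fraction Coverage in \[0, 1\], default 1.
#' @param effect_percentile Optional percentile in (0, 100); when set, the
#'   scenario is a deterministic run with the expenditure effect fixed at
#'   that percentile of its uncertainty distribution.
#' @param years,discount_rate,carryover_fraction Optional multi-year
#'   overrides; when `years > 1` the scenario dispatches to
#'   [simulate_multi_year()].
#' @return A list of class `mtm_scenario_config`.
#' @export
scenario_config <- function(name, population = NULL, criteria = NULL,
                            coverage_fraction = 1, effect_percentile = NULL,
                            years = 1, discount_rate = 0.03,
                            carryover_fraction = 0) {
  if (coverage_fraction < 0 || coverage_fraction > 1)
    stop("'coverage_fraction' must lie in [0, 1]")
  structure(list(name = name, population = population, criteria = criteria,
                 coverage_fraction = coverage_fraction,
                 effect_percentile = effect_percentile, years = years,
                 discount_rate = discount_rate,
                 carryover_fraction = carryover_fraction),
            class = "mtm_scenario_config")
}

.shipped_scenarios <- function(name) {
  switch(name,
    primary = scenario_config("primary",
                              default_population_spec("primary_2019")),
    food_insecure = scenario_config(
      "food_insecure", default_population_spec("food_insecure_2017")),
    diabetes_only = scenario_config(
      "diabetes_only", default_population_spec("diabetes_only")),
    chf_only = scenario_config("chf_only",
                               default_population_spec("chf_only")),
    coverage50 = scenario_config("coverage50",
                                 default_population_spec("primary_2019"),
                                 coverage_fraction = 0.5),
    stop("unknown scenario name: '", name, "'"))
}

#' Run a named or configured scenario
#'
#' Generates the scenario population, applies any eligibility restriction,
#' and dispatches to [run_monte_carlo()] (or [simulate_multi_year()] when
#' `years > 1`) with the configured overrides. A shared seed gives paired
#' comparisons across scenarios.
#'
#' @param config An [scenario_config()] or one of the shipped scenario
#'   names.
#' @param seed Integer seed shared across scenarios for paired comparisons.
#' @param n_records Synthetic-population size, default 50,000.
#' @param n_replicates Monte Carlo replicates, default 1000.
#' @inheritParams run_monte_carlo
#' @return An `mtm_sim`, `mtm_multiyear`, or (for percentile scenarios) the
#'   deterministic [central_estimate()] table.
#' @export
run_scenario <- function(config, seed, n_records = 50000,
                         n_replicates = 1000,
                         pooled_effects = default_pooled_effects(),
                         cost_inputs = default_cost_inputs()) {
  if (is.character(config)) config <- .shipped_scenarios(config)
  stopifnot(inherits(config, "mtm_scenario_config"))
  spec <- if (is.null(config$population))
    default_population_spec("primary_2019") else config$population
  records <- generate_population(spec, n_records, seed = seed)
  if (!is.null(config$criteria))
    records <- apply_eligibility_filter(records, config$criteria)
  if (!is.null(config$effect_percentile)) {
    p <- config$effect_percentile
    if (p <= 0 || p >= 100)
      stop("'effect_percentile' must lie in (0, 100)")
    pe <- pooled_effects$expenditure
    red <- stats::qnorm(p / 100, pe$estimate,
                        se_from_ci(pe$ci_low, pe$ci_high))
    pooled_effects$expenditure <- pooled_effect(
      pe$outcome, min(max(red, 0), 1), min(max(red, 0), 1),
      min(max(red, 0), 1), k = pe$k, scale = pe$scale)
    return(central_estimate(records, pooled_effects, cost_inputs,
                            config$coverage_fraction))
  }
  if (config$years > 1)
    simulate_multi_year(records, pooled_effects = pooled_effects,
                        cost_inputs = cost_inputs, years = config$years,
                        discount_rate = config$discount_rate,
                        carryover_fraction = config$carryover_fraction,
                        n_replicates = n_replicates, seed = seed,
                        coverage_fraction = config$coverage_fraction)
  else
    run_monte_carlo(records, pooled_effects, cost_inputs,
                    n_replicates = n_replicates, seed = seed,
                    coverage_fraction = config$coverage_fraction)
}

#' Net savings across percentiles of the expenditure effect
#'
#' For each percentile `p`, the expenditure reduction is fixed at the
#' Normal quantile of its pooled uncertainty distribution and net savings
#' are computed deterministically, holding every other input at its central
#' estimate: `net(p) = reduction(p) * baseline expenditures - program
#' cost`.
#'
#' @param percentiles Percentiles in (0, 100); the published sweep uses
#'   `c(2.5, 10, 25, 50, 75, 90, 97.5)`.
#' @param baseline_expenditures_total Total annual baseline expenditures of
#'   the covered population, USD.
#' @param program_cost_central Central-estimate annual program cost, USD.
#' @param pooled_expenditure The expenditure [pooled_effect()].
#' @return data.frame with columns `percentile`, `expenditure_reduction`,
#'   `net_savings` (non-decreasing in the percentile).
#' @export
effect_percentile_sweep <- function(percentiles = c(2.5, 10, 25, 50, 75,
                                                    90, 97.5),
                                    baseline_expenditures_total,
                                    program_cost_central,
                                    pooled_expenditure =
                                      default_pooled_effects()$expenditure) {
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must lie strictly inside (0, 100)")
  se <- se_from_ci(pooled_expenditure$ci_low, pooled_expenditure$ci_high)
  red <- stats::qnorm(percentiles / 100, pooled_expenditure$estimate, se)
  data.frame(percentile = percentiles,
             expenditure_reduction = red,
             net_savings = red * baseline_expenditures_total -
               program_cost_central)
}

#' Break-even expenditure-reduction effect
#'
#' The minimum fractional reduction in annual expenditures at which the
#' policy's net cost is zero, holding other inputs at their central
#' estimates: `program cost / baseline expenditures` (closed form; the
#' identity is also verified by bisection in the test-suite).
#'
#' @param program_cost_central Central annual program cost, USD.
#' @param baseline_expenditures_total Total baseline annual expenditures,
#'   USD (> 0).
#' @return A list of class `mtm_threshold` with `break_even_value`
#'   (fraction), `solver`, `residual_net_cost`.
#' @export
break_even_effect <- function(program_cost_central,
                              baseline_expenditures_total) {
  if (baseline_expenditures_total <= 0)
    stop("'baseline_expenditures_total' must be > 0")
  be <- program_cost_central / baseline_expenditures_total
  structure(list(quantity = "expenditure_effect", break_even_value = be,
                 solver = "closed_form",
                 residual_net_cost =
                   be * baseline_expenditures_total - program_cost_central),
            class = "mtm_threshold")
}

#' Break-even per-meal cost
#'
#' The per-meal price at which 1-year net policy cost is zero under linear
#' scaling of the monthly contract cost in the per-meal price
#' ([meal_cost_to_monthly()]): solves `savings = n * (months *
#' monthly(m) + screening)` for `m`.
#'
#' @param savings_central Central averted expenditures, USD/year.
#' @param n_covered Covered persons (> 0).
#' @param months Treated months per year.
#' @param screening_cost Screening cost per person, USD.
#' @param inputs An [cost_inputs()] supplying the monthly/per-meal anchor.
#' @return A list of class `mtm_threshold`; `break_even_value` is `NA` with
#'   a warning when savings cannot even cover screening (no positive
#'   solution).
#' @export
break_even_meal_cost <- function(savings_central, n_covered, months = 8,
                                 screening_cost = 31.255,
                                 inputs = default_cost_inputs()) {
  if (n_covered <= 0) stop("'n_covered' must be > 0")
  per_person <- savings_central / n_covered - screening_cost
  slope <- months * inputs$monthly_meal_cost_mean / inputs$per_meal_cost_mean
  if (per_person <= 0) {
    warning("no positive break-even meal price: savings do not cover ",
            "screening costs alone")
    return(structure(list(quantity = "per_meal_cost",
                          break_even_value = NA_real_,
                          solver = "closed_form",
                          residual_net_cost = NA_real_),
                     class = "mtm_threshold"))
  }
  m <- per_person / slope
  resid <- savings_central -
    n_covered * (months * meal_cost_to_monthly(m, inputs) + screening_cost)
  structure(list(quantity = "per_meal_cost", break_even_value = m,
                 solver = "closed_form", residual_net_cost = resid),
            class = "mtm_threshold")
}

#' @export
print.mtm_threshold <- function(x, ...) {
  cat("Break-even threshold (", x$quantity, ", ", x$solver, "): ",
      signif(x$break_even_value, 4), "\n  residual net cost at solution: ",
      signif(x$residual_net_cost, 3), "\n", sep = "")
  invisible(x)
}
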
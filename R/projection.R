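# Ten-year open-cohort projection with log-linear growth and discounting.

#' Fit an annual growth rate by log-linear regression
#'
#' Ordinary least squares of `log(value)` on `year`; the annual growth rate
#' is `exp(slope) - 1`.
#'
#' @param series data.frame with columns `year` and `value` (all values
#'   > 0), or a numeric vector of values with `years` supplied.
#' @param years Optional years when `series` is a plain vector.
#' @return Annual growth rate as a fraction/year.
#' @examples
#' fit_loglinear_growth(data.frame(year = 0:9, value = 100 * 1.03^(0:9)))
#' @export
fit_loglinear_growth <- function(series, years = NULL) {
  if (is.data.frame(series)) {
    year <- series$year; value <- series$value
  } else {
    value <- series
    year <- if (is.null(years)) seq_along(value) else years
  }
  if (length(value) < 2)
    stop("insufficient data: at least 2 points are required")
  if (any(value <= 0))
    stop("domain error: all values must be > 0 for a log-linear fit")
  fit <- stats::lm(log(value) ~ year)
  unname(exp(stats::coef(fit)[2]) - 1)
}

#' Simulate a historical expenditure (or population) series
#'
#' Geometric growth with multiplicative lognormal noise; the synthetic
#' stand-in for historical survey series used to exercise
#' [fit_loglinear_growth()] by parameter recovery.
#'
#' @param base_value Value in the first year (> 0).
#' @param annual_growth True growth rate, fraction/year.
#' @param years Vector of calendar years, default 2010:2019.
#' @param noise_sd SD of log-scale multiplicative noise, default 0.02.
#' @param seed Integer seed.
#' @return data.frame with columns `year`, `value`.
#' @export
simulate_expenditure_history <- function(base_value, annual_growth,
                                         years = 2010:2019,
                                         noise_sd = 0.02, seed = 1) {
  stopifnot(base_value > 0)
  set.seed(as.integer(seed))
  t <- years - years[1]
  data.frame(year = years,
             value = base_value * (1 + annual_growth)^t *
               exp(stats::rnorm(length(t), 0, noise_sd)))
}

#' Growth assumptions per payer stratum
#'
#' @param payer Payer label.
#' @param annual_pop_growth,annual_per_capita_expenditure_growth Fractions
#'   per year in (-1, 1).
#' @return A list of class `mtm_growth_model`.
#' @export
growth_model <- function(payer, annual_pop_growth,
                         annual_per_capita_expenditure_growth) {
  if (abs(annual_pop_growth) >= 1 ||
      abs(annual_per_capita_expenditure_growth) >= 1)
    stop("growth rates must lie in (-1, 1)")
  structure(list(payer = payer, annual_pop_growth = annual_pop_growth,
                 annual_per_capita_expenditure_growth =
                   annual_per_capita_expenditure_growth),
            class = "mtm_growth_model")
}

#' Published growth assumptions for the 10-year projection
#'
#' Annual population growth of 1.0% (private), 2.1% (Medicare), 3.0%
#' (Medicaid) and 5.7% (dual eligible), and inflation-adjusted per-capita
#' expenditure growth of 1.5%, 1.7%, 3.5% and 3.9% respectively.
#'
#' @return Named list of [growth_model()] objects keyed by payer.
#' @export
default_growth_models <- function() {
  out <- lapply(seq_len(nrow(.mtm_growth)), function(i)
    growth_model(.mtm_growth$payer[i], .mtm_growth$annual_pop_growth[i],
                 .mtm_growth$annual_per_capita_expenditure_growth[i]))
  names(out) <- .mtm_growth$payer
  out
}

#' Project a population spec forward
#'
#' Applies geometric growth for `year_offset` years: stratum population is
#' multiplied by `(1 + pop growth)^offset` and mean expenditures (with SD at
#' constant coefficient of variation) by `(1 + expenditure growth)^offset`;
#' hospitalization rates are held constant (open cohort).
#'
#' @param base_population An [population_spec()].
#' @param growth Named list of [growth_model()] objects keyed by payer;
#'   strata without a match use the rates stored in the spec.
#' @param year_offset Integer >= 0; 0 returns the spec unchanged.
#' @return A projected `mtm_population_spec`.
#' @export
project_year <- function(base_population, growth = NULL, year_offset) {
  stopifnot(inherits(base_population, "mtm_population_spec"),
            year_offset >= 0)
  if (year_offset == 0) return(base_population)
  out <- base_population
  out$strata <- lapply(base_population$strata, function(s) {
    if (!is.null(growth) && s$payer %in% names(growth)) {
      gp <- growth[[s$payer]]$annual_pop_growth
      ge <- growth[[s$payer]]$annual_per_capita_expenditure_growth
    } else {
      gp <- s$pop_growth_rate
      ge <- s$per_capita_expenditure_growth_rate
    }
    s$n_population <- s$n_population * (1 + gp)^year_offset
    mult <- (1 + ge)^year_offset
    s$mean_expenditure <- s$mean_expenditure * mult
    s$sd_expenditure <- s$sd_expenditure * mult  # constant CV
    s
  })
  out$base_year <- base_population$base_year + year_offset
  out
}

#' Discount a monetary flow to present value
#'
#' `amount / (1 + rate)^year_offset`; the base year (offset 0) is
#' undiscounted.
#'
#' @param amount USD (vectorized).
#' @param rate Annual discount rate >= 0.
#' @param year_offset Years after the base year (>= 0).
#' @return Discounted USD.
#' @export
discount_value <- function(amount, rate, year_offset) {
  if (any(rate < 0)) stop("'rate' must be >= 0")
  amount / (1 + rate)^year_offset
}

#' Multi-year open-cohort policy simulation
#'
#' Runs the 1-year Monte Carlo engine for each projected year: stratum
#' populations and per-capita expenditures grow geometrically at the payer
#' growth rates, hospitalization rates are held constant, and fresh effect,
#' cost and baseline draws are taken each year. Dollar flows (averted
#' expenditures, program costs, net savings) are discounted to the base
#' year; hospitalization counts are not discounted. With
#' `carryover_fraction > 0`, that share of the previous year's averted
#' expenditures recurs in the following year (discounted, with no meal or
#' screening cost), emulating benefits that persist one extra year. All
#' cumulative quantities are sums over years taken replicate-wise, so their
#' uncertainty intervals reflect the summed simulations.
#'
#' @param records Person table for the base year.
#' @param growth Named list of [growth_model()] objects keyed by payer; by
#'   default the published rates ([default_growth_models()]).
#' @param years Horizon in years (>= 1); `years = 1` reproduces
#'   [run_monte_carlo()] exactly under the same seed.
#' @param discount_rate Annual discount rate for dollar flows, default 0.03.
#' @param carryover_fraction Fraction in \[0, 1\] of recipients with a
#'   second year of sustained expenditure reductions, default 0.
#' @inheritParams run_monte_carlo
#' @return An object of class `mtm_multiyear`: `cumulative` (long summary
#'   data.frame), `per_year` (data.frame with a `year_offset` column),
#'   replicate arrays, and the run settings.
#' @export
simulate_multi_year <- function(records, growth = default_growth_models(),
                                pooled_effects = default_pooled_effects(),
                                cost_inputs = default_cost_inputs(),
                                years = 10, discount_rate = 0.03,
                                carryover_fraction = 0,
                                n_replicates = 1000, seed,
                                coverage_fraction = 1,
                                months_of_meals = cost_inputs$months_of_meals,
                                baseline_uncertainty = c("bootstrap",
                                                         "none")) {
  baseline_uncertainty <- match.arg(baseline_uncertainty)
  if (years < 1) stop("'years' must be >= 1")
  if (carryover_fraction < 0 || carryover_fraction > 1)
    stop("'carryover_fraction' must lie in [0, 1]")
  set.seed(as.integer(seed))
  sd_ <- .strata_data(records)
  S <- length(sd_)
  payers <- names(sd_)
  gp <- vapply(payers, function(p)
    if (p %in% names(growth)) growth[[p]]$annual_pop_growth else 0, 0)
  ge <- vapply(payers, function(p)
    if (p %in% names(growth))
      growth[[p]]$annual_per_capita_expenditure_growth else 0, 0)

  dollar_q <- c("averted_expenditures", "program_cost", "net_savings")
  yearly <- array(NA_real_,
                  dim = c(n_replicates, S + 1, 4, years),
                  dimnames = list(NULL, c(payers, "total"),
                                  .mtm_quantities, NULL))
  prev_ae_undisc <- NULL  # [rep, stratum] undiscounted averted expenditures
  for (t in seq_len(years)) {
    off <- t - 1
    reps <- .mc_loop(sd_, pooled_effects, cost_inputs, n_replicates,
                     coverage_fraction, months_of_meals,
                     baseline_uncertainty,
                     pop_scale = (1 + gp)^off, exp_scale = (1 + ge)^off)
    ae_undisc <- reps[, seq_len(S), "averted_expenditures", drop = FALSE]
    dim(ae_undisc) <- c(n_replicates, S)
    disc <- (1 + discount_rate)^off
    reps[, , dollar_q] <- reps[, , dollar_q] / disc
    if (carryover_fraction > 0 && t > 1) {
      extra <- carryover_fraction * prev_ae_undisc / disc
      reps[, seq_len(S), "averted_expenditures"] <-
        reps[, seq_len(S), "averted_expenditures"] + extra
      reps[, seq_len(S), "net_savings"] <-
        reps[, seq_len(S), "net_savings"] + extra
      reps[, "total", "averted_expenditures"] <-
        reps[, "total", "averted_expenditures"] + rowSums(extra)
      reps[, "total", "net_savings"] <-
        reps[, "total", "net_savings"] + rowSums(extra)
    }
    yearly[, , , t] <- reps
    prev_ae_undisc <- ae_undisc
  }
  cum <- apply(yearly, c(1, 2, 3), sum)
  per_year <- do.call(rbind, lapply(seq_len(years), function(t)
    cbind(year_offset = t - 1, .summarize_reps(yearly[, , , t]))))
  structure(list(cumulative = .summarize_reps(cum),
                 per_year = per_year,
                 replicates_cumulative = cum,
                 fraction_cost_saving =
                   mean(cum[, "total", "net_savings"] > 0),
                 horizon_years = years, discount_rate = discount_rate,
                 carryover_fraction = carryover_fraction,
                 n_replicates = n_replicates, seed = as.integer(seed),
                 coverage_fraction = coverage_fraction,
                 months_of_meals = months_of_meals,
                 baseline_uncertainty = baseline_uncertainty),
            class = "mtm_multiyear")
}

#' @export
print.mtm_multiyear <- function(x, ...) {
  cat(x$horizon_years, "-year MTM policy projection: ", x$n_replicates,
      " replicates/year, ", 100 * x$discount_rate, "% discounting",
      if (x$carryover_fraction > 0)
        paste0(", ", 100 * x$carryover_fraction, "% carryover"),
      " (seed ", x$seed, ")\n\nCumulative totals:\n", sep = "")
  print(format_result_table(x)$formatted, row.names = FALSE)
  cat("\nFraction of replicates cost-saving (cumulative): ",
      round(100 * x$fraction_cost_saving, 1), "%\n", sep = "")
  invisible(x)
}

#' @export
summary.mtm_multiyear <- function(object, ...) object$cumulative
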
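# One-year probabilistic cohort policy simulation.

.mtm_quantities <- c("averted_hospitalizations", "averted_expenditures",
                     "program_cost", "net_savings")

#' Effect-size draws
#'
#' @param expenditure_reduction,hospitalization_reduction Fractions in
#'   \[0, 1\]; may be vectors (e.g. one value per payer stratum).
#' @return A list of class `mtm_effect_draws`.
#' @export
effect_draws <- function(expenditure_reduction, hospitalization_reduction) {
  if (any(expenditure_reduction < 0 | expenditure_reduction > 1) ||
      any(hospitalization_reduction < 0 | hospitalization_reduction > 1))
    stop("effect draws must lie in [0, 1]")
  structure(list(expenditure_reduction = expenditure_reduction,
                 hospitalization_reduction = hospitalization_reduction),
            class = "mtm_effect_draws")
}

#' Draw effect sizes from their pooled uncertainty
#'
#' Independent normal draws centred at the pooled estimates with standard
#' errors recovered from the pooled 95% CIs, truncated to \[0, 1\]
#' (inverse-CDF truncation). Uses the current RNG state.
#'
#' @param pooled_expenditure,pooled_hospitalization [pooled_effect()]
#'   objects on the percent-reduction scale.
#' @param n Number of draws per outcome.
#' @return An [effect_draws()] with vectors of length `n`.
#' @export
draw_effects <- function(pooled_expenditure, pooled_hospitalization, n = 1) {
  se_e <- se_from_ci(pooled_expenditure$ci_low, pooled_expenditure$ci_high)
  se_h <- se_from_ci(pooled_hospitalization$ci_low,
                     pooled_hospitalization$ci_high)
  effect_draws(
    .rtnorm(n, pooled_expenditure$estimate, se_e, 0, 1),
    .rtnorm(n, pooled_hospitalization$estimate, se_h, 0, 1))
}

# per-stratum baseline data extracted once from a person table
.strata_data <- function(records) {
  if (!nrow(records)) stop("'records' must be non-empty")
  payers <- intersect(.mtm_payers, unique(records$payer))
  payers <- c(payers, setdiff(unique(records$payer), payers))
  out <- lapply(payers, function(p) {
    idx <- records$payer == p
    w <- records$weight[idx]
    list(payer = p, n_population = sum(w), n_records = sum(idx),
         prob = w / sum(w),
         uniform_weights = length(unique(round(w, 9))) == 1L,
         expenditure = records$annual_expenditure[idx],
         hospitalizations = records$annual_hospitalizations[idx],
         mean_expenditure = .wmean(records$annual_expenditure[idx], w),
         mean_hospitalizations =
           .wmean(records$annual_hospitalizations[idx], w))
  })
  names(out) <- payers
  out
}

# core accounting for one replicate; all arguments vectorized over strata
.replicate_core <- function(n_population, mean_expenditure,
                            mean_hospitalizations, r_exp, r_hosp,
                            screening, monthly, coverage, months) {
  ah <- coverage * n_population * mean_hospitalizations * r_hosp
  ae <- coverage * n_population * mean_expenditure * r_exp
  pc <- coverage * n_population * (months * monthly + screening)
  cbind(averted_hospitalizations = ah, averted_expenditures = ae,
        program_cost = pc, net_savings = ae - pc)
}

.with_total <- function(m) rbind(m, total = colSums(m))

#' Evaluate one simulation replicate
#'
#' Applies fixed effect and cost draws to the weighted baseline of a person
#' table, stratified by payer: averted hospitalizations are
#' `reduction * sum(w_i * hosp_i) * coverage`, averted expenditures
#' analogously, program cost from [compute_program_cost()] on the covered
#' weight, and net savings their difference.
#'
#' @param records Person table.
#' @param effects An [effect_draws()]; scalar values are shared across
#'   strata, vectors must have one value per stratum (payer order of the
#'   table).
#' @param costs An [cost_draw()] (scalar).
#' @param coverage_fraction Share of eligible persons covered, in \[0, 1\].
#' @param months_of_meals Treated months per year.
#' @return A data.frame with one row per stratum plus a `total` row and the
#'   four outcome columns.
#' @export
simulate_replicate <- function(records, effects, costs,
                               coverage_fraction = 1, months_of_meals = 8) {
  stopifnot(inherits(effects, "mtm_effect_draws"),
            inherits(costs, "mtm_cost_draw"))
  if (coverage_fraction < 0 || coverage_fraction > 1)
    stop("'coverage_fraction' must lie in [0, 1]")
  sd_ <- .strata_data(records)
  S <- length(sd_)
  r_exp <- rep_len(effects$expenditure_reduction, S)
  r_hosp <- rep_len(effects$hospitalization_reduction, S)
  m <- .replicate_core(
    vapply(sd_, `[[`, 0, "n_population"),
    vapply(sd_, `[[`, 0, "mean_expenditure"),
    vapply(sd_, `[[`, 0, "mean_hospitalizations"),
    r_exp, r_hosp, costs$screening_cost, costs$monthly_meal_cost,
    coverage_fraction, months_of_meals)
  rownames(m) <- names(sd_)
  out <- as.data.frame(.with_total(m))
  out <- cbind(stratum = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Deterministic central-value run
#'
#' Evaluates the model once with every input at its central value: pooled
#' effect point estimates, screening at the range midpoint, the monthly
#' contract anchor, and the baseline moments. Given a person table the
#' baseline is its observed weighted means (no resampling); given an
#' [population_spec()] the calibrated stratum moments are used directly, so
#' the result is pure arithmetic with no sampling error.
#'
#' @param x A person table or an `mtm_population_spec`.
#' @inheritParams run_monte_carlo
#' @return As [simulate_replicate()].
#' @export
central_estimate <- function(x, pooled_effects = default_pooled_effects(),
                             cost_inputs = default_cost_inputs(),
                             coverage_fraction = 1,
                             months_of_meals = cost_inputs$months_of_meals) {
  eff <- effect_draws(pooled_effects$expenditure$estimate,
                      pooled_effects$hospitalization$estimate)
  costs <- .central_cost_draw(cost_inputs)
  if (inherits(x, "mtm_population_spec")) {
    m <- .replicate_core(
      vapply(x$strata, `[[`, 0, "n_population"),
      vapply(x$strata, `[[`, 0, "mean_expenditure"),
      vapply(x$strata, `[[`, 0, "mean_hospitalizations"),
      eff$expenditure_reduction, eff$hospitalization_reduction,
      costs$screening_cost, costs$monthly_meal_cost,
      coverage_fraction, months_of_meals)
    rownames(m) <- names(x$strata)
    out <- as.data.frame(.with_total(m))
    out <- cbind(stratum = rownames(out), out)
    rownames(out) <- NULL
    return(out)
  }
  simulate_replicate(x, eff, costs, coverage_fraction, months_of_meals)
}

# replicate loop shared by the 1-year and multi-year engines; assumes the
# RNG has been seeded by the caller. Draw order per replicate: per-stratum
# expenditure effects, per-stratum hospitalization effects, screening cost,
# monthly meal cost, then per-stratum bootstrap indices.
.mc_loop <- function(sd_, pooled_effects, cost_inputs, n_replicates,
                     coverage_fraction, months_of_meals,
                     baseline_uncertainty = c("bootstrap", "none"),
                     pop_scale = NULL, exp_scale = NULL) {
  baseline_uncertainty <- match.arg(baseline_uncertainty)
  S <- length(sd_)
  if (is.null(pop_scale)) pop_scale <- rep(1, S)
  if (is.null(exp_scale)) exp_scale <- rep(1, S)
  pe <- pooled_effects$expenditure
  ph <- pooled_effects$hospitalization
  se_e <- se_from_ci(pe$ci_low, pe$ci_high)
  se_h <- se_from_ci(ph$ci_low, ph$ci_high)
  n_pop <- vapply(sd_, `[[`, 0, "n_population") * pop_scale

  reps <- array(NA_real_, dim = c(n_replicates, S + 1, 4),
                dimnames = list(NULL, c(names(sd_), "total"),
                                .mtm_quantities))
  for (r in seq_len(n_replicates)) {
    r_exp <- .rtnorm(S, pe$estimate, se_e, 0, 1)
    r_hosp <- .rtnorm(S, ph$estimate, se_h, 0, 1)
    screening <- stats::runif(1, cost_inputs$screening_cost_low,
                              cost_inputs$screening_cost_high)
    monthly <- .rtnorm(1, cost_inputs$monthly_meal_cost_mean,
                       cost_inputs$monthly_meal_cost_sd, lower = 0)
    if (baseline_uncertainty == "bootstrap") {
      me <- mh <- numeric(S)
      for (s in seq_len(S)) {
        n_s <- sd_[[s]]$n_records
        idx <- if (sd_[[s]]$uniform_weights)
          sample.int(n_s, n_s, replace = TRUE)
        else sample.int(n_s, n_s, replace = TRUE, prob = sd_[[s]]$prob)
        me[s] <- mean(sd_[[s]]$expenditure[idx])
        mh[s] <- mean(sd_[[s]]$hospitalizations[idx])
      }
    } else {
      me <- vapply(sd_, `[[`, 0, "mean_expenditure")
      mh <- vapply(sd_, `[[`, 0, "mean_hospitalizations")
    }
    reps[r, , ] <- .with_total(.replicate_core(
      n_pop, me * exp_scale, mh, r_exp, r_hosp, screening, monthly,
      coverage_fraction, months_of_meals))
  }
  reps
}

#' Summarize Monte Carlo replicates
#'
#' Arithmetic mean with a 95% uncertainty interval given by the empirical
#' 2.5th and 97.5th percentiles (`stats::quantile()` type 7, linear
#' interpolation between order statistics).
#'
#' @param replicates Numeric vector, or matrix with one column per quantity.
#' @return A data.frame with columns `mean`, `ui_low`, `ui_high` (one row
#'   per column of `replicates`).
#' @export
summarize_simulations <- function(replicates) {
  if (!length(replicates)) stop("no replicates to summarize")
  m <- as.matrix(replicates)
  out <- data.frame(
    mean = colMeans(m),
    ui_low = apply(m, 2, stats::quantile, probs = 0.025, type = 7),
    ui_high = apply(m, 2, stats::quantile, probs = 0.975, type = 7))
  rownames(out) <- colnames(m)
  out
}

# long summary table from a replicate array [rep, stratum, quantity]
.summarize_reps <- function(reps) {
  strata <- dimnames(reps)[[2]]
  qs <- dimnames(reps)[[3]]
  out <- do.call(rbind, lapply(strata, function(s) {
    sm <- summarize_simulations(reps[, s, , drop = TRUE])
    cbind(data.frame(stratum = s, quantity = qs,
                     stringsAsFactors = FALSE), sm)
  }))
  rownames(out) <- NULL
  out
}

#' Run the 1-year Monte Carlo policy simulation
#'
#' Propagates uncertainty in effect sizes (independent truncated-normal
#' draws per payer stratum), program costs (uniform screening, truncated-
#' normal monthly contract cost, shared across strata), and baseline
#' utilization (bootstrap resampling of the person table within stratum,
#' weights rescaled) through `n_replicates` replicates, and summarizes each
#' quantity per stratum and in total as mean and 95% uncertainty interval.
#'
#' @param records Person table from [generate_population()] (or read from
#'   CSV).
#' @param pooled_effects List with `expenditure` and `hospitalization`
#'   [pooled_effect()] objects; see [default_pooled_effects()].
#' @param cost_inputs An [cost_inputs()] object.
#' @param n_replicates Number of Monte Carlo replicates (>= 1), default
#'   1000.
#' @param seed Integer seed (required; the whole run is reproducible).
#' @param coverage_fraction Share of eligible persons covered, in \[0, 1\].
#' @param months_of_meals Treated months per year; defaults to the cost
#'   input value (8).
#' @param baseline_uncertainty `"bootstrap"` (default) or `"none"` to hold
#'   baseline utilization fixed at the observed weighted means.
#' @return An object of class `mtm_sim`: list with `summary` (long
#'   data.frame of mean/UI per stratum and quantity), `replicates` (array
#'   `[n_replicates, strata + total, 4]`), `fraction_cost_saving`, and the
#'   run settings.
#' @examples
#' pop <- generate_population(default_population_spec(), 2000, seed = 7)
#' sim <- run_monte_carlo(pop, n_replicates = 200, seed = 7)
#' sim
#' @export
run_monte_carlo <- function(records,
                            pooled_effects = default_pooled_effects(),
                            cost_inputs = default_cost_inputs(),
                            n_replicates = 1000, seed,
                            coverage_fraction = 1,
                            months_of_meals = cost_inputs$months_of_meals,
                            baseline_uncertainty = c("bootstrap", "none")) {
  baseline_uncertainty <- match.arg(baseline_uncertainty)
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  if (coverage_fraction < 0 || coverage_fraction > 1)
    stop("'coverage_fraction' must lie in [0, 1]")
  set.seed(as.integer(seed))
  sd_ <- .strata_data(records)
  reps <- .mc_loop(sd_, pooled_effects, cost_inputs, n_replicates,
                   coverage_fraction, months_of_meals,
                   baseline_uncertainty)
  structure(list(summary = .summarize_reps(reps), replicates = reps,
                 fraction_cost_saving =
                   mean(reps[, "total", "net_savings"] > 0),
                 n_replicates = n_replicates, seed = as.integer(seed),
                 coverage_fraction = coverage_fraction,
                 months_of_meals = months_of_meals,
                 baseline_uncertainty = baseline_uncertainty),
            class = "mtm_sim")
}

#' @export
print.mtm_sim <- function(x, ...) {
  cat("1-year MTM policy simulation: ", x$n_replicates,
      " replicates, coverage ", x$coverage_fraction, ", ",
      x$months_of_meals, " months of meals (seed ", x$seed, ")\n\n",
      sep = "")
  print(format_result_table(x)$formatted, row.names = FALSE)
  cat("\nFraction of replicates cost-saving: ",
      round(100 * x$fraction_cost_saving, 1), "%\n", sep = "")
  invisible(x)
}

#' @export
summary.mtm_sim <- function(object, ...) object$summary

#' Scatter of replicate program costs against averted expenditures
#'
#' One point per replicate and payer stratum; the diagonal marks policy cost
#' neutrality (points above it are cost-saving replicates).
#'
#' @param x An `mtm_sim` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mtm_sim <- function(x, ...) {
  strata <- setdiff(dimnames(x$replicates)[[2]], "total")
  cols <- grDevices::hcl.colors(max(length(strata), 3L), "Dark 3")
  pc <- x$replicates[, strata, "program_cost", drop = FALSE] / 1e9
  ae <- x$replicates[, strata, "averted_expenditures", drop = FALSE] / 1e9
  lim <- range(0, pc, ae)
  graphics::plot(NA, xlim = lim, ylim = lim,
                 xlab = "MTM program cost ($B)",
                 ylab = "Averted health care expenditures ($B)", ...)
  for (i in seq_along(strata))
    graphics::points(pc[, i, 1], ae[, i, 1], col = cols[i], pch = 16,
                     cex = 0.5)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = strata, col = cols[seq_along(strata)],
                   pch = 16, bty = "n")
  invisible(x)
}
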
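# Random-effects pooling of study-level MTM effect estimates.

#' Standard error from a symmetric normal confidence interval
#'
#' @param ci_low,ci_high Interval bounds (`ci_high > ci_low`).
#' @param level Confidence level, default 0.95.
#' @return `(ci_high - ci_low) / (2 * z)` with `z` the standard-normal
#'   quantile for `level`.
#' @examples
#' se_from_ci(6.9, 32.4)   # ~6.505
#' @export
se_from_ci <- function(ci_low, ci_high, level = 0.95) {
  if (any(ci_high <= ci_low))
    stop("interval ordering error: 'ci_high' must exceed 'ci_low'")
  z <- stats::qnorm(1 - (1 - level) / 2)
  (ci_high - ci_low) / (2 * z)
}

#' Construct a pooled-effect object directly
#'
#' Used for the shipped defaults, which pin the published pooled values; the
#' study-level inputs behind them live only in supplementary material, for
#' which [system.file("extdata", "studies_template.csv", package =
#' "mtmsim")] ships a fill-in template.
#'
#' @param outcome Outcome label, e.g. `"expenditure_pct_change"` or
#'   `"hospitalization_rr"`.
#' @param estimate Pooled point estimate.
#' @param ci_low,ci_high 95% interval bounds.
#' @param tau2 Between-study variance (>= 0).
#' @param k Number of studies.
#' @param scale One of `"percent_reduction"`, `"log_rr"`, `"usd"`.
#' @return A list of class `mtm_pooled_effect`.
#' @export
pooled_effect <- function(outcome, estimate, ci_low, ci_high, tau2 = 0,
                          k = 1, scale = c("percent_reduction", "log_rr",
                                           "usd")) {
  scale <- match.arg(scale)
  if (tau2 < 0) stop("'tau2' must be >= 0")
  if (!(ci_low <= estimate && estimate <= ci_high))
    stop("estimate must lie inside [ci_low, ci_high]")
  if (k < 1) stop("'k' must be >= 1")
  structure(list(outcome = outcome, estimate = estimate, ci_low = ci_low,
                 ci_high = ci_high, se = se_from_ci(ci_low, ci_high),
                 tau2 = tau2, k = as.integer(k), scale = scale),
            class = "mtm_pooled_effect")
}

#' DerSimonian-Laird random-effects pooling
#'
#' Inverse-variance random-effects meta-analysis with the
#' DerSimonian-Laird moment estimator of the between-study variance:
#' with fixed-effect weights \eqn{w_i = 1/se_i^2},
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2 / \sum w))},
#' random-effects weights \eqn{w_i^* = 1/(se_i^2 + \tau^2)}, pooled estimate
#' \eqn{\sum w^* \hat\theta / \sum w^*} and a normal-approximation 95% CI.
#'
#' @param studies A data.frame of study records with columns `estimate` and
#'   `se` (or `ci_low`/`ci_high`, from which SEs are derived), and optionally
#'   `outcome` and `scale` (must be constant if present).
#' @param method Pooling method; only `"DL"` is implemented.
#' @return An [pooled_effect()] object with the pooled estimate, 95% CI,
#'   `tau2` and `k`.
#' @examples
#' pool_random_effects(data.frame(estimate = c(10, 20, 30), se = c(2, 3, 4)))
#' @export
pool_random_effects <- function(studies, method = "DL") {
  method <- match.arg(method, "DL")
  if (is.null(studies) || !nrow(studies))
    stop("empty input: at least one study is required")
  if ("scale" %in% names(studies) &&
      length(unique(studies$scale)) > 1L)
    stop("scale mismatch: studies must share a common scale, got ",
         paste(unique(studies$scale), collapse = ", "))
  if ("outcome" %in% names(studies) &&
      length(unique(studies$outcome)) > 1L)
    stop("scale mismatch: studies must share a common outcome")
  est <- studies$estimate
  se <- if ("se" %in% names(studies) && !all(is.na(studies$se)))
    studies$se else se_from_ci(studies$ci_low, studies$ci_high)
  if (any(is.na(est)) || any(is.na(se)) || any(se <= 0))
    stop("every study needs an estimate and a positive se")
  k <- length(est)
  w <- 1 / se^2
  fixed <- sum(w * est) / sum(w)
  Q <- sum(w * (est - fixed)^2)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
          else 0
  wstar <- 1 / (se^2 + tau2)
  pooled <- sum(wstar * est) / sum(wstar)
  se_pooled <- 1 / sqrt(sum(wstar))
  z <- stats::qnorm(0.975)
  out <- pooled_effect(
    outcome = if ("outcome" %in% names(studies)) studies$outcome[1]
              else "pooled",
    estimate = pooled, ci_low = pooled - z * se_pooled,
    ci_high = pooled + z * se_pooled, tau2 = tau2, k = k,
    scale = if ("scale" %in% names(studies)) studies$scale[1]
            else "percent_reduction")
  out$Q <- Q
  out
}

#' Pool hospitalization relative risks on the log scale
#'
#' Study-level relative risks (with CIs) are log-transformed, pooled by
#' [pool_random_effects()], and back-transformed to a percent reduction
#' `1 - RR`.
#'
#' @param studies data.frame with columns `estimate`, `ci_low`, `ci_high` on
#'   the RR scale (all > 0).
#' @return An `mtm_pooled_effect` on the percent-reduction scale.
#' @export
pool_hospitalization_rr <- function(studies) {
  if (any(studies$estimate <= 0) || any(studies$ci_low <= 0))
    stop("relative risks must be positive")
  logd <- data.frame(estimate = log(studies$estimate),
                     ci_low = log(studies$ci_low),
                     ci_high = log(studies$ci_high),
                     scale = "log_rr", outcome = "hospitalization_rr",
                     stringsAsFactors = FALSE)
  p <- pool_random_effects(logd)
  # 1 - RR: the upper RR bound maps to the lower reduction bound
  pooled_effect(outcome = "hospitalization_rr",
                estimate = 1 - exp(p$estimate),
                ci_low = 1 - exp(p$ci_high),
                ci_high = 1 - exp(p$ci_low),
                tau2 = p$tau2, k = p$k, scale = "percent_reduction")
}

#' Participant-weighted mean duration of MTM receipt
#'
#' @param studies data.frame with columns `duration_months` and
#'   `n_participants`.
#' @return Weighted mean months per patient per year.
#' @export
weighted_mean_duration <- function(studies) {
  d <- studies$duration_months
  n <- studies$n_participants
  if (!length(n) || sum(n) <= 0)
    stop("zero total weight: 'n_participants' must sum to > 0")
  sum(n * d) / sum(n)
}

#' Pooled per-meal cost across contributing organizations
#'
#' @param costs Numeric vector of per-meal costs (USD/meal), or a data.frame
#'   with a `estimate` column.
#' @return Named vector `c(mean, sd)`; the sample SD is 0 for a single value.
#' @export
pooled_meal_cost <- function(costs) {
  if (is.data.frame(costs)) costs <- costs$estimate
  if (!length(costs)) stop("empty input: no per-meal costs")
  c(mean = mean(costs),
    sd = if (length(costs) > 1) stats::sd(costs) else 0)
}

#' Shipped pooled effect sizes
#'
#' The published pooled values from the five-study meta-analysis: a 19.7%
#' (95% CI 6.9%-32.4%) reduction in annual health-care expenditures and a
#' 47.0% (31.7%-62.3%) reduction in annual hospitalizations, both expressed
#' as fractions on the percent-reduction scale.
#'
#' @return List with elements `expenditure` and `hospitalization`, each an
#'   `mtm_pooled_effect`.
#' @export
default_pooled_effects <- function() {
  list(
    expenditure = pooled_effect("expenditure_pct_change", 0.197,
                                0.069, 0.324, k = 5,
                                scale = "percent_reduction"),
    hospitalization = pooled_effect("hospitalization_rr", 0.470,
                                    0.317, 0.623, k = 5,
                                    scale = "percent_reduction"))
}

#' @export
print.mtm_pooled_effect <- function(x, digits = 3, ...) {
  cat("Pooled effect (", x$outcome, ", ", x$scale, ", k = ", x$k, ")\n",
      sep = "")
  cat("  estimate: ", signif(x$estimate, digits), "  95% CI (",
      signif(x$ci_low, digits), ", ", signif(x$ci_high, digits),
      ")  tau2 = ", signif(x$tau2, digits), "\n", sep = "")
  invisible(x)
}
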
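#' Define one payer stratum of an eligible population
#'
#' A stratum is described by its weighted population count and the first two
#' moments of annual health-care expenditures (USD/year) and hospitalization
#' counts (per person-year), plus annual growth rates used by the 10-year
#' projection.
#'
#' @param payer One of `"private"`, `"medicare"`, `"medicaid"`, `"dual"`.
#' @param n_population Weighted number of eligible persons (> 0).
#' @param mean_expenditure,sd_expenditure Mean and SD of annual expenditures,
#'   USD/year (> 0).
#' @param mean_hospitalizations,sd_hospitalizations Mean and SD of annual
#'   hospitalization counts (> 0).
#' @param pop_growth_rate,per_capita_expenditure_growth_rate Annual growth
#'   rates as fractions in (-1, 1).
#' @return A list of class `mtm_stratum_spec`.
#' @export
stratum_spec <- function(payer, n_population,
                         mean_expenditure, sd_expenditure,
                         mean_hospitalizations, sd_hospitalizations,
                         pop_growth_rate = 0,
                         per_capita_expenditure_growth_rate = 0) {
  payer <- match.arg(payer, .mtm_payers)
  if (!is.numeric(n_population) || n_population <= 0)
    stop("'n_population' must be > 0 (stratum ", payer, ")")
  for (fld in c("sd_expenditure", "sd_hospitalizations")) {
    v <- get(fld)
    if (!is.numeric(v) || v <= 0)
      stop("invalid parameter '", fld, "': SD must be > 0 (stratum ",
           payer, ")")
  }
  if (mean_expenditure <= 0 || mean_hospitalizations <= 0)
    stop("stratum means must be > 0 (stratum ", payer, ")")
  for (fld in c("pop_growth_rate", "per_capita_expenditure_growth_rate")) {
    v <- get(fld)
    if (abs(v) >= 1) stop("'", fld, "' must lie in (-1, 1)")
  }
  structure(list(payer = payer, n_population = n_population,
                 mean_expenditure = mean_expenditure,
                 sd_expenditure = sd_expenditure,
                 mean_hospitalizations = mean_hospitalizations,
                 sd_hospitalizations = sd_hospitalizations,
                 pop_growth_rate = pop_growth_rate,
                 per_capita_expenditure_growth_rate =
                   per_capita_expenditure_growth_rate),
            class = "mtm_stratum_spec")
}

#' Define a full eligible-population specification
#'
#' Bundles payer strata with diagnosis prevalences, distributional families
#' and demographic descriptors; the unit the synthetic-population generator
#' consumes.
#'
#' @param strata List of [stratum_spec()] objects.
#' @param diagnosis_prevalences Named vector of prevalences in \[0, 1\] over
#'   the diet-sensitive diagnosis flags (`diabetes`, `chf`, `mi`,
#'   `other_heart`, `stroke`, `cancer`, `emphysema`, `ckd`, `hiv`).
#' @param food_insecurity_prevalence Prevalence in \[0, 1\] of the
#'   food-insecurity flag.
#' @param expenditure_distribution `"lognormal"` (default) or `"gamma"`;
#'   moment-matched per stratum.
#' @param hospitalization_distribution `"negative_binomial"` (default) or
#'   `"poisson"`; negative binomial is moment-matched and requires
#'   variance > mean.
#' @param utilization_correlation Gaussian-copula rank correlation between
#'   expenditures and hospitalization counts, default 0.5.
#' @param base_year Calendar base year.
#' @param demographics Optional list with `age_mean`, `age_sd`, and named
#'   probability vectors `sex`, `race_ethnicity`, `census_region`
#'   (descriptive fields only).
#' @return A list of class `mtm_population_spec`.
#' @seealso [default_population_spec()] for the shipped calibrations.
#' @export
population_spec <- function(strata, diagnosis_prevalences,
                            food_insecurity_prevalence = 0,
                            expenditure_distribution = c("lognormal", "gamma"),
                            hospitalization_distribution =
                              c("negative_binomial", "poisson"),
                            utilization_correlation = 0.5,
                            base_year = 2019,
                            demographics = NULL) {
  expenditure_distribution <- match.arg(expenditure_distribution)
  hospitalization_distribution <- match.arg(hospitalization_distribution)
  if (!length(strata) || !all(vapply(strata, inherits, TRUE,
                                     "mtm_stratum_spec")))
    stop("'strata' must be a non-empty list of stratum_spec objects")
  missing_dx <- setdiff(.mtm_diagnoses, names(diagnosis_prevalences))
  if (length(missing_dx))
    stop("diagnosis_prevalences missing flags: ",
         paste(missing_dx, collapse = ", "))
  diagnosis_prevalences <- diagnosis_prevalences[.mtm_diagnoses]
  if (any(diagnosis_prevalences < 0 | diagnosis_prevalences > 1))
    stop("diagnosis prevalences must lie in [0, 1]")
  if (food_insecurity_prevalence < 0 || food_insecurity_prevalence > 1)
    stop("'food_insecurity_prevalence' must lie in [0, 1]")
  if (abs(utilization_correlation) > 1)
    stop("'utilization_correlation' must lie in [-1, 1]")
  names(strata) <- vapply(strata, `[[`, "", "payer")
  if (anyDuplicated(names(strata)))
    stop("duplicated payer stratum")
  structure(list(strata = strata,
                 diagnosis_prevalences = diagnosis_prevalences,
                 food_insecurity_prevalence = food_insecurity_prevalence,
                 expenditure_distribution = expenditure_distribution,
                 hospitalization_distribution = hospitalization_distribution,
                 utilization_correlation = utilization_correlation,
                 base_year = base_year,
                 demographics = demographics),
            class = "mtm_population_spec")
}

#' Shipped population calibrations
#'
#' Returns a ready-to-use [population_spec()] for one of the four modeled
#' eligible populations: the 2019 primary population (6,309,998 adults with a
#' diet-sensitive condition and an IADL limitation), the 2017 food-insecure
#' secondary population (1,887,681), and the diabetes-only / CHF-only
#' restricted populations. Per-stratum baseline means are back-derived from
#' published per-payer central results and, where overall moments are
#' published, rescaled so the weighted aggregate matches them exactly; SDs
#' use the primary population's coefficients of variation.
#'
#' @param name One of `"primary_2019"`, `"food_insecure_2017"`,
#'   `"diabetes_only"`, `"chf_only"`.
#' @param utilization_correlation Passed through to [population_spec()].
#' @return An `mtm_population_spec`.
#' @examples
#' spec <- default_population_spec("primary_2019")
#' sum(vapply(spec$strata, `[[`, 0, "n_population"))  # 6,309,998
#' @export
default_population_spec <- function(name = c("primary_2019",
                                             "food_insecure_2017",
                                             "diabetes_only", "chf_only"),
                                    utilization_correlation = 0.5) {
  name <- match.arg(name)
  cal <- .mtm_populations[[name]]
  tab <- cal$strata
  # back-derive stratum means from per-payer averted central values
  mean_exp <- tab$averted_expenditures /
    (.mtm_central_effects$expenditure * tab$n_population)
  mean_hosp <- tab$averted_hospitalizations /
    (.mtm_central_effects$hospitalization * tab$n_population)
  if (!is.null(cal$overall)) {
    w <- tab$n_population / sum(tab$n_population)
    mean_exp <- mean_exp * cal$overall$mean_expenditure / sum(w * mean_exp)
    mean_hosp <- mean_hosp *
      cal$overall$mean_hospitalizations / sum(w * mean_hosp)
    cv_exp <- cal$overall$sd_expenditure / cal$overall$mean_expenditure
    cv_hosp <- cal$overall$sd_hospitalizations /
      cal$overall$mean_hospitalizations
  } else {
    cv_exp <- .mtm_cv$expenditure
    cv_hosp <- .mtm_cv$hospitalizations
  }
  strata <- lapply(seq_len(nrow(tab)), function(i) {
    g <- .mtm_growth[.mtm_growth$payer == tab$payer[i], ]
    stratum_spec(payer = tab$payer[i],
                 n_population = tab$n_population[i],
                 mean_expenditure = mean_exp[i],
                 sd_expenditure = mean_exp[i] * cv_exp,
                 mean_hospitalizations = mean_hosp[i],
                 sd_hospitalizations = mean_hosp[i] * cv_hosp,
                 pop_growth_rate = g$annual_pop_growth,
                 per_capita_expenditure_growth_rate =
                   g$annual_per_capita_expenditure_growth)
  })
  population_spec(strata = strata,
                  diagnosis_prevalences = cal$diagnosis_prevalences,
                  food_insecurity_prevalence = cal$food_insecurity_prevalence,
                  utilization_correlation = utilization_correlation,
                  base_year = cal$base_year,
                  demographics = .mtm_demographics[[cal$demographics]])
}

#' @export
print.mtm_population_spec <- function(x, ...) {
  tab <- do.call(rbind, lapply(x$strata, function(s)
    data.frame(payer = s$payer, n_population = s$n_population,
               mean_expenditure = round(s$mean_expenditure),
               mean_hosp = round(s$mean_hospitalizations, 3))))
  cat("Eligible-population specification (base year ", x$base_year, ")\n",
      sep = "")
  cat("  total weighted N: ",
      format(sum(tab$n_population), big.mark = ","), "\n", sep = "")
  cat("  expenditure family: ", x$expenditure_distribution,
      "; hospitalization family: ", x$hospitalization_distribution,
      "; copula rho = ", x$utilization_correlation, "\n", sep = "")
  print(tab, row.names = FALSE)
  invisible(x)
}

# total weighted population of a spec
.spec_total_n <- function(spec)
  sum(vapply(spec$strata, `[[`, 0, "n_population"))

# weighted aggregate moments implied by a spec (means only)
.spec_aggregate <- function(spec) {
  n <- vapply(spec$strata, `[[`, 0, "n_population")
  w <- n / sum(n)
  list(mean_expenditure =
         sum(w * vapply(spec$strata, `[[`, 0, "mean_expenditure")),
       mean_hospitalizations =
         sum(w * vapply(spec$strata, `[[`, 0, "mean_hospitalizations")))
}
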
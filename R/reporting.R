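# Result formatting, configuration handling, run manifests.

.round_to <- function(x, unit) round(x / unit) * unit

.fmt_count <- function(x)
  formatC(.round_to(x, 1000), format = "d", big.mark = " ")

.fmt_billions <- function(x)
  formatC(.round_to(x, 1e8) / 1e9, format = "f", digits = 1)

#' Format simulation results in the published table conventions
#'
#' Hospitalization counts are rounded to the nearest 1,000 and dollar
#' quantities to the nearest $100M (displayed in billions), with
#' uncertainty intervals rendered as `"mean (low to high)"`. Rounding is
#' presentation-only: the unrounded values are returned alongside.
#'
#' @param result An `mtm_sim` or `mtm_multiyear` object, or a long summary
#'   data.frame with columns `stratum`, `quantity`, `mean`, `ui_low`,
#'   `ui_high`.
#' @return A list of class `mtm_result_table` with elements `formatted`
#'   (character table, one row per stratum) and `raw` (the unrounded long
#'   summary).
#' @export
format_result_table <- function(result) {
  raw <- if (inherits(result, "mtm_sim")) result$summary
         else if (inherits(result, "mtm_multiyear")) result$cumulative
         else result
  fmt_cell <- function(q, m, lo, hi) {
    f <- if (q == "averted_hospitalizations") .fmt_count else .fmt_billions
    paste0(f(m), " (", f(lo), " to ", f(hi), ")")
  }
  strata <- unique(raw$stratum)
  rows <- lapply(strata, function(s) {
    sub <- raw[raw$stratum == s, ]
    cells <- vapply(.mtm_quantities, function(q) {
      r <- sub[sub$quantity == q, ]
      fmt_cell(q, r$mean, r$ui_low, r$ui_high)
    }, "")
    data.frame(stratum = s,
               averted_hospitalizations = cells[1],
               averted_expenditures_bn = cells[2],
               program_cost_bn = cells[3],
               net_savings_bn = cells[4],
               stringsAsFactors = FALSE)
  })
  structure(list(formatted = do.call(rbind, rows), raw = raw),
            class = "mtm_result_table")
}

#' @export
print.mtm_result_table <- function(x, ...) {
  print(x$formatted, row.names = FALSE)
  invisible(x)
}

# configuration -------------------------------------------------------------

.config_schema <- list(
  population = c("primary_2019", "food_insecure_2017", "diabetes_only",
                 "chf_only"),
  n_records = NULL,
  utilization_correlation = NULL,
  effects = list(expenditure = c("estimate", "ci_low", "ci_high"),
                 hospitalization = c("estimate", "ci_low", "ci_high")),
  costs = c("screening_cost_low", "screening_cost_high",
            "monthly_meal_cost_mean", "monthly_meal_cost_sd",
            "months_of_meals", "per_meal_cost_mean", "per_meal_cost_sd"),
  simulation = c("n_replicates", "coverage_fraction"),
  projection = c("years", "discount_rate", "carryover_fraction"))

.default_config <- function() {
  eff <- default_pooled_effects()
  ci <- default_cost_inputs()
  list(population = "primary_2019",
       n_records = 50000,
       utilization_correlation = 0.5,
       effects = list(
         expenditure = list(estimate = eff$expenditure$estimate,
                            ci_low = eff$expenditure$ci_low,
                            ci_high = eff$expenditure$ci_high),
         hospitalization = list(estimate = eff$hospitalization$estimate,
                                ci_low = eff$hospitalization$ci_low,
                                ci_high = eff$hospitalization$ci_high)),
       costs = unclass(ci)[.config_schema$costs],
       simulation = list(n_replicates = 1000, coverage_fraction = 1.0),
       projection = list(years = 10, discount_rate = 0.03,
                         carryover_fraction = 0.0))
}

.check_unknown <- function(x, allowed, path) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown configuration key(s) under '", path, "': ",
         paste(extra, collapse = ", "))
}

#' Load and validate a model configuration
#'
#' Reads a YAML (or JSON) configuration, merges it over the shipped
#' defaults, and validates every constraint; unknown keys are errors
#' (strict mode). Shipped configurations live under
#' `system.file("extdata", "config", package = "mtmsim")`.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL` for pure
#'   defaults.
#' @return A validated nested list of class `mtm_config`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
          else if (grepl("\\.json$", path)) jsonlite::read_json(
            path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  .check_unknown(user, names(.config_schema), "<top level>")
  for (sec in c("effects", "costs", "simulation", "projection")) {
    if (!is.null(user[[sec]])) {
      allowed <- .config_schema[[sec]]
      .check_unknown(user[[sec]],
                     if (is.list(allowed)) names(allowed) else allowed, sec)
      if (sec == "effects")
        for (o in names(user$effects))
          .check_unknown(user$effects[[o]], .config_schema$effects[[o]],
                         paste0("effects$", o))
    }
  }
  cfg <- .default_config()
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(cfg[[k]])) {
      for (k2 in names(user[[k]])) {
        if (is.list(user[[k]][[k2]]) && is.list(cfg[[k]][[k2]])) {
          for (k3 in names(user[[k]][[k2]]))
            cfg[[k]][[k2]][[k3]] <- user[[k]][[k2]][[k3]]
        } else cfg[[k]][[k2]] <- user[[k]][[k2]]
      }
    } else cfg[[k]] <- user[[k]]
  }
  # constraint validation, with key paths in messages
  if (!cfg$population %in% .config_schema$population)
    stop("config error at 'population': must be one of ",
         paste(.config_schema$population, collapse = ", "))
  if (cfg$costs$months_of_meals <= 0 || cfg$costs$months_of_meals > 12)
    stop("config error at 'costs$months_of_meals': must lie in (0, 12]")
  if (cfg$simulation$coverage_fraction < 0 ||
      cfg$simulation$coverage_fraction > 1)
    stop("config error at 'simulation$coverage_fraction': must lie in ",
         "[0, 1]")
  if (cfg$simulation$n_replicates < 1)
    stop("config error at 'simulation$n_replicates': must be >= 1")
  if (cfg$n_records < 0)
    stop("config error at 'n_records': must be >= 0")
  if (cfg$projection$discount_rate < 0)
    stop("config error at 'projection$discount_rate': must be >= 0")
  if (cfg$projection$carryover_fraction < 0 ||
      cfg$projection$carryover_fraction > 1)
    stop("config error at 'projection$carryover_fraction': must lie in ",
         "[0, 1]")
  for (o in c("expenditure", "hospitalization")) {
    e <- cfg$effects[[o]]
    if (!(e$ci_low <= e$estimate && e$estimate <= e$ci_high))
      stop("config error at 'effects$", o,
           "': estimate must lie inside [ci_low, ci_high]")
  }
  structure(cfg, class = "mtm_config")
}

#' @rdname load_config
#' @param config An `mtm_config` to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# config -> model objects
.config_effects <- function(cfg) list(
  expenditure = pooled_effect("expenditure_pct_change",
                              cfg$effects$expenditure$estimate,
                              cfg$effects$expenditure$ci_low,
                              cfg$effects$expenditure$ci_high, k = 5,
                              scale = "percent_reduction"),
  hospitalization = pooled_effect("hospitalization_rr",
                                  cfg$effects$hospitalization$estimate,
                                  cfg$effects$hospitalization$ci_low,
                                  cfg$effects$hospitalization$ci_high,
                                  k = 5, scale = "percent_reduction"))

.config_costs <- function(cfg) do.call(cost_inputs, cfg$costs)

.config_population_spec <- function(cfg)
  default_population_spec(cfg$population,
                          utilization_correlation =
                            cfg$utilization_correlation)

#' Run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit: package
#' version, master seed, the resolved configuration, and MD5 digests of the
#' input and output files.
#'
#' @param seed Master seed of the run.
#' @param config Resolved `mtm_config`.
#' @param files Character vector of file paths to digest.
#' @return A list of class `mtm_manifest`.
#' @export
run_manifest <- function(seed, config, files = character()) {
  files <- files[file.exists(files)]
  structure(list(package = "mtmsim",
                 version = as.character(utils::packageVersion("mtmsim")),
                 timestamp = format(Sys.time(), tz = "UTC",
                                    usetz = TRUE),
                 seed = seed, config = unclass(config),
                 file_digests = as.list(tools::md5sum(files))),
            class = "mtm_manifest")
}

.write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
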
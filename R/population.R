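# Synthetic person-level population generator and eligibility filtering.

# Inverse-CDF truncated normal; sd = 0 degenerates to the clamped mean.
.rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# lognormal parameters matched to a given mean and sd
.lognormal_params <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# negative-binomial size/mu matched to mean and sd (requires var > mean)
.negbin_params <- function(mean, sd) {
  v <- sd^2
  if (v <= mean)
    stop("invalid parameter 'sd_hospitalizations': variance (", signif(v, 4),
         ") must exceed the mean (", signif(mean, 4),
         ") for a negative binomial")
  list(size = mean^2 / (v - mean), mu = mean)
}

# Pre-adjust Bernoulli prevalences so that the post-rejection marginals
# (conditioning on >=1 flag) equal the targets: solve c = 1 - prod(1 - p*c)
# by fixed point and draw at p*c; the conditional marginal is then p*c/c = p.
.adjust_prevalences <- function(p) {
  if (any(p >= 1)) return(p)  # a sure flag disables the rejection step
  c_ <- 1
  for (i in 1:100) {
    c_new <- 1 - prod(1 - p * c_)
    if (abs(c_new - c_) < 1e-12) break
    c_ <- c_new
  }
  p * c_
}

# integer allocation proportional to shares, largest-remainder rule
.allocate <- function(n, shares) {
  q <- n * shares / sum(shares)
  out <- floor(q)
  left <- n - sum(out)
  if (left > 0) {
    ord <- order(q - out, decreasing = TRUE)
    out[ord[seq_len(left)]] <- out[ord[seq_len(left)]] + 1
  }
  out
}

.empty_person_table <- function() {
  cols <- c("person_id", "weight", "payer", "age_years", "sex",
            "race_ethnicity", "census_region", "annual_expenditure",
            "annual_hospitalizations", "annual_ed_visits",
            paste0("dx_", .mtm_diagnoses), "iadl_limited", "food_insecure")
  out <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
  names(out) <- cols
  for (ch in c("person_id", "payer", "sex", "race_ethnicity",
               "census_region"))
    out[[ch]] <- character(0)
  for (nm in c("weight", "age_years", "annual_expenditure",
               "annual_hospitalizations", "annual_ed_visits"))
    out[[nm]] <- numeric(0)
  for (lg in c(paste0("dx_", .mtm_diagnoses), "iadl_limited",
               "food_insecure"))
    out[[lg]] <- logical(0)
  out
}

#' Generate a synthetic eligible population
#'
#' Draws `n_records` person-level records emulating the MTM-eligible
#' population described by `spec`. Expenditures and hospitalization counts
#' are drawn per payer stratum from moment-matched marginals (lognormal /
#' negative binomial by default) linked by a Gaussian copula; diagnosis flags
#' are independent Bernoulli draws with a rejection step forcing at least
#' one flag per record (draw probabilities are pre-adjusted by a fixed-point
#' calibration so the post-rejection marginal prevalences equal the spec
#' targets); every record has
#' `iadl_limited = TRUE` (eligibility by construction). Weights are uniform
#' within stratum and scale exactly to the stratum population count.
#'
#' @param spec An [population_spec()] object.
#' @param n_records Number of records to generate (>= 0). Records are
#'   allocated to strata proportionally to stratum population.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A data.frame, one row per person, with columns `person_id`,
#'   `weight`, `payer`, `age_years`, `sex`, `race_ethnicity`,
#'   `census_region`, `annual_expenditure`, `annual_hospitalizations`,
#'   `annual_ed_visits`, the `dx_*` diagnosis flags, `iadl_limited` and
#'   `food_insecure`.
#' @examples
#' pop <- generate_population(default_population_spec(), 2000, seed = 1)
#' sum(pop$weight)  # 6,309,998
#' @export
generate_population <- function(spec, n_records, seed) {
  stopifnot(inherits(spec, "mtm_population_spec"))
  if (!is.numeric(n_records) || n_records < 0)
    stop("'n_records' must be a non-negative count")
  n_records <- as.integer(n_records)
  if (n_records == 0L) return(.empty_person_table())
  set.seed(as.integer(seed))

  n_pop <- vapply(spec$strata, `[[`, 0, "n_population")
  n_s <- .allocate(n_records, n_pop)
  rho <- spec$utilization_correlation
  prev <- .adjust_prevalences(spec$diagnosis_prevalences)
  K <- length(prev)
  demo <- spec$demographics

  pieces <- vector("list", length(spec$strata))
  for (i in seq_along(spec$strata)) {
    s <- spec$strata[[i]]
    n <- n_s[i]
    if (n == 0L) { pieces[[i]] <- .empty_person_table(); next }

    # correlated uniforms via Gaussian copula
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    u_exp <- stats::pnorm(z1)
    u_hosp <- stats::pnorm(z2)

    exp_draw <- switch(spec$expenditure_distribution,
      lognormal = {
        p <- .lognormal_params(s$mean_expenditure, s$sd_expenditure)
        stats::qlnorm(u_exp, p$meanlog, p$sdlog)
      },
      gamma = {
        shape <- (s$mean_expenditure / s$sd_expenditure)^2
        stats::qgamma(u_exp, shape = shape,
                      rate = shape / s$mean_expenditure)
      })
    hosp_draw <- switch(spec$hospitalization_distribution,
      negative_binomial = {
        p <- .negbin_params(s$mean_hospitalizations, s$sd_hospitalizations)
        stats::qnbinom(u_hosp, size = p$size, mu = p$mu)
      },
      poisson = stats::qpois(u_hosp, s$mean_hospitalizations))

    # ED visits: generator realism only, negative binomial at the published
    # primary moments; not used by the simulation engine
    edp <- .negbin_params(0.98, 1.68)
    ed_draw <- stats::rnbinom(n, size = edp$size, mu = edp$mu)

    dx <- matrix(stats::runif(n * K) < rep(prev, each = n), n, K)
    bad <- which(rowSums(dx) == 0L)
    while (length(bad)) {
      dx[bad, ] <- matrix(stats::runif(length(bad) * K) <
                            rep(prev, each = length(bad)), length(bad), K)
      bad <- bad[rowSums(dx[bad, , drop = FALSE]) == 0L]
    }
    colnames(dx) <- paste0("dx_", names(prev))

    fi <- stats::runif(n) < spec$food_insecurity_prevalence

    if (!is.null(demo)) {
      age <- .rtnorm(n, demo$age_mean, demo$age_sd, lower = 18, upper = 105)
      sex <- sample(names(demo$sex), n, TRUE, prob = demo$sex)
      race <- sample(names(demo$race_ethnicity), n, TRUE,
                     prob = demo$race_ethnicity)
      region <- sample(names(demo$census_region), n, TRUE,
                       prob = demo$census_region)
    } else {
      age <- rep(65, n); sex <- rep("unknown", n)
      race <- rep("unknown", n); region <- rep("unknown", n)
    }

    piece <- data.frame(
      person_id = NA_character_,
      weight = rep(s$n_population / n, n),
      payer = rep(s$payer, n),
      age_years = age, sex = sex, race_ethnicity = race,
      census_region = region,
      annual_expenditure = exp_draw,
      annual_hospitalizations = as.numeric(hosp_draw),
      annual_ed_visits = as.numeric(ed_draw),
      stringsAsFactors = FALSE)
    piece <- cbind(piece, as.data.frame(dx))
    piece$iadl_limited <- TRUE
    piece$food_insecure <- fi
    pieces[[i]] <- piece
  }
  out <- do.call(rbind, pieces)
  out$person_id <- sprintf("P%07d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Eligibility criteria
#'
#' @param required_diagnoses Non-empty character vector of diagnosis flags
#'   (any-of semantics), subset of the nine diet-sensitive flags.
#' @param require_iadl Require an IADL limitation (default `TRUE`).
#' @param require_food_insecurity Require food insecurity (default `FALSE`;
#'   the secondary-analysis restriction).
#' @return A list of class `mtm_eligibility_criteria`.
#' @export
eligibility_criteria <- function(required_diagnoses = .mtm_diagnoses,
                                 require_iadl = TRUE,
                                 require_food_insecurity = FALSE) {
  if (!length(required_diagnoses))
    stop("'required_diagnoses' must be non-empty")
  bad <- setdiff(required_diagnoses, .mtm_diagnoses)
  if (length(bad))
    stop("unknown diagnosis flag(s): ", paste(bad, collapse = ", "))
  structure(list(required_diagnoses = required_diagnoses,
                 require_iadl = isTRUE(require_iadl),
                 require_food_insecurity = isTRUE(require_food_insecurity)),
            class = "mtm_eligibility_criteria")
}

#' Filter a person table by eligibility criteria
#'
#' Keeps exactly the records with at least one required diagnosis flag, an
#' IADL limitation if required, and food insecurity if required. Row order
#' and weights are untouched.
#'
#' @param records A person table (see [generate_population()]).
#' @param criteria An [eligibility_criteria()] object.
#' @return The qualifying subset of `records`.
#' @export
apply_eligibility_filter <- function(records, criteria) {
  stopifnot(inherits(criteria, "mtm_eligibility_criteria"))
  if (!nrow(records)) return(records)
  dx_cols <- paste0("dx_", criteria$required_diagnoses)
  has_dx <- rowSums(as.matrix(records[, dx_cols, drop = FALSE])) > 0
  keep <- has_dx
  if (criteria$require_iadl) keep <- keep & records$iadl_limited
  if (criteria$require_food_insecurity) keep <- keep & records$food_insecure
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# columns that must be present in a person-table CSV
.mandatory_person_cols <- function()
  c("person_id", "weight", "payer", "annual_expenditure",
    "annual_hospitalizations", paste0("dx_", .mtm_diagnoses),
    "iadl_limited", "food_insecure")

.person_logical_cols <- function()
  c(paste0("dx_", .mtm_diagnoses), "iadl_limited", "food_insecure")

#' Read / write person-level tables as CSV
#'
#' The CSV schema has one column per person-record field with logical flags
#' encoded 0/1 and a mandatory header row. `write_person_table()` followed by
#' `read_person_table()` is the identity on valid tables; unknown columns are
#' ignored with a warning.
#'
#' @param path File path.
#' @param records A person table.
#' @return `read_person_table()` returns the person table;
#'   `write_person_table()` returns `path` invisibly.
#' @export
read_person_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  missing_cols <- setdiff(.mandatory_person_cols(), names(raw))
  if (length(missing_cols))
    stop("person table schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  known <- names(.empty_person_table())
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
    raw <- raw[, setdiff(names(raw), extra), drop = FALSE]
  }
  for (nm in c("weight", "annual_expenditure", "annual_hospitalizations",
               "annual_ed_visits", "age_years")) {
    if (!nm %in% names(raw)) next
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(v) & !is.na(raw[[nm]]) & raw[[nm]] != "")
    if (length(bad))
      stop("parse error in column '", nm, "' at row ", bad[1],
           ": non-numeric value '", raw[[nm]][bad[1]], "'")
    raw[[nm]] <- v
  }
  for (nm in intersect(.person_logical_cols(), names(raw)))
    raw[[nm]] <- as.logical(as.integer(raw[[nm]]))
  raw$person_id <- as.character(raw$person_id)
  # stable column order where possible
  raw[, intersect(known, names(raw)), drop = FALSE]
}

#' @rdname read_person_table
#' @export
write_person_table <- function(records, path) {
  out <- records
  for (nm in intersect(.person_logical_cols(), names(out)))
    out[[nm]] <- as.integer(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# weighted helpers ----------------------------------------------------------

.wmean <- function(x, w) sum(w * x) / sum(w)

.wsd <- function(x, w) {
  m <- .wmean(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

.wquantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], 0)
}

#' Weighted descriptive summary of a person table
#'
#' Weighted N, mean (SD) and median (IQR) of annual expenditures,
#' hospitalizations and ED visits, payer-stratum shares and diagnosis
#' prevalences, all using the record weights.
#'
#' @param records A non-empty person table.
#' @return A list of class `mtm_population_summary` with data.frames
#'   `utilization`, `strata` and `diagnoses`, plus `weighted_n`.
#' @export
population_summary <- function(records) {
  if (!nrow(records)) stop("empty population: no records to summarize")
  w <- records$weight
  util <- do.call(rbind, lapply(
    c(annual_expenditure = "annual_expenditure",
      annual_hospitalizations = "annual_hospitalizations",
      annual_ed_visits = "annual_ed_visits"),
    function(col) {
      if (!col %in% names(records)) return(NULL)
      x <- records[[col]]
      q <- .wquantile(x, w, c(0.25, 0.5, 0.75))
      data.frame(variable = col, mean = .wmean(x, w), sd = .wsd(x, w),
                 median = q[2], q25 = q[1], q75 = q[3],
                 stringsAsFactors = FALSE)
    }))
  rownames(util) <- NULL
  strat <- stats::aggregate(list(weight = w),
                            by = list(payer = records$payer), FUN = sum)
  strat$share <- strat$weight / sum(w)
  dx_cols <- grep("^dx_", names(records), value = TRUE)
  dxprev <- vapply(dx_cols, function(cn) .wmean(records[[cn]], w), 0)
  diagnoses <- data.frame(diagnosis = sub("^dx_", "", dx_cols),
                          prevalence = unname(dxprev),
                          stringsAsFactors = FALSE)
  structure(list(weighted_n = sum(w), n_records = nrow(records),
                 utilization = util, strata = strat, diagnoses = diagnoses,
                 food_insecure_share =
                   if ("food_insecure" %in% names(records))
                     .wmean(records$food_insecure, w) else NA_real_),
            class = "mtm_population_summary")
}

#' @export
print.mtm_population_summary <- function(x, ...) {
  cat("Weighted N:", format(round(x$weighted_n), big.mark = ","),
      " (", x$n_records, " records)\n", sep = "")
  cat("\nUtilization and expenditures (weighted):\n")
  print(transform(x$utilization, mean = signif(mean, 5),
                  sd = signif(sd, 5)), row.names = FALSE)
  cat("\nPayer strata:\n")
  print(transform(x$strata, share = round(share, 3)), row.names = FALSE)
  cat("\nDiagnosis prevalences:\n")
  print(transform(x$diagnoses, prevalence = round(prevalence, 3)),
        row.names = FALSE)
  invisible(x)
}
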
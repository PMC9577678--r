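# Shared fixtures and independent oracles, all built in code.

# Six hand-written toy persons: two diabetes+IADL, one diabetes only, one
# IADL only, one neither, one CHF+IADL+food-insecure.
toy_person_table <- function() {
  dx0 <- setNames(as.list(rep(FALSE, 9)),
                  paste0("dx_", c("diabetes", "chf", "mi", "other_heart",
                                  "stroke", "cancer", "emphysema", "ckd",
                                  "hiv")))
  mk <- function(id, payer, exp, hosp, iadl, fi, ...) {
    dx <- utils::modifyList(dx0, list(...))
    cbind(data.frame(person_id = id, weight = 1, payer = payer,
                     age_years = 70, sex = "female",
                     race_ethnicity = "nh_white", census_region = "south",
                     annual_expenditure = exp,
                     annual_hospitalizations = hosp,
                     annual_ed_visits = 0, stringsAsFactors = FALSE),
          as.data.frame(dx),
          data.frame(iadl_limited = iadl, food_insecure = fi))
  }
  rbind(mk("T1", "private", 10000, 1, TRUE, FALSE, dx_diabetes = TRUE),
        mk("T2", "medicare", 20000, 0, TRUE, FALSE, dx_diabetes = TRUE),
        mk("T3", "medicaid", 30000, 2, FALSE, FALSE, dx_diabetes = TRUE),
        mk("T4", "dual", 40000, 0, TRUE, FALSE),
        mk("T5", "private", 50000, 3, FALSE, FALSE),
        mk("T6", "medicare", 60000, 1, TRUE, TRUE, dx_chf = TRUE))
}

# Independent DerSimonian-Laird evaluation, written directly from the
# moment-estimator formulas (no shared code with pool_random_effects).
dl_oracle <- function(est, se) {
  w <- se^-2
  theta_f <- sum(w * est) / sum(w)
  Q <- sum(w * (est - theta_f)^2)
  k <- length(est)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(estimate = sum(ws * est) / sum(ws), tau2 = tau2,
       se = 1 / sqrt(sum(ws)), Q = Q)
}

# small fast population for engine tests
small_population <- function(n = 4000, seed = 42)
  generate_population(default_population_spec(), n, seed = seed)
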
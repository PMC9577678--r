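# Calibration constants for the shipped population configurations.
#
# Published sources used for calibration, all 2019 USD:
#   * overall moments of the eligible population (weighted N, mean/SD of
#     annual expenditures, hospitalizations, ED visits, diagnosis
#     prevalences) from the MEPS-derived sample description table;
#   * per-payer central estimates of averted expenditures / hospitalizations
#     from the 1-year results table, used to BACK-DERIVE per-stratum baseline
#     means (stratum mean = stratum averted central value / pooled effect /
#     stratum N) because per-stratum baseline moments are not published;
#   * annual growth rates of population size and per-capita inflation-adjusted
#     expenditures by payer, from the 10-year projection assumptions.
#
# When overall moments are published for a population (primary, food-insecure
# secondary), the back-derived stratum means are rescaled by a common factor
# so that the weighted aggregate reproduces the published overall mean
# exactly; subgroup populations (diabetes-only, CHF-only) have no published
# overall moments and keep the back-derived values.

.mtm_diagnoses <- c("diabetes", "chf", "mi", "other_heart", "stroke",
                    "cancer", "emphysema", "ckd", "hiv")

.mtm_payers <- c("private", "medicare", "medicaid", "dual")

# Pooled central effects used in back-derivation (also the shipped defaults).
.mtm_central_effects <- list(expenditure = 0.197, hospitalization = 0.470)

.mtm_growth <- data.frame(
  payer = .mtm_payers,
  annual_pop_growth = c(0.010, 0.021, 0.030, 0.057),
  annual_per_capita_expenditure_growth = c(0.015, 0.017, 0.035, 0.039),
  stringsAsFactors = FALSE
)

.mtm_demographics <- list(
  primary = list(
    age_mean = 68.1, age_sd = 16.6,
    sex = c(female = 0.634, male = 0.366),
    race_ethnicity = c(hispanic = 0.113, nh_asian = 0.031, nh_black = 0.142,
                       nh_white = 0.667, other_multiple = 0.047),
    census_region = c(northeast = 0.178, midwest = 0.202, south = 0.394,
                      west = 0.226)
  ),
  secondary = list(
    age_mean = 60.5, age_sd = 15.5,
    sex = c(female = 0.637, male = 0.363),
    race_ethnicity = c(hispanic = 0.193, nh_asian = 0.039, nh_black = 0.254,
                       nh_white = 0.451, other_multiple = 0.063),
    census_region = c(northeast = 0.154, midwest = 0.305, south = 0.362,
                      west = 0.179)
  )
)

.mtm_populations <- list(
  primary_2019 = list(
    base_year = 2019,
    strata = data.frame(
      payer = .mtm_payers,
      n_population = c(1485365, 2571562, 697292, 1555779),
      averted_expenditures = c(8.9e9, 13.4e9, 4.5e9, 11.9e9),
      averted_hospitalizations = c(290000, 712000, 195000, 397000),
      stringsAsFactors = FALSE
    ),
    overall = list(mean_expenditure = 31134, sd_expenditure = 34749,
                   median_expenditure = 20107,
                   mean_hospitalizations = 0.54, sd_hospitalizations = 0.94,
                   mean_ed_visits = 0.98, sd_ed_visits = 1.68),
    diagnosis_prevalences = c(diabetes = 0.449, chf = 0.268, mi = 0.213,
                              other_heart = 0.365, stroke = 0.361,
                              cancer = 0.372, emphysema = 0.107,
                              ckd = 0.013, hiv = 0.006),
    # descriptive flag only in the primary population; share chosen to mirror
    # the ratio of the food-insecure secondary population to the primary one
    food_insecurity_prevalence = 0.299,
    demographics = "primary"
  ),
  food_insecure_2017 = list(
    base_year = 2017,
    strata = data.frame(
      payer = .mtm_payers,
      n_population = c(330587, 587828, 286066, 683200),
      averted_expenditures = c(2.7e9, 3.1e9, 2.8e9, 4.4e9),
      averted_hospitalizations = c(78000, 167000, 117000, 144000),
      stringsAsFactors = FALSE
    ),
    overall = list(mean_expenditure = 33634, sd_expenditure = 48978,
                   median_expenditure = 19153,
                   mean_hospitalizations = 0.59, sd_hospitalizations = 1.02,
                   mean_ed_visits = 1.09, sd_ed_visits = 1.85),
    diagnosis_prevalences = c(diabetes = 0.518, chf = 0.194, mi = 0.196,
                              other_heart = 0.389, stroke = 0.223,
                              cancer = 0.243, emphysema = 0.161,
                              ckd = 0.016, hiv = 0.012),
    food_insecurity_prevalence = 1.0,
    demographics = "secondary"
  ),
  diabetes_only = list(
    base_year = 2019,
    strata = data.frame(
      payer = .mtm_payers,
      n_population = c(636320, 1001345, 368460, 824381),
      averted_expenditures = c(4.3e9, 5.6e9, 2.5e9, 7.0e9),
      averted_hospitalizations = c(118000, 304000, 63000, 216000),
      stringsAsFactors = FALSE
    ),
    overall = NULL,  # subgroup moments unpublished; back-derived values kept
    diagnosis_prevalences = c(diabetes = 1.0, chf = 0.268, mi = 0.213,
                              other_heart = 0.365, stroke = 0.361,
                              cancer = 0.372, emphysema = 0.107,
                              ckd = 0.013, hiv = 0.006),
    food_insecurity_prevalence = 0.299,
    demographics = "primary"
  ),
  chf_only = list(
    base_year = 2019,
    strata = data.frame(
      payer = .mtm_payers,
      n_population = c(374445, 871058, 119035, 330745),
      averted_expenditures = c(2.5e9, 5.0e9, 0.7e9, 2.6e9),
      averted_hospitalizations = c(77000, 288000, 37900, 127000),
      stringsAsFactors = FALSE
    ),
    overall = NULL,
    diagnosis_prevalences = c(diabetes = 0.449, chf = 1.0, mi = 0.213,
                              other_heart = 0.365, stroke = 0.361,
                              cancer = 0.372, emphysema = 0.107,
                              ckd = 0.013, hiv = 0.006),
    food_insecurity_prevalence = 0.299,
    demographics = "primary"
  )
)

# Coefficients of variation of the primary population, reused for strata and
# for subgroup populations whose SDs are unpublished.
.mtm_cv <- list(expenditure = 34749 / 31134, hospitalizations = 0.94 / 0.54)
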
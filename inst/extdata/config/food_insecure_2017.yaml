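# Secondary eligible population, 2017: adds food insecurity as an
# eligibility criterion (weighted N 1,887,681).
population: food_insecure_2017
n_records: 50000            # synthetic person-level sample size
utilization_correlation: 0.5  # Gaussian-copula rho, expenditures x hospitalizations (modeling choice; joint distribution unpublished)

effects:
  expenditure:              # pooled % reduction in annual expenditures, 5-study random-effects meta-analysis
    estimate: 0.197
    ci_low: 0.069
    ci_high: 0.324
  hospitalization:          # pooled % reduction in annual hospitalizations
    estimate: 0.470
    ci_low: 0.317
    ci_high: 0.623

costs:
  screening_cost_low: 27.34    # Medicare medical-nutrition-therapy reimbursement, lowest locality
  screening_cost_high: 35.17   # highest locality
  monthly_meal_cost_mean: 487.60  # calibrated monthly contract anchor (back-solved from published total program cost)
  monthly_meal_cost_sd: 18.70  # calibrated so program-cost 95% UI half-width ~7.5% of mean
  months_of_meals: 8           # participant-weighted mean duration of MTM receipt
  per_meal_cost_mean: 9.30     # pooled per-meal contract cost
  per_meal_cost_sd: 0.64

simulation:
  n_replicates: 1000
  coverage_fraction: 1.0

projection:
  years: 10
  discount_rate: 0.03          # primary; 0 and 0.05 as sensitivity analyses
  carryover_fraction: 0.0      # 0.15 in the sustained-benefit sensitivity analysis
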
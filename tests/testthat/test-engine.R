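# One-year Monte Carlo policy engine.

test_that("effect draws reproduce their pooled uncertainty", {
  eff <- default_pooled_effects()
  # degenerate: zero-width uncertainty returns the point estimates
  pe0 <- pooled_effect("expenditure_pct_change", 0.197, 0.197 - 1e-12,
                       0.197 + 1e-12)
  ph0 <- pooled_effect("hospitalization_rr", 0.470, 0.470 - 1e-12,
                       0.470 + 1e-12)
  set.seed(1)
  d0 <- draw_effects(pe0, ph0, n = 4)
  expect_equal(d0$expenditure_reduction, rep(0.197, 4), tolerance = 1e-6)
  expect_equal(d0$hospitalization_reduction, rep(0.470, 4),
               tolerance = 1e-6)

  set.seed(2)
  d <- draw_effects(eff$expenditure, eff$hospitalization, n = 10000)
  q <- quantile(d$expenditure_reduction, c(0.025, 0.975))
  expect_equal(unname(q), c(0.069, 0.324), tolerance = 0.03)

  # truncation: estimate near 0 never yields negative draws
  pe_low <- pooled_effect("expenditure_pct_change", 0.02,
                          0.02 - qnorm(0.975) * 0.05,
                          0.02 + qnorm(0.975) * 0.05)
  set.seed(3)
  dl <- draw_effects(pe_low, ph0, n = 5000)
  expect_true(all(dl$expenditure_reduction >= 0))
})

test_that("a single replicate matches hand arithmetic on a toy table", {
  toy <- toy_person_table()
  eff <- effect_draws(0.2, 0.5)
  costs <- cost_draw(30, 400)
  rep1 <- simulate_replicate(toy, eff, costs, coverage_fraction = 1,
                             months_of_meals = 8)
  tot <- rep1[rep1$stratum == "total", ]
  # weights are all 1: sums are plain sums over the six records
  expect_equal(tot$averted_hospitalizations, 0.5 * 7)
  expect_equal(tot$averted_expenditures, 0.2 * 210000)
  expect_equal(tot$program_cost, 6 * (8 * 400 + 30))
  expect_equal(tot$net_savings, 0.2 * 210000 - 6 * (8 * 400 + 30))

  # zero effects: nothing averted, net = -cost
  z <- simulate_replicate(toy, effect_draws(0, 0), costs)
  zt <- z[z$stratum == "total", ]
  expect_equal(zt$averted_hospitalizations, 0)
  expect_equal(zt$averted_expenditures, 0)
  expect_equal(zt$net_savings, -zt$program_cost)
})

test_that("replicate summaries use mean and type-7 percentiles", {
  expect_equal(unlist(summarize_simulations(rep(5, 100))),
               c(mean = 5, ui_low = 5, ui_high = 5))
  s <- summarize_simulations(1:1000)
  expect_equal(s$mean, 500.5)
  expect_equal(s$ui_low, unname(quantile(1:1000, 0.025, type = 7)))
  set.seed(8)
  z <- rnorm(100000)
  sz <- summarize_simulations(z)
  expect_equal(c(sz$ui_low, sz$ui_high), c(-1.96, 1.96), tolerance = 0.03)
})

test_that("Monte Carlo aggregation satisfies the accounting invariants", {
  pop <- small_population()
  sim <- run_monte_carlo(pop, n_replicates = 150, seed = 21)
  reps <- sim$replicates
  strata <- setdiff(dimnames(reps)[[2]], "total")

  # net = averted expenditures - program cost, exactly, in every replicate
  expect_equal(reps[, , "net_savings"],
               reps[, , "averted_expenditures"] - reps[, , "program_cost"])
  # total = sum of strata for all quantities, every replicate
  for (q in dimnames(reps)[[3]])
    expect_equal(reps[, "total", q],
                 rowSums(reps[, strata, q]), tolerance = 1e-12)
  # ui_low <= mean <= ui_high throughout
  expect_true(all(sim$summary$ui_low <= sim$summary$mean + 1e-9))
  expect_true(all(sim$summary$mean <= sim$summary$ui_high + 1e-9))
})

test_that("fixed seeds reproduce bit-identical results", {
  pop <- small_population()
  s1 <- run_monte_carlo(pop, n_replicates = 60, seed = 5)
  s2 <- run_monte_carlo(pop, n_replicates = 60, seed = 5)
  expect_identical(s1$replicates, s2$replicates)
  expect_identical(s1$summary, s2$summary)
})

test_that("coverage scales every replicate linearly", {
  pop <- small_population()
  full <- run_monte_carlo(pop, n_replicates = 60, seed = 9,
                          coverage_fraction = 1)
  half <- run_monte_carlo(pop, n_replicates = 60, seed = 9,
                          coverage_fraction = 0.5)
  expect_equal(half$replicates, full$replicates / 2, tolerance = 1e-12)
  zero <- run_monte_carlo(pop, n_replicates = 10, seed = 9,
                          coverage_fraction = 0)
  expect_true(all(zero$replicates == 0))
})

test_that("degenerate inputs collapse every uncertainty interval", {
  pop <- small_population()
  eff <- list(
    expenditure = pooled_effect("expenditure_pct_change", 0.197,
                                0.197 - 1e-12, 0.197 + 1e-12),
    hospitalization = pooled_effect("hospitalization_rr", 0.470,
                                    0.470 - 1e-12, 0.470 + 1e-12))
  ci <- cost_inputs(screening_cost_low = 31.255,
                    screening_cost_high = 31.255,
                    monthly_meal_cost_sd = 0)
  sim <- run_monte_carlo(pop, eff, ci, n_replicates = 50, seed = 3,
                         baseline_uncertainty = "none")
  expect_equal(sim$summary$ui_low, sim$summary$mean, tolerance = 1e-6)
  expect_equal(sim$summary$ui_high, sim$summary$mean, tolerance = 1e-6)
  # and the collapsed point equals the deterministic central run
  ce <- central_estimate(pop, eff, ci)
  tot <- sim$summary[sim$summary$stratum == "total", ]
  expect_equal(tot$mean[tot$quantity == "net_savings"],
               ce$net_savings[ce$stratum == "total"], tolerance = 1e-6)
})

test_that("replicate means converge to the closed-form point estimate", {
  pop <- small_population()
  sim <- run_monte_carlo(pop, n_replicates = 400, seed = 31)
  ce <- central_estimate(pop)
  for (q in c("averted_expenditures", "averted_hospitalizations")) {
    x <- sim$replicates[, "total", q]
    mc_se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - ce[[q]][ce$stratum == "total"]), 2.5 * mc_se)
  }
})

test_that("monotonicity: larger effects and cheaper meals help", {
  toy <- toy_person_table()
  costs <- cost_draw(30, 400)
  lo <- simulate_replicate(toy, effect_draws(0.1, 0.3), costs)
  hi <- simulate_replicate(toy, effect_draws(0.3, 0.6), costs)
  expect_true(all(hi$averted_expenditures >= lo$averted_expenditures))
  expect_true(all(hi$averted_hospitalizations >=
                    lo$averted_hospitalizations))
  dear <- simulate_replicate(toy, effect_draws(0.1, 0.3),
                             cost_draw(30, 600))
  expect_true(all(dear$net_savings <= lo$net_savings))
})
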
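# Growth fitting, projection, discounting, multi-year engine.

test_that("log-linear growth fitting recovers known rates", {
  expect_equal(fit_loglinear_growth(
    data.frame(year = 2010:2019, value = rep(100, 10))), 0)
  # noiseless exponential: machine-precision recovery
  expect_equal(fit_loglinear_growth(
    data.frame(year = 0:9, value = 100 * 1.03^(0:9))), 0.03,
    tolerance = 1e-12)
  # 2% multiplicative noise: within +/- 0.01
  hist <- simulate_expenditure_history(30000, 0.03, 2010:2019,
                                       noise_sd = 0.02, seed = 17)
  expect_lt(abs(fit_loglinear_growth(hist) - 0.03), 0.01)

  expect_error(fit_loglinear_growth(
    data.frame(year = 1:3, value = c(1, -1, 2))), "domain")
  expect_error(fit_loglinear_growth(
    data.frame(year = 1, value = 5)), "insufficient")
})

test_that("project_year applies geometric growth per stratum", {
  spec <- default_population_spec()
  growth <- default_growth_models()
  expect_identical(project_year(spec, growth, 0), spec)

  p9 <- project_year(spec, growth, 9)
  expect_equal(p9$strata$dual$n_population,
               spec$strata$dual$n_population * 1.057^9)
  expect_equal(1.057^9, 1.647, tolerance = 1e-3)
  # expenditures: mean and SD scale together (constant CV)
  expect_equal(p9$strata$private$mean_expenditure,
               spec$strata$private$mean_expenditure * 1.015^9)
  expect_equal(p9$strata$private$sd_expenditure /
                 p9$strata$private$mean_expenditure,
               spec$strata$private$sd_expenditure /
                 spec$strata$private$mean_expenditure)
  # hospitalization rates held constant (open cohort)
  expect_equal(p9$strata$medicare$mean_hospitalizations,
               spec$strata$medicare$mean_hospitalizations)

  # geometric-series oracle over the 10-year private multipliers
  mults <- sapply(0:9, function(t)
    project_year(spec, growth, t)$strata$private$n_population /
      spec$strata$private$n_population)
  expect_equal(sum(mults), (1.01^10 - 1) / 0.01, tolerance = 1e-10)
  expect_equal(sum(mults), 10.462, tolerance = 1e-4)
})

test_that("discounting follows the base-year convention", {
  expect_equal(discount_value(100, 0, 0:5), rep(100, 6))
  expect_equal(discount_value(100, 0.03, 1), 97.087, tolerance = 1e-4)
  expect_equal(discount_value(100, 0.07, 0), 100)
  expect_error(discount_value(100, -0.01, 1), ">= 0")
})

test_that("a 1-year horizon reproduces the 1-year engine exactly", {
  pop <- small_population()
  my <- simulate_multi_year(pop, years = 1, n_replicates = 40, seed = 12)
  sim <- run_monte_carlo(pop, n_replicates = 40, seed = 12)
  expect_equal(my$replicates_cumulative, sim$replicates)
  expect_equal(my$cumulative, sim$summary)
})

test_that("degenerate 2-year run is exactly additive and closes the geometric series", {
  pop <- small_population()
  eff <- list(
    expenditure = pooled_effect("expenditure_pct_change", 0.197,
                                0.197 - 1e-12, 0.197 + 1e-12),
    hospitalization = pooled_effect("hospitalization_rr", 0.470,
                                    0.470 - 1e-12, 0.470 + 1e-12))
  ci <- cost_inputs(screening_cost_low = 31.255,
                    screening_cost_high = 31.255,
                    monthly_meal_cost_sd = 0)
  zero_growth <- lapply(default_growth_models(), function(g)
    growth_model(g$payer, 0, 0))
  my <- simulate_multi_year(pop, zero_growth, eff, ci, years = 2,
                            discount_rate = 0, n_replicates = 5,
                            seed = 4, baseline_uncertainty = "none")
  y1 <- run_monte_carlo(pop, eff, ci, n_replicates = 5, seed = 4,
                        baseline_uncertainty = "none")
  expect_equal(my$replicates_cumulative, 2 * y1$replicates,
               tolerance = 1e-9)

  # geometric closure: growth + discounting, degenerate draws
  growth <- default_growth_models()
  my10 <- simulate_multi_year(pop, growth, eff, ci, years = 10,
                              discount_rate = 0.03, n_replicates = 2,
                              seed = 4, baseline_uncertainty = "none")
  ce <- central_estimate(pop, eff, ci)
  for (p in c("private", "medicare", "medicaid", "dual")) {
    gp <- growth[[p]]$annual_pop_growth
    ge <- growth[[p]]$annual_per_capita_expenditure_growth
    mult_ae <- sum(((1 + gp) * (1 + ge) / 1.03)^(0:9))
    got <- my10$cumulative
    got <- got[got$stratum == p & got$quantity == "averted_expenditures",
               "mean"]
    expect_equal(got, ce$averted_expenditures[ce$stratum == p] * mult_ae,
                 tolerance = 1e-9)
    mult_h <- sum((1 + gp)^(0:9))  # undiscounted
    goth <- my10$cumulative
    goth <- goth[goth$stratum == p &
                   goth$quantity == "averted_hospitalizations", "mean"]
    expect_equal(goth,
                 ce$averted_hospitalizations[ce$stratum == p] * mult_h,
                 tolerance = 1e-9)
  }
})

test_that("discounting is monotone for dollars and inert for counts", {
  pop <- small_population(n = 2000)
  runs <- lapply(c(0, 0.03, 0.05), function(r)
    simulate_multi_year(pop, years = 10, discount_rate = r,
                        n_replicates = 30, seed = 77))
  net <- sapply(runs, function(x) {
    s <- x$cumulative
    s[s$stratum == "total" & s$quantity == "averted_expenditures", "mean"]
  })
  expect_true(net[1] > net[2] && net[2] > net[3])
  hosp <- sapply(runs, function(x) {
    s <- x$cumulative
    s[s$stratum == "total" &
        s$quantity == "averted_hospitalizations", "mean"]
  })
  expect_equal(hosp[1], hosp[2])
  expect_equal(hosp[2], hosp[3])
})

test_that("carryover is off by default and strictly helps when on", {
  pop <- small_population(n = 2000)
  base <- simulate_multi_year(pop, years = 3, n_replicates = 25, seed = 13)
  zero <- simulate_multi_year(pop, years = 3, carryover_fraction = 0,
                              n_replicates = 25, seed = 13)
  expect_identical(base$replicates_cumulative, zero$replicates_cumulative)
  carry <- simulate_multi_year(pop, years = 3, carryover_fraction = 0.15,
                               n_replicates = 25, seed = 13)
  expect_true(all(carry$replicates_cumulative[, "total", "net_savings"] >
                    base$replicates_cumulative[, "total", "net_savings"]))
  # program cost unchanged: carryover recipients need no meals
  expect_equal(carry$replicates_cumulative[, "total", "program_cost"],
               base$replicates_cumulative[, "total", "program_cost"])
})
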
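# Synthetic-population generator, eligibility filtering, CSV round-trip.

test_that("generated moments are calibrated to the population spec", {
  spec <- default_population_spec("primary_2019")
  pop <- generate_population(spec, 50000, seed = 101)

  expect_equal(sum(pop$weight), 6309998)  # weights scaled, not sampled
  w <- pop$weight
  n <- nrow(pop)

  # weighted means within 3 standard errors of the calibration targets
  m_exp <- sum(w * pop$annual_expenditure) / sum(w)
  se_exp <- 34749 / sqrt(n)
  expect_lt(abs(m_exp - 31134), 3 * se_exp)

  m_hosp <- sum(w * pop$annual_hospitalizations) / sum(w)
  expect_lt(abs(m_hosp - 0.54), 3 * 0.94 / sqrt(n))

  # stratum shares match the spec populations
  shares <- tapply(pop$weight, pop$payer, sum) / sum(w)
  expect_equal(shares[["medicare"]], 2571562 / 6309998, tolerance = 1e-6)

  # diagnosis prevalence within 3 SE of the published target (diabetes
  # 44.9%); the rejection-step pre-adjustment keeps the marginal on target
  target <- spec$diagnosis_prevalences[["diabetes"]]
  p_hat <- sum(w * pop$dx_diabetes) / sum(w)
  expect_lt(abs(p_hat - target), 3 * sqrt(target * (1 - target) / n))

  # everyone is eligible by construction
  expect_true(all(pop$iadl_limited))
  dx <- pop[, grep("^dx_", names(pop))]
  expect_true(all(rowSums(dx) >= 1))
})

test_that("generation is deterministic and handles the empty case", {
  spec <- default_population_spec()
  expect_identical(generate_population(spec, 1000, seed = 7),
                   generate_population(spec, 1000, seed = 7))
  empty <- generate_population(spec, 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_equal(sum(empty$weight), 0)
})

test_that("lognormal moment matching implies the observed expenditure median", {
  # closed form: median = mean / sqrt(1 + cv^2)
  implied_median <- 31134 / sqrt(1 + (34749 / 31134)^2)
  expect_equal(implied_median, 20776, tolerance = 1e-4)
  expect_lt(abs(implied_median - 20107) / 20107, 0.05)

  # the generated population reproduces the implied median
  pop <- generate_population(default_population_spec(), 50000, seed = 5)
  med <- median(pop$annual_expenditure)
  expect_equal(med, implied_median, tolerance = 0.05)
})

test_that("invalid distribution parameters name the offending field", {
  expect_error(stratum_spec("private", 1000, 30000, -1, 0.5, 0.9),
               "sd_expenditure")
  expect_error(
    generate_population(
      population_spec(
        list(stratum_spec("private", 1000, 30000, 33000, 0.5, 0.55)),
        default_population_spec()$diagnosis_prevalences),
      100, seed = 1),
    "sd_hospitalizations")  # variance <= mean: negative binomial impossible
})

test_that("eligibility filter matches exhaustive enumeration on toy records", {
  toy <- toy_person_table()
  primary <- eligibility_criteria()
  kept <- apply_eligibility_filter(toy, primary)
  expect_identical(kept$person_id, c("T1", "T2", "T6"))
  expect_identical(kept$weight, rep(1, 3))  # weights untouched

  fi <- eligibility_criteria(require_food_insecurity = TRUE)
  expect_identical(apply_eligibility_filter(toy, fi)$person_id, "T6")

  diab <- eligibility_criteria(required_diagnoses = "diabetes")
  expect_identical(apply_eligibility_filter(toy, diab)$person_id,
                   c("T1", "T2"))

  # idempotence and the empty case
  expect_identical(apply_eligibility_filter(kept, primary), kept)
  expect_equal(nrow(apply_eligibility_filter(toy[0, ], primary)), 0)
})

test_that("person-table CSV round-trip is the identity", {
  toy <- toy_person_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_person_table(toy, path)
  back <- read_person_table(path)
  expect_equal(back, toy)
  expect_type(back$dx_diabetes, "logical")  # 0/1 re-read as booleans

  big <- generate_population(default_population_spec(), 500, seed = 3)
  write_person_table(big, path)
  expect_equal(read_person_table(path), big)
})

test_that("person-table schema and parse errors are informative", {
  toy <- toy_person_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_person_table(toy[, setdiff(names(toy), "weight")], path)
  expect_error(read_person_table(path), "weight")

  bad <- toy
  bad$annual_expenditure <- as.character(bad$annual_expenditure)
  bad$annual_expenditure[3] <- "oops"
  write_person_table(bad, path)
  expect_error(read_person_table(path), "row 3")

  extra <- cbind(toy, bogus = 1)
  write_person_table(extra, path)
  expect_warning(out <- read_person_table(path), "bogus")
  expect_equal(out, toy)
})

test_that("population_summary reproduces hand-computed weighted statistics", {
  toy <- toy_person_table()
  s <- population_summary(toy)
  expect_equal(s$weighted_n, 6)
  util <- s$utilization
  expect_equal(util$mean[util$variable == "annual_expenditure"], 35000)
  expect_equal(util$mean[util$variable == "annual_hospitalizations"], 7 / 6)

  one <- toy[2, ]
  one$weight <- 10
  s1 <- population_summary(one)
  expect_equal(s1$weighted_n, 10)
  expect_equal(s1$utilization$mean[1], 20000)
  expect_equal(s1$utilization$sd[1], 0)

  expect_error(population_summary(toy[0, ]), "empty")
})
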
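# Synthetic-country generator: reproducibility, configured structure, and
# the thinning mechanism that encodes the ground truth.

test_that("configuration errors name the offending field", {
  expect_error(synthetic_config(n_municipalities = 0), "n_municipalities")
  expect_error(synthetic_config(weeks_per_year = 4), "weeks_per_year")
  expect_error(synthetic_config(reporting_floor = 0), "reporting_floor")
  expect_error(synthetic_config(seasonal_amplitude = 1), "seasonal_amplitude")
  expect_error(synthetic_config(region_multipliers = c(1, -1, 1), n_regions = 3,
                                n_municipalities = 30),
               "region_multipliers")
  expect_error(synthetic_config(region_sizes = c(10, 10), n_regions = 2,
                                n_municipalities = 30), "region_sizes")
})

test_that("municipality simulation is reproducible and seed-sensitive", {
  cfg <- synthetic_config(seed = 1, n_municipalities = 10, n_regions = 2)
  a <- simulate_municipalities(cfg)
  b <- simulate_municipalities(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 10L)

  c_ <- simulate_municipalities(synthetic_config(seed = 2,
                                                 n_municipalities = 10,
                                                 n_regions = 2))
  expect_false(isTRUE(all.equal(a$population, c_$population)))
})

test_that("the default country has 152 municipalities in the configured region sizes", {
  m <- simulate_municipalities(synthetic_config(seed = 3))
  expect_equal(nrow(m), 152L)
  expect_equal(unname(table(m$region_true)[paste0("T", 1:7)]),
               table(rep(1:7, c(11, 19, 12, 14, 56, 22, 18))) |> unname())
  expect_true(all(m$population >= 500))
  expect_true(all(m$pct_rural >= 0 & m$pct_rural <= 100))
})

test_that("deprivation variables are positively rank-correlated with rurality", {
  m <- simulate_municipalities(synthetic_config(seed = 4))
  for (v in deprivation_variables()) {
    expect_gt(cor(m$pct_rural, m[[v]], method = "spearman"), 0.3)
  }
})

test_that("observed counts are a thinning of true counts; no thinning at floor 1", {
  cfg <- tiny_config(reporting_floor = 0.5)
  sim <- simulate_country(cfg)
  expect_true(all(sim$cases$cases <= sim$cases$true_cases))
  expect_true(all(sim$cases$deaths <= sim$cases$cases))

  full <- simulate_country(tiny_config(reporting_floor = 1))
  expect_identical(full$cases$cases, full$cases$true_cases)
  expect_false(any(full$truth$underreporter_flag))
})

test_that("truth table is internally consistent", {
  sim <- simulate_country(tiny_config(seed = 5))
  tr <- sim$truth
  expect_true(all(tr$reporting_prob > 0 & tr$reporting_prob <= 1))
  expect_true(all(tr$true_rate >= 0))
  expect_identical(tr$underreporter_flag,
                   tr$reporting_prob < sim$config$underreporter_cutoff)
})

test_that("zero seasonal amplitude gives a flat weekly expectation", {
  cfg <- synthetic_config(n_municipalities = 200, n_regions = 4, years = 1,
                          seed = 6, seasonal_amplitude = 0,
                          reporting_floor = 1)
  sim <- simulate_country(cfg)
  weekly <- tapply(sim$cases$cases, sim$cases$week, sum)
  # under a flat profile the 52 weekly totals are iid Poisson with a common
  # mean: the chi-square statistic stays below an extreme-tail bound
  stat <- sum((weekly - mean(weekly))^2 / mean(weekly))
  expect_lt(stat, qchisq(1 - 1e-6, df = 51))
})

test_that("national true count matches its closed-form expectation", {
  cfg <- synthetic_config(seed = 7)
  sim <- simulate_country(cfg)
  expected <- expected_national_cases(sim$municipalities, cfg)
  observed <- sum(sim$cases$true_cases)
  # Poisson total: mean = variance = sum of rates
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
})

test_that("national observed count is monotone in the reporting floor", {
  floors <- c(1, 0.875, 0.75, 0.625, 0.5)
  totals <- vapply(floors, function(f) {
    sim <- simulate_country(tiny_config(seed = 8, reporting_floor = f))
    sum(sim$cases$cases)
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("case simulation rejects a municipality table with missing columns", {
  m <- simulate_municipalities(tiny_config())
  m$pct_rural <- NULL
  expect_error(simulate_cases(m, tiny_config()), "pct_rural",
               class = "snakemap_schema_error")
})

test_that("reporting probability is 1 below the knee and decays to the floor", {
  cfg <- tiny_config(reporting_floor = 0.4, deprivation_reporting_knee = 0.6)
  u <- c(0.1, 0.6, 0.8, 1)
  p <- reporting_probability(u, cfg)
  expect_equal(p, c(1, 1, 0.7, 0.4))
})
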
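# Descriptive statistics: the national arithmetic identities, per-region
# incidence, and the circular five-week sliding mean.

test_that("national summary reproduces the printed surveillance arithmetic", {
  cs <- data.frame(municipality_id = "NAT", year = 1, week = 1,
                   cases = 3286, deaths = 34)
  m <- data.frame(municipality_id = "NAT", population = 5.9e6)
  s <- incidence_summary(cs, m, years = 5)
  expect_equal(s$cumulative_incidence_per_100k, 1e5 * 3286 / 5.9e6)
  expect_equal(round(s$cumulative_incidence_per_100k), 56)
  expect_equal(s$annual_incidence_per_100k * 5,
               s$cumulative_incidence_per_100k)
  expect_equal(round(s$mortality_per_100k, 1), 0.6)
  expect_equal(round(s$case_fatality_pct), 1)
})

test_that("an empty series yields zero incidence and a warned zero CFR", {
  cs <- data.frame(municipality_id = "A", year = 1, week = 1, cases = 0,
                   deaths = 0)
  m <- data.frame(municipality_id = "A", population = 1e5)
  expect_warning(s <- incidence_summary(cs, m), "no cases")
  expect_equal(s$cumulative_incidence_per_100k, 0)
  expect_equal(s$case_fatality_pct, 0)
})

test_that("degenerate inputs are rejected", {
  m <- data.frame(municipality_id = "A", population = 0)
  cs <- data.frame(municipality_id = "A", year = 1, week = 1, cases = 1,
                   deaths = 0)
  expect_error(incidence_summary(cs, m), class = "snakemap_schema_error")
  cs$deaths <- 5
  m$population <- 10
  expect_error(incidence_summary(cs, m), class = "snakemap_schema_error")
})

test_that("a single region reproduces the national incidence", {
  ids <- sprintf("M%03d", 1:4)
  m <- toy_municipalities(rep(0, 4), population = c(1e4, 2e4, 3e4, 4e4),
                          ids = ids)
  cs <- data.frame(municipality_id = ids, year = 1, week = 1,
                   cases = c(1, 2, 3, 4), deaths = 0)
  a <- data.frame(municipality_id = ids, region = "ALL")
  r <- regional_incidence(cs, m, a)
  s <- incidence_summary(cs, m)
  expect_equal(r$incidence_per_100k, s$cumulative_incidence_per_100k)
})

test_that("regional incidences are proportional to cases at equal population", {
  ids <- c("A", "B")
  m <- data.frame(municipality_id = ids, population = c(1e5, 1e5))
  cs <- data.frame(municipality_id = ids, year = 1, week = 1,
                   cases = c(10, 30), deaths = 0)
  a <- data.frame(municipality_id = ids, region = ids)
  r <- regional_incidence(cs, m, a)
  expect_equal(r$incidence_per_100k[r$region == "B"] /
                 r$incidence_per_100k[r$region == "A"], 3)
  expect_equal(sum(r$cases), sum(cs$cases))  # conservation
})

test_that("the region with the largest configured multiplier reports the highest incidence", {
  for (seed in 1:10) {
    cfg <- synthetic_config(seed = 60 + seed, reporting_floor = 1)
    sim <- simulate_country(cfg)
    a <- data.frame(municipality_id = sim$municipalities$municipality_id,
                    region = sim$municipalities$region_true)
    r <- regional_incidence(sim$cases, sim$municipalities, a)
    top_configured <- paste0("T", which.max(cfg$region_multipliers))
    expect_equal(r$region[which.max(r$incidence_per_100k)], top_configured)
  }
})

test_that("smoothing preserves constants and spreads a unit impulse", {
  expect_equal(seasonal_smooth(rep(3.5, 52)), rep(3.5, 52))
  x <- rep(0, 52)
  x[10] <- 1
  sm <- seasonal_smooth(x, 5)
  expect_equal(sm[8:12], rep(1 / 5, 5))
  expect_equal(sm[-(8:12)], rep(0, 47))
})

test_that("circular smoothing preserves the mean and is linear", {
  set.seed(61)
  x <- rpois(52, 10)
  y <- runif(52)
  expect_equal(mean(seasonal_smooth(x)), mean(x))
  expect_equal(seasonal_smooth(2 * x + 3 * y),
               2 * seasonal_smooth(x) + 3 * seasonal_smooth(y))
  # direct five-term averaging oracle, wrapping the year boundary
  direct <- vapply(1:52, function(i) {
    mean(x[((i + (-2:2) - 1) %% 52) + 1])
  }, numeric(1))
  expect_equal(seasonal_smooth(x, 5), direct)
})

test_that("even or oversized windows are rejected", {
  expect_error(seasonal_smooth(rep(1, 52), 4),
               class = "snakemap_parameter_error")
  expect_error(seasonal_smooth(rep(1, 3), 5),
               class = "snakemap_parameter_error")
})

test_that("seasonal profiles fold week 53 and average across years", {
  cs <- data.frame(
    municipality_id = "A",
    year = rep(1:2, each = 53),
    week = rep(1:53, 2),
    cases = 1,
    deaths = 0
  )
  prof <- seasonal_profile(cs)
  expect_equal(nrow(prof), 52)
  expect_equal(prof$mean_cases[52], 2)  # weeks 52 and 53 folded together
  expect_equal(prof$mean_cases[1:51], rep(1, 51))
})

test_that("the simulated seasonal peak appears near the configured peak week", {
  cfg <- synthetic_config(seed = 62, reporting_floor = 1)
  sim <- simulate_country(cfg)
  a <- data.frame(municipality_id = sim$municipalities$municipality_id,
                  region = sim$municipalities$region_true)
  prof <- seasonal_profile(sim$cases, a)
  east <- prof[prof$region == "T7", ]
  peak <- east$week[which.max(east$smoothed)]
  dist <- min(abs(peak - cfg$peak_week[7]), 52 - abs(peak - cfg$peak_week[7]))
  expect_lte(dist, 4)
})
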
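# Synthetic-country generator: municipality tables and weekly snakebite case
# series with a known, deprivation-dependent reporting mechanism, so that the
# index, the low-reporter detector and the incidence model can all be checked
# against ground truth.

#' Names of the six deprivation / health-access variables
#'
#' The underreporting index aggregates six municipality-level variables:
#' road distance from the municipality centre to the nearest hospital,
#' percentage of households more than 5 km from a health centre, percentage of
#' the population in poverty, illiteracy percentage, percentage of the
#' municipality area more than 1 km from a road, and the number of latest
#' births that took place outside the health-care system per inhabitant.
#' Higher raw values indicate worse standing for all six.
#'
#' @return Character vector of six column names.
#' @export
deprivation_variables <- function() {
  c("dist_hospital_m", "pct_households_gt5km_hc", "pct_poverty",
    "pct_illiterate", "pct_area_gt1km_road", "births_outside_hc_per_inhab")
}

#' Configuration for the synthetic country
#'
#' Defines a country of `n_municipalities` municipalities grouped into
#' `n_regions` environmental regions, with weekly snakebite counts over
#' `years` years. The true weekly rate for a municipality is
#' population x baseline x region multiplier x exp(rural_effect x %rural) x
#' seasonal multiplier, globally scaled so the expected national case count
#' over the study period equals `baseline_rate` per 100,000 inhabitants.
#' Observed counts are a binomial thinning of true counts: municipalities
#' below the `deprivation_reporting_knee` quantile of the deprivation ranking
#' report every case, and the reporting probability then decays linearly to
#' `reporting_floor` for the most deprived municipality.
#'
#' @param n_municipalities Number of municipalities (default 152).
#' @param n_regions Number of environmental regions (default 7).
#' @param years Number of years simulated (default 5).
#' @param weeks_per_year Epidemiological weeks per year (default 52; at least
#'   5 so the seasonal smoothing window fits).
#' @param seed Integer seed for the generator's RNG stream.
#' @param baseline_rate National true bites per 100,000 inhabitants over the
#'   whole `years`-year period (default 56).
#' @param region_multipliers Positive rate multipliers, one per region. The
#'   default for seven regions follows the relative per-region incidence
#'   profile of the Nicaraguan surveillance data (a wet lowland east-coast
#'   region with roughly three-fold the national rate, drier low-rate western
#'   regions).
#' @param region_sizes Municipality counts per region; must sum to
#'   `n_municipalities`. The default for 152 municipalities in 7 regions is
#'   c(11, 19, 12, 14, 56, 22, 18), the national region sizes.
#' @param rural_effect Log-rate increment per percentage point of rural
#'   population (default 0.01, i.e. +1% rate per point).
#' @param seasonal_amplitude Relative amplitude of the annual sinusoid in
#'   \[0, 1) (default 0.5, making the expected weekly rate vary three-fold
#'   between trough and peak).
#' @param peak_week Week of the seasonal peak, recycled per region (default
#'   49, mid-December).
#' @param reporting_floor Reporting probability of the most deprived
#'   municipality, in (0, 1] (default 0.5).
#' @param deprivation_reporting_knee Deprivation quantile in (0, 1) above
#'   which reporting decays (default 0.9: reporting loss is confined to
#'   roughly the most deprived decile of municipalities, the extreme end of
#'   the index where the reported-incidence drop is located).
#' @param underreporter_cutoff Municipalities with reporting probability
#'   strictly below this value are recorded as true underreporters in the
#'   ground truth (default 0.7).
#' @param case_fatality Probability that a reported case is fatal
#'   (default 0.01).
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_municipalities = 152L,
                             n_regions = 7L,
                             years = 5L,
                             weeks_per_year = 52L,
                             seed = 1L,
                             baseline_rate = 56,
                             region_multipliers = NULL,
                             region_sizes = NULL,
                             rural_effect = 0.01,
                             seasonal_amplitude = 0.5,
                             peak_week = 49L,
                             reporting_floor = 0.5,
                             deprivation_reporting_knee = 0.9,
                             underreporter_cutoff = 0.7,
                             case_fatality = 0.01) {
  check_scalar(n_municipalities, "n_municipalities", lower = 1, integer = TRUE)
  check_scalar(n_regions, "n_regions", lower = 1, integer = TRUE)
  if (n_regions > n_municipalities) {
    stop_snakemap("snakemap_config_error",
                  "invalid configuration field 'n_regions' (more regions than municipalities)")
  }
  check_scalar(years, "years", lower = 1, integer = TRUE)
  check_scalar(weeks_per_year, "weeks_per_year", lower = 5, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(baseline_rate, "baseline_rate", lower = 0, open_lower = TRUE)
  check_scalar(rural_effect, "rural_effect")
  check_scalar(seasonal_amplitude, "seasonal_amplitude", lower = 0, upper = 1,
               open_upper = TRUE)
  check_scalar(reporting_floor, "reporting_floor", lower = 0, upper = 1,
               open_lower = TRUE)
  check_scalar(deprivation_reporting_knee, "deprivation_reporting_knee",
               lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  check_scalar(underreporter_cutoff, "underreporter_cutoff", lower = 0,
               upper = 1)
  check_scalar(case_fatality, "case_fatality", lower = 0, upper = 1)

  if (is.null(region_multipliers)) {
    region_multipliers <- if (n_regions == 7L) {
      # per-region incidence relative to the national rate, matching the
      # published regional incidence profile (west coast south / central /
      # north / high, mountains, east inland, east coast)
      c(58.8, 24.1, 39.8, 26.8, 59.6, 46.8, 187.9) / 56
    } else {
      rep(1, n_regions)
    }
  }
  if (length(region_multipliers) != n_regions ||
      !is.numeric(region_multipliers) || any(!is.finite(region_multipliers)) ||
      any(region_multipliers <= 0)) {
    stop_snakemap("snakemap_config_error",
                  "invalid configuration field 'region_multipliers' (need %d positive values)",
                  n_regions)
  }

  if (is.null(region_sizes)) {
    region_sizes <- if (n_regions == 7L && n_municipalities == 152L) {
      c(11L, 19L, 12L, 14L, 56L, 22L, 18L)
    } else {
      base <- rep(n_municipalities %/% n_regions, n_regions)
      base + c(rep(1L, n_municipalities %% n_regions),
               rep(0L, n_regions - n_municipalities %% n_regions))
    }
  }
  if (length(region_sizes) != n_regions || any(region_sizes < 1) ||
      sum(region_sizes) != n_municipalities) {
    stop_snakemap("snakemap_config_error",
                  "invalid configuration field 'region_sizes' (need %d positive counts summing to %d)",
                  n_regions, n_municipalities)
  }

  peak_week <- as.integer(rep_len(peak_week, n_regions))
  if (any(peak_week < 1) || any(peak_week > weeks_per_year)) {
    stop_snakemap("snakemap_config_error",
                  "invalid configuration field 'peak_week' (must lie in 1..weeks_per_year)")
  }

  structure(list(
    n_municipalities = as.integer(n_municipalities),
    n_regions = as.integer(n_regions),
    years = as.integer(years),
    weeks_per_year = as.integer(weeks_per_year),
    seed = as.integer(seed),
    baseline_rate = baseline_rate,
    region_multipliers = region_multipliers,
    region_sizes = as.integer(region_sizes),
    rural_effect = rural_effect,
    seasonal_amplitude = seasonal_amplitude,
    peak_week = peak_week,
    reporting_floor = reporting_floor,
    deprivation_reporting_knee = deprivation_reporting_knee,
    underreporter_cutoff = underreporter_cutoff,
    case_fatality = case_fatality
  ), class = "synthetic_config")
}

# Per-region environmental profiles (mean altitude in m, mean annual
# precipitation in mm). The seven-region default sketches the national
# gradient: low dry west coast, a high western plateau, wet mountains, and a
# very wet low east coast.
region_profiles <- function(n_regions) {
  if (n_regions == 7L) {
    data.frame(
      altitude_m = c(100, 120, 220, 900, 950, 320, 30),
      precipitation_mm = c(1800, 1400, 1600, 1400, 2000, 2600, 3400)
    )
  } else {
    data.frame(
      altitude_m = seq(50, 1000, length.out = n_regions),
      precipitation_mm = seq(1200, 3200, length.out = n_regions)
    )
  }
}

#' Simulate the municipality table
#'
#' Draws `n_municipalities` municipalities: log-normal populations around
#' 30,000, rural population percentages, demographic covariates, per-region
#' altitude and precipitation, spatially clustered centroid coordinates (so
#' the generating regions are contiguous), and six deprivation / health-access
#' variables positively correlated with rurality. The generating region label
#' is kept in column `region_true`.
#'
#' The RNG is seeded from `config$seed`; re-running with the same
#' configuration reproduces the table exactly.
#'
#' @param config A [synthetic_config()].
#' @return A `data.frame`, one row per municipality.
#' @export
simulate_municipalities <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    stop_snakemap("snakemap_config_error",
                  "'config' must be created by synthetic_config()")
  }
  set.seed(config$seed)
  n <- config$n_municipalities
  k <- config$n_regions

  # region centres on a jittered lattice: guarantees separation, so the
  # point clouds of different regions rarely interleave
  grid_side <- ceiling(sqrt(k))
  cells <- sample(grid_side^2, k)
  cell_xy <- cbind((cells - 1L) %% grid_side, (cells - 1L) %/% grid_side)
  centres <- cell_xy * (100 / grid_side) + 50 / grid_side +
    matrix(stats::runif(2 * k, -6, 6), ncol = 2)

  region_id <- rep(seq_len(k), times = config$region_sizes)
  prof <- region_profiles(k)

  centroid_x <- centres[region_id, 1] + stats::rnorm(n, 0, 7)
  centroid_y <- centres[region_id, 2] + stats::rnorm(n, 0, 7)
  altitude_m <- pmax(0, prof$altitude_m[region_id] + stats::rnorm(n, 0, 80))
  precipitation_mm <- pmax(200, prof$precipitation_mm[region_id] +
                             stats::rnorm(n, 0, 150))

  population <- pmax(500, round(stats::rlnorm(n, log(30000), 0.8)))

  rural_logit <- stats::rnorm(n, stats::qlogis(0.44), 1.2)
  pct_rural <- 100 * stats::plogis(rural_logit)

  # shared deprivation latent loaded on rurality; each observed variable mixes
  # the latent with its own noise, giving rank correlations with %rural well
  # above 0.3 by construction
  z <- 0.8 * as.numeric(scale(rural_logit)) + 0.6 * stats::rnorm(n)
  mix <- function(b) 0.7 * z + 0.7 * stats::rnorm(n) + b

  municipalities <- data.frame(
    municipality_id = sprintf("M%03d", seq_len(n)),
    population = population,
    centroid_x = centroid_x,
    centroid_y = centroid_y,
    altitude_m = altitude_m,
    precipitation_mm = precipitation_mm,
    region_true = sprintf("T%d", region_id),
    pct_rural = pct_rural,
    pct_under15 = 100 * stats::plogis(stats::qlogis(0.37) +
                                        0.3 * as.numeric(scale(rural_logit)) +
                                        0.2 * stats::rnorm(n)),
    pct_male_surplus = stats::rnorm(n, 1, 2),
    dist_hospital_m = exp(9 + 0.8 * mix(0)),
    pct_households_gt5km_hc = 100 * stats::plogis(1.2 * mix(-1)),
    pct_poverty = 100 * stats::plogis(1.0 * mix(0.2)),
    pct_illiterate = 100 * stats::plogis(1.0 * mix(-0.8)),
    pct_area_gt1km_road = 100 * stats::plogis(1.3 * mix(-0.5)),
    births_outside_hc_per_inhab = exp(-4 + 0.9 * mix(0)),
    stringsAsFactors = FALSE
  )
  municipalities
}

# Deprivation quantile per municipality: 1/n for the least deprived, 1 for
# the most deprived, from the rank-sum index of the six variables.
deprivation_quantile <- function(municipalities) {
  idx <- compute_index(rank_variables(municipalities))
  # most deprived = lowest rank sum = position 1
  pos <- ordinal_position(idx$rank_sum, idx$municipality_id)
  n <- nrow(idx)
  u <- (n - pos + 1) / n
  names(u) <- idx$municipality_id
  u[municipalities$municipality_id]
}

#' Reporting probability implied by the deprivation mechanism
#'
#' Municipalities at or below the knee quantile of deprivation report every
#' case; above the knee the reporting probability decays linearly from 1 to
#' `reporting_floor` at the most deprived municipality.
#'
#' @param u Deprivation quantile in (0, 1], higher = more deprived.
#' @param config A [synthetic_config()].
#' @return Numeric vector of reporting probabilities in (0, 1].
#' @export
reporting_probability <- function(u, config) {
  knee <- config$deprivation_reporting_knee
  floor_ <- config$reporting_floor
  ifelse(u <= knee, 1, 1 - (1 - floor_) * (u - knee) / (1 - knee))
}

#' Simulate weekly case series and ground truth
#'
#' True weekly counts are Poisson with rate
#' population x baseline x region multiplier x exp(rural_effect x %rural) x
#' seasonal sinusoid, with a global scale chosen so that the expected national
#' true count over the simulated period equals
#' `baseline_rate / 100,000 x total population` exactly. Observed counts are a
#' binomial thinning of the true counts at each municipality's reporting
#' probability; deaths are a binomial draw from observed cases at the
#' case-fatality probability.
#'
#' The RNG stream is seeded deterministically from `config$seed` (offset by
#' one so it does not replay the municipality stream) and consumed in
#' documented order: true counts, then the reporting uniforms, then the death
#' uniforms, each laid out municipality-major then year then week. Thinning
#' and deaths are drawn by inverse-CDF (`qbinom` on those uniforms), so two
#' runs differing only in the reporting parameters share true counts and
#' uniforms, and the observed counts are then pointwise monotone in the
#' reporting probability.
#'
#' @param municipalities Municipality table from [simulate_municipalities()]
#'   (columns `municipality_id`, `population`, `pct_rural`, `region_true` and
#'   the six deprivation variables are required).
#' @param config A [synthetic_config()].
#' @return A list with elements `cases` (long `data.frame`:
#'   `municipality_id`, `year`, `week`, `cases`, `deaths`, `true_cases`) and
#'   `truth` (`data.frame`: `municipality_id`, `true_rate` — expected bites
#'   per person over the whole period —, `reporting_prob`,
#'   `underreporter_flag`).
#' @export
simulate_cases <- function(municipalities, config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    stop_snakemap("snakemap_config_error",
                  "'config' must be created by synthetic_config()")
  }
  check_columns(municipalities,
                c("municipality_id", "population", "pct_rural", "region_true",
                  deprivation_variables()),
                "municipalities")
  set.seed(config$seed + 1L)

  n <- nrow(municipalities)
  region_id <- as.integer(sub("^T", "", municipalities$region_true))
  if (any(is.na(region_id)) || any(region_id < 1) ||
      any(region_id > config$n_regions)) {
    stop_snakemap("snakemap_schema_error",
                  "column 'region_true' does not match the configured regions")
  }

  w <- municipalities$population *
    config$region_multipliers[region_id] *
    exp(config$rural_effect * municipalities$pct_rural)
  n_weeks_total <- config$years * config$weeks_per_year
  total_pop <- sum(municipalities$population)
  scale_c <- (config$baseline_rate / 1e5) * total_pop / (sum(w) * n_weeks_total)

  weeks <- seq_len(config$weeks_per_year)
  # one row per region: seasonal multiplier per week, mean exactly 1
  seasonal <- 1 + config$seasonal_amplitude *
    cos(2 * pi * outer(config$peak_week, weeks, function(p, w) (w - p)) /
          config$weeks_per_year)

  u <- deprivation_quantile(municipalities)
  rp <- reporting_probability(u, config)

  grid <- expand.grid(week = weeks, year = seq_len(config$years),
                      m = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  # municipality-major ordering for the documented RNG consumption order
  grid <- grid[order(grid$m, grid$year, grid$week), , drop = FALSE]

  lambda <- scale_c * w[grid$m] * seasonal[cbind(region_id[grid$m], grid$week)]
  true_cases <- stats::rpois(nrow(grid), lambda)
  u_report <- stats::runif(nrow(grid))
  u_death <- stats::runif(nrow(grid))
  cases <- as.integer(stats::qbinom(u_report, true_cases, rp[grid$m]))
  deaths <- as.integer(stats::qbinom(u_death, cases, config$case_fatality))

  series <- data.frame(
    municipality_id = municipalities$municipality_id[grid$m],
    year = grid$year,
    week = grid$week,
    cases = cases,
    deaths = deaths,
    true_cases = true_cases,
    stringsAsFactors = FALSE
  )
  rownames(series) <- NULL

  truth <- data.frame(
    municipality_id = municipalities$municipality_id,
    true_rate = scale_c * w * n_weeks_total / municipalities$population,
    reporting_prob = unname(rp),
    underreporter_flag = unname(rp < config$underreporter_cutoff),
    stringsAsFactors = FALSE
  )
  list(cases = series, truth = truth)
}

#' Simulate a full synthetic country
#'
#' Convenience wrapper running [simulate_municipalities()] then
#' [simulate_cases()].
#'
#' @param config A [synthetic_config()].
#' @return A list with `municipalities`, `cases`, `truth` and the `config`.
#' @export
simulate_country <- function(config = synthetic_config()) {
  municipalities <- simulate_municipalities(config)
  sim <- simulate_cases(municipalities, config)
  list(municipalities = municipalities, cases = sim$cases, truth = sim$truth,
       config = config)
}

#' Expected national case count implied by a configuration
#'
#' Closed form: the generator scales municipal rates so that the expected
#' national true count over the simulated period is exactly
#' `baseline_rate / 100,000 x total population`.
#'
#' @param municipalities Municipality table.
#' @param config A [synthetic_config()].
#' @return A single number.
#' @export
expected_national_cases <- function(municipalities, config) {
  (config$baseline_rate / 1e5) * sum(municipalities$population)
}
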
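# Descriptive epidemiology: cumulative and annual incidence per 100,000,
# mortality, case fatality, per-region incidence, and smoothed weekly
# seasonal profiles (centered 5-week sliding mean, circular over the year).

#' National incidence summary
#'
#' Cumulative incidence per 100,000 = 100,000 x total cases / total
#' population; annual incidence = cumulative / years; mortality per 100,000
#' over the period; case fatality rate (%) = 100 x deaths / cases (defined as
#' 0, with a warning, when there are no cases). Values are exact; rounding
#' happens only in the print method (incidence to the nearest integer,
#' mortality to 1 decimal, CFR to the nearest percent).
#'
#' @param case_series Long table with `municipality_id`, `cases`, and
#'   optionally `deaths`.
#' @param municipalities Table with `municipality_id` and `population`.
#' @param years Length of the study period in years (default 5).
#' @return List of class `incidence_summary`.
#' @export
incidence_summary <- function(case_series, municipalities, years = 5) {
  check_columns(case_series, c("municipality_id", "cases"), "case_series")
  check_columns(municipalities, c("municipality_id", "population"),
                "municipalities")
  if (any(case_series$cases < 0)) {
    stop_snakemap("snakemap_schema_error", "negative case counts")
  }
  totals <- aggregate_cases(case_series)
  total_cases <- sum(totals$cases)
  total_deaths <- sum(totals$deaths)
  population <- sum(municipalities$population)
  if (population <= 0) {
    stop_snakemap("snakemap_schema_error", "total population must be positive")
  }
  if (total_deaths > total_cases) {
    stop_snakemap("snakemap_schema_error", "more deaths than cases")
  }
  cfr <- if (total_cases == 0) {
    warning("no cases: case fatality rate defined as 0", call. = FALSE)
    0
  } else {
    100 * total_deaths / total_cases
  }
  cumulative <- 1e5 * total_cases / population
  structure(list(
    total_cases = total_cases,
    total_deaths = total_deaths,
    population = population,
    years = years,
    cumulative_incidence_per_100k = cumulative,
    annual_incidence_per_100k = cumulative / years,
    mortality_per_100k = 1e5 * total_deaths / population,
    case_fatality_pct = cfr
  ), class = "incidence_summary")
}

#' @export
print.incidence_summary <- function(x, ...) {
  cat(sprintf("%d reported cases, %d deaths among %s inhabitants over %g years\n",
              x$total_cases, x$total_deaths,
              format(x$population, big.mark = ","), x$years))
  cat(sprintf("%g-year incidence: %.0f per 100,000 (%.1f per year)\n",
              x$years, x$cumulative_incidence_per_100k,
              x$annual_incidence_per_100k))
  cat(sprintf("mortality: %.1f per 100,000 in %g years; case fatality rate: %.0f%%\n",
              x$mortality_per_100k, x$years, x$case_fatality_pct))
  invisible(x)
}

#' Per-region cumulative incidence
#'
#' @param case_series Long case table.
#' @param municipalities Table with `municipality_id`, `population`.
#' @param assignment A `region_assignment`.
#' @return `data.frame`: region, municipalities, population, cases,
#'   `incidence_per_100k` (cumulative over the series).
#' @export
regional_incidence <- function(case_series, municipalities, assignment) {
  check_columns(assignment, c("municipality_id", "region"), "assignment")
  totals <- aggregate_cases(case_series)
  m <- merge(municipalities[, c("municipality_id", "population")],
             assignment, by = "municipality_id")
  m <- merge(m, totals[, c("municipality_id", "cases")],
             by = "municipality_id", all.x = TRUE)
  m$cases[is.na(m$cases)] <- 0
  out <- do.call(rbind, lapply(split(m, m$region), function(g) {
    data.frame(region = g$region[1], n = nrow(g),
               population = sum(g$population), cases = sum(g$cases),
               incidence_per_100k = 1e5 * sum(g$cases) / sum(g$population),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$region), , drop = FALSE]
}

#' Centered circular sliding mean
#'
#' Smooths a weekly profile with a centered moving average of `window` weeks
#' (the week itself plus the (window-1)/2 previous and following weeks),
#' wrapping circularly so week 1 neighbours the last week. A circular window
#' preserves the mean of the series exactly and treats the turn of the year
#' symmetrically.
#'
#' @param x Numeric series (one value per week).
#' @param window Odd window length, at least 1 and at most `length(x)`
#'   (default 5).
#' @return Numeric vector, same length as `x`.
#' @export
seasonal_smooth <- function(x, window = 5L) {
  if (!is.numeric(window) || length(window) != 1L || window < 1L ||
      window %% 2L == 0L || window > length(x)) {
    stop_snakemap("snakemap_parameter_error",
                  "'window' must be odd, >= 1 and <= length(x)")
  }
  h <- (window - 1L) / 2L
  L <- length(x)
  vapply(seq_len(L), function(i) {
    mean(x[((i - 1L + seq(-h, h)) %% L) + 1L])
  }, numeric(1))
}

#' Weekly seasonal profile per (super-)region
#'
#' Computes the mean reported count per epidemiological week across years,
#' per region (nationally if `assignment` is NULL), then applies the centered
#' circular sliding mean. Weeks beyond `weeks_per_year` (e.g. ISO week 53)
#' are folded into the last week before averaging.
#'
#' @param case_series Long case table with `year` and `week`.
#' @param assignment Optional `region_assignment` (possibly aggregated into
#'   super-regions with [aggregate_regions()]).
#' @param weeks_per_year Number of weeks in the profile (default 52).
#' @param window Smoothing window (default 5).
#' @return `data.frame`: region, week, `mean_cases`, `smoothed`.
#' @export
seasonal_profile <- function(case_series, assignment = NULL,
                             weeks_per_year = 52L, window = 5L) {
  check_columns(case_series, c("municipality_id", "year", "week", "cases"),
                "case_series")
  cs <- case_series
  cs$week <- pmin(cs$week, weeks_per_year)
  cs$region <- if (is.null(assignment)) {
    "national"
  } else {
    check_columns(assignment, c("municipality_id", "region"), "assignment")
    reg <- assignment$region[match(cs$municipality_id,
                                   assignment$municipality_id)]
    if (anyNA(reg)) {
      stop_snakemap("snakemap_schema_error",
                    "case records for municipalities without a region: %s",
                    paste(unique(cs$municipality_id[is.na(reg)]), collapse = ", "))
    }
    reg
  }
  n_years <- length(unique(cs$year))
  out <- do.call(rbind, lapply(split(cs, cs$region), function(g) {
    weekly <- numeric(weeks_per_year)
    agg <- stats::aggregate(g$cases, by = list(week = g$week), FUN = sum)
    weekly[agg$week] <- agg$x / n_years
    data.frame(region = g$region[1], week = seq_len(weeks_per_year),
               mean_cases = weekly,
               smoothed = seasonal_smooth(weekly, window),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
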
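# Low-reporter detection: within each environmental region, municipalities
# that combine a large rural population share (top 40% of the within-region
# rural ranking) with a low reported incidence (bottom 40% of the
# within-region incidence ranking) are flagged as likely underreporting.

#' Aggregate a weekly case series to municipality totals
#'
#' @param case_series Long table with `municipality_id`, `cases` and
#'   optionally `deaths`.
#' @return `data.frame`: `municipality_id`, `cases`, `deaths` (0 if absent).
#' @export
aggregate_cases <- function(case_series) {
  check_columns(case_series, c("municipality_id", "cases"), "case_series")
  deaths <- if ("deaths" %in% names(case_series)) case_series$deaths else 0
  agg <- stats::aggregate(
    cbind(cases = case_series$cases, deaths = deaths),
    by = list(municipality_id = case_series$municipality_id), FUN = sum
  )
  agg[order(agg$municipality_id), , drop = FALSE]
}

#' Flag within-region low-reporters
#'
#' Within each region, municipalities are ranked by reported incidence
#' (cases / population, ascending: position 1 = lowest incidence) and by
#' rural population percentage (descending: position 1 = most rural), ties
#' broken by ascending `municipality_id`. A municipality is flagged iff both
#' its rural position and its incidence position are at most
#' `ceiling(q x region size)` — i.e. it is in the top `q` share of the rural
#' ranking and the bottom `q` share of the incidence ranking. Municipalities
#' with no case record get a case total of 0. Regions with fewer than 3
#' municipalities are skipped with a warning (`low_reporter` is NA there):
#' a 40% cut is degenerate at that size.
#'
#' @param case_totals Output of [aggregate_cases()] (columns
#'   `municipality_id`, `cases`).
#' @param municipalities Table with `municipality_id`, `population`,
#'   `pct_rural`.
#' @param assignment A `region_assignment`.
#' @param q Quantile of the two rankings (default 0.40).
#' @return `data.frame`: `municipality_id`, `region`, `incidence_per_100k`,
#'   `incidence_rank`, `rural_rank`, `low_reporter`.
#' @export
detect_low_reporters <- function(case_totals, municipalities, assignment,
                                 q = 0.40) {
  check_columns(case_totals, c("municipality_id", "cases"), "case_totals")
  check_columns(municipalities, c("municipality_id", "population", "pct_rural"),
                "municipalities")
  check_columns(assignment, c("municipality_id", "region"), "assignment")
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 1) {
    stop_snakemap("snakemap_parameter_error", "'q' must be a single value in [0, 1]")
  }
  if (any(municipalities$population <= 0)) {
    stop_snakemap("snakemap_schema_error",
                  "non-positive population for: %s",
                  paste(municipalities$municipality_id[
                    municipalities$population <= 0], collapse = ", "))
  }
  unassigned <- setdiff(municipalities$municipality_id,
                        assignment$municipality_id)
  if (length(unassigned) > 0L) {
    stop_snakemap("snakemap_schema_error",
                  "municipalities without a region: %s",
                  paste(unassigned, collapse = ", "))
  }

  m <- merge(municipalities[, c("municipality_id", "population", "pct_rural")],
             assignment, by = "municipality_id")
  m <- merge(m, case_totals[, c("municipality_id", "cases")],
             by = "municipality_id", all.x = TRUE)
  m$cases[is.na(m$cases)] <- 0
  m$incidence_per_100k <- 1e5 * m$cases / m$population

  out <- lapply(split(m, m$region), function(g) {
    n_r <- nrow(g)
    g$incidence_rank <- ordinal_position(g$incidence_per_100k,
                                         g$municipality_id)
    g$rural_rank <- ordinal_position(-g$pct_rural, g$municipality_id)
    if (n_r < 3L) {
      warning(sprintf("region '%s' has %d municipalities; skipped by the low-reporter rule",
                      g$region[1], n_r), call. = FALSE)
      g$low_reporter <- NA
    } else {
      cut <- ceiling(q * n_r)
      g$low_reporter <- g$incidence_rank <= cut & g$rural_rank <= cut
    }
    g
  })
  out <- do.call(rbind, out)
  out <- out[order(out$municipality_id),
             c("municipality_id", "region", "incidence_per_100k",
               "incidence_rank", "rural_rank", "low_reporter")]
  rownames(out) <- NULL
  out
}
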
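# End-to-end orchestration: simulate or ingest the country, assign regions,
# build the underreporting index, flag low-reporters, fit the three model
# columns, compute descriptives and seasonal curves, and write a consolidated
# report. Every written table carries a provenance comment (tool version,
# config hash, seed) and re-running with the same configuration reproduces
# the outputs byte for byte.

#' Pipeline configuration
#'
#' @param mode "synthetic" (simulate the country) or "files" (read tables
#'   from `paths`).
#' @param synthetic A [synthetic_config()] used in synthetic mode.
#' @param paths Named list with `municipalities` and `cases` CSV paths (file
#'   mode).
#' @param k_regions Number of environmental regions to form (default 7).
#' @param index_variables Index variable columns
#'   (default [deprivation_variables()]).
#' @param category_fractions Index category fractions, best to worst.
#' @param low_reporter_q Dual-rank quantile for the low-reporter rule
#'   (default 0.40).
#' @param n_worst Number of worst-index municipalities listed in the report
#'   (default 10).
#' @param out_dir Output directory (created if missing).
#' @param seed Seed; in synthetic mode it overrides `synthetic$seed`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            synthetic = synthetic_config(),
                            paths = list(),
                            k_regions = 7L,
                            index_variables = deprivation_variables(),
                            category_fractions = c(32, 45, 45, 20, 10) / 152,
                            low_reporter_q = 0.40,
                            n_worst = 10L,
                            out_dir = tempfile("snakemap_run_"),
                            seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "files") {
    for (p in c("municipalities", "cases")) {
      if (is.null(paths[[p]]) || !file.exists(paths[[p]])) {
        stop_snakemap("snakemap_io_error",
                      "file-mode path '%s' is missing or does not exist", p)
      }
    }
  }
  if (!is.null(seed)) {
    synthetic$seed <- as.integer(seed)
  }
  structure(list(
    mode = mode, synthetic = synthetic, paths = paths,
    k_regions = as.integer(k_regions),
    index_variables = index_variables,
    category_fractions = category_fractions,
    low_reporter_q = low_reporter_q,
    n_worst = as.integer(n_worst),
    out_dir = out_dir,
    seed = synthetic$seed
  ), class = "pipeline_config")
}

#' Validate input tables
#'
#' Checks schema, value ranges (percentages in \[0, 100\], counts >= 0,
#' populations > 0, deaths <= cases) and municipality-id referential
#' integrity between the case series and the municipality table.
#'
#' @param tables Named list with elements `municipalities` and optionally
#'   `cases`.
#' @return `data.frame` of issues (`table`, `id`, `column`, `issue`); zero
#'   rows when the bundle is clean.
#' @export
validate_inputs <- function(tables) {
  issues <- data.frame(table = character(), id = character(),
                       column = character(), issue = character(),
                       stringsAsFactors = FALSE)
  add <- function(table, id, column, issue) {
    issues <<- rbind(issues, data.frame(table = table, id = as.character(id),
                                        column = column, issue = issue,
                                        stringsAsFactors = FALSE))
  }
  m <- tables$municipalities
  if (is.null(m)) {
    add("municipalities", NA, NA, "table missing")
    return(issues)
  }
  for (col in c("municipality_id", "population")) {
    if (!col %in% names(m)) add("municipalities", NA, col, "column missing")
  }
  if ("municipality_id" %in% names(m) && anyDuplicated(m$municipality_id)) {
    add("municipalities", m$municipality_id[duplicated(m$municipality_id)][1],
        "municipality_id", "duplicate id")
  }
  if ("population" %in% names(m)) {
    bad <- which(!is.finite(m$population) | m$population <= 0)
    for (i in bad) add("municipalities", m$municipality_id[i], "population",
                       "population must be > 0")
  }
  for (col in intersect(c("pct_rural", "pct_under15", "pct_poverty",
                          "pct_illiterate", "pct_households_gt5km_hc",
                          "pct_area_gt1km_road"), names(m))) {
    bad <- which(!is.finite(m[[col]]) | m[[col]] < 0 | m[[col]] > 100)
    for (i in bad) add("municipalities", m$municipality_id[i], col,
                       "percentage outside [0, 100]")
  }
  cs <- tables$cases
  if (!is.null(cs)) {
    for (col in c("municipality_id", "year", "week", "cases")) {
      if (!col %in% names(cs)) add("cases", NA, col, "column missing")
    }
    if ("cases" %in% names(cs)) {
      bad <- which(!is.finite(cs$cases) | cs$cases < 0)
      for (i in bad) add("cases", cs$municipality_id[i], "cases",
                         sprintf("negative or non-finite count at row %d", i))
    }
    if (all(c("cases", "deaths") %in% names(cs))) {
      # rows with an invalid count are already reported above
      bad <- which(cs$deaths < 0 | (cs$cases >= 0 & cs$deaths > cs$cases))
      for (i in bad) add("cases", cs$municipality_id[i], "deaths",
                         sprintf("deaths outside [0, cases] at row %d", i))
    }
    if (all(c("municipality_id") %in% names(cs)) &&
        "municipality_id" %in% names(m)) {
      unknown <- setdiff(unique(cs$municipality_id), m$municipality_id)
      for (u in unknown) add("cases", u, "municipality_id",
                             "case record for unknown municipality")
    }
  }
  issues
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    code <- intersect(class(e), c("snakemap_validation_error",
                                  "snakemap_schema_error",
                                  "snakemap_parameter_error",
                                  "snakemap_config_error",
                                  "snakemap_io_error"))
    code <- if (length(code) > 0) code[1] else "snakemap_stage_error"
    stop(structure(
      class = unique(c(code, "snakemap_stage_error", "snakemap_error",
                       "error", "condition")),
      list(message = sprintf("[stage %s] %s", stage, conditionMessage(e)),
           stage = stage, call = NULL)
    ))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input simulation or ingestion, validation, region
#' assignment, underreporting index, low-reporter detection, the three
#' Poisson model fits (terms entered separately, region + demographics,
#' fully adjusted), the descriptive summary and seasonal curves, and a
#' consolidated report listing the worst-index municipalities and the
#' low-reporter flags (the two detection layers of the final map). In
#' synthetic mode the report also scores both detectors against the
#' simulated truth (sensitivity and specificity); when the configuration
#' creates no true underreporters this is reported as undefined.
#'
#' A stage failure aborts with the stage name and a machine-readable
#' condition class; outputs written before the failure are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all intermediate results and the report.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop_snakemap("snakemap_config_error",
                  "'config' must be created by pipeline_config()")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("snakemap %s config=%s seed=%d",
                   as.character(utils::packageVersion("snakemap")),
                   md5_of_object(unclass(config)[setdiff(names(config), "out_dir")]),
                   config$seed)
  out <- function(name) file.path(config$out_dir, name)

  # -- inputs ---------------------------------------------------------------
  truth <- NULL
  if (config$mode == "synthetic") {
    sim <- run_stage("simulate", simulate_country(config$synthetic))
    municipalities <- sim$municipalities
    cases <- sim$cases
    truth <- sim$truth
    write_table(municipalities, out("municipalities.csv"), stamp)
    write_table(cases[, c("municipality_id", "year", "week", "cases",
                          "deaths")],
                out("cases.csv"), stamp)
    jsonlite::write_json(truth, out("truth.json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    municipalities <- run_stage("ingest",
                                read_municipalities(config$paths$municipalities))
    cases <- run_stage("ingest", read_case_series(config$paths$cases))
  }

  run_stage("validate", {
    issues <- validate_inputs(list(municipalities = municipalities,
                                   cases = cases))
    required <- c("municipality_id", "population", "centroid_x", "centroid_y",
                  "altitude_m", "precipitation_mm", "pct_rural", "pct_under15",
                  "pct_male_surplus", config$index_variables)
    missing <- setdiff(required, names(municipalities))
    if (length(missing) > 0L) {
      stop_snakemap("snakemap_validation_error",
                    "municipality table is missing column(s): %s",
                    paste(missing, collapse = ", "))
    }
    if (nrow(issues) > 0L) {
      stop_snakemap("snakemap_validation_error",
                    "input validation failed: %s",
                    paste(sprintf("%s/%s: %s", issues$table, issues$column,
                                  issues$issue), collapse = "; "))
    }
  })

  # -- regions --------------------------------------------------------------
  assignment <- run_stage("regions",
                          assign_regions(municipalities, k = config$k_regions))
  write_table(as.data.frame(assignment), out("regions.csv"), stamp)

  # -- underreporting index -------------------------------------------------
  index <- run_stage("index",
                     underreporting_index(municipalities,
                                          config$index_variables,
                                          category_fractions =
                                            config$category_fractions))
  write_table(index, out("index.csv"), stamp)

  # -- low reporters --------------------------------------------------------
  totals <- aggregate_cases(cases)
  flags <- run_stage("lowreporters",
                     detect_low_reporters(totals, municipalities, assignment,
                                          q = config$low_reporter_q))
  write_table(flags, out("low_reporters.csv"), stamp)

  # -- models ---------------------------------------------------------------
  analysis <- merge(municipalities, totals[, c("municipality_id", "cases")],
                    by = "municipality_id", all.x = TRUE)
  analysis$cases[is.na(analysis$cases)] <- 0
  analysis <- merge(analysis, as.data.frame(assignment), by = "municipality_id")
  analysis <- merge(analysis,
                    data.frame(municipality_id = index$municipality_id,
                               index_category = as.character(index$category)),
                    by = "municipality_id")
  fits <- run_stage("fit", list(
    separate = fit_incidence_model(analysis, "separate"),
    region_demo = fit_incidence_model(analysis, "region_demo"),
    full = fit_incidence_model(analysis, "full")
  ))
  comparison <- model_comparison_report(fits)
  write_table(comparison, out("model_comparison.csv"), stamp)
  fit_json <- lapply(fits[c("region_demo", "full")], function(f) {
    list(coefficients = f$coefficients, loglik = f$loglik,
         iterations = f$iterations, converged = f$converged)
  })
  jsonlite::write_json(fit_json, out("fits.json"), auto_unbox = TRUE,
                       digits = NA)

  # -- descriptives ---------------------------------------------------------
  summary_ <- run_stage("describe",
                        incidence_summary(cases, municipalities,
                                          years = if (config$mode == "synthetic")
                                            config$synthetic$years else 5))
  jsonlite::write_json(unclass(summary_), out("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  per_region <- regional_incidence(cases, municipalities, assignment)
  write_table(per_region, out("regional_incidence.csv"), stamp)
  curves <- run_stage("describe", seasonal_profile(cases, assignment))
  write_table(curves, out("seasonal_curves.csv"), stamp)

  # -- report ---------------------------------------------------------------
  worst <- index$municipality_id[order(index$rank_sum,
                                       index$municipality_id)]
  worst <- worst[seq_len(min(config$n_worst, length(worst)))]
  flagged <- flags$municipality_id[which(flags$low_reporter)]
  report <- list(
    stamp = stamp,
    seed = config$seed,
    n_municipalities = nrow(municipalities),
    worst_index_municipalities = worst,
    low_reporters = flagged,
    n_low_reporters = length(flagged),
    overlap_worst_low_reporters = length(intersect(worst, flagged))
  )
  if (!is.null(truth)) {
    score_detector <- function(detected) {
      pos <- truth$municipality_id[truth$underreporter_flag]
      neg <- truth$municipality_id[!truth$underreporter_flag]
      if (length(pos) == 0L) {
        list(sensitivity = "undefined (no true underreporters)",
             specificity = sum(!neg %in% detected) / length(neg))
      } else {
        list(sensitivity = sum(pos %in% detected) / length(pos),
             specificity = sum(!neg %in% detected) / length(neg))
      }
    }
    report$truth_evaluation <- list(
      n_true_underreporters = sum(truth$underreporter_flag),
      worst_index = score_detector(worst),
      low_reporters = score_detector(flagged)
    )
  }
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(municipalities = municipalities, cases = cases,
                 truth = truth, assignment = assignment, index = index,
                 flags = flags, fits = fits, comparison = comparison,
                 summary = summary_, regional = per_region, curves = curves,
                 report = report, out_dir = config$out_dir))
}
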
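# Delimited-text and JSON input/output. All tables are CSV with a header
# row, UTF-8, "." decimal; optional "#"-prefixed provenance comments at the
# top of written files are skipped on read.

#' Write a table as CSV with an optional provenance comment
#'
#' @param df Data frame.
#' @param path Output path.
#' @param header_comment Optional character vector written as `# `-prefixed
#'   lines before the header.
#' @export
write_table <- function(df, path, header_comment = NULL) {
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) {
                    stop_snakemap("snakemap_io_error", "cannot open '%s': %s",
                                  path, conditionMessage(e))
                  })
  on.exit(close(con), add = TRUE)
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

read_table <- function(path, table_name) {
  if (!file.exists(path)) {
    stop_snakemap("snakemap_io_error", "file not found: %s", path)
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  encoding = "UTF-8")
}

#' Read a municipality table
#'
#' @param path CSV path.
#' @return `data.frame`.
#' @export
read_municipalities <- function(path) {
  df <- read_table(path, "municipalities")
  check_columns(df, c("municipality_id", "population"), "municipalities")
  df
}

#' Read a long-format weekly case series
#'
#' @param path CSV path.
#' @return `data.frame` with `municipality_id`, `year`, `week`, `cases`,
#'   `deaths`.
#' @export
read_case_series <- function(path) {
  df <- read_table(path, "case_series")
  check_columns(df, c("municipality_id", "year", "week", "cases"),
                "case_series")
  if (!"deaths" %in% names(df)) df$deaths <- 0L
  df
}

#' Read a region assignment
#'
#' @param path CSV path.
#' @return `region_assignment` data frame.
#' @export
read_region_assignment <- function(path) {
  df <- read_table(path, "assignment")
  check_columns(df, c("municipality_id", "region"), "assignment")
  class(df) <- c("region_assignment", "data.frame")
  df
}

#' Write municipalities as a GeoJSON point layer
#'
#' One point feature per municipality at its centroid, with the requested
#' columns as properties. Intended for loading the detection results into
#' standard GIS tools.
#'
#' @param municipalities Table with `municipality_id`, `centroid_x`,
#'   `centroid_y`.
#' @param path Output path.
#' @param properties Columns (from `municipalities`) to carry as feature
#'   properties.
#' @export
write_geojson_points <- function(municipalities, path,
                                 properties = "municipality_id") {
  check_columns(municipalities,
                c("municipality_id", "centroid_x", "centroid_y", properties),
                "municipalities")
  features <- lapply(seq_len(nrow(municipalities)), function(i) {
    row <- municipalities[i, ]
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(row$centroid_x, row$centroid_y)),
      properties = as.list(row[properties])
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
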
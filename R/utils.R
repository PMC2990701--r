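# Internal helpers shared across modules.

#' @keywords internal
stop_snakemap <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "snakemap_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' @keywords internal
check_columns <- function(df, cols, table_name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_snakemap("snakemap_schema_error",
                  "table '%s' is missing required column(s): %s",
                  table_name, paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' @keywords internal
check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         integer = FALSE, open_lower = FALSE,
                         open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper) &&
    (!integer || x == round(x))
  if (!ok) {
    stop_snakemap("snakemap_config_error",
                  "invalid configuration field '%s' (value: %s)",
                  field, paste(format(x), collapse = ", "))
  }
  invisible(x)
}

# Ordinal ranking with deterministic tie-break: among equal values the
# smaller id comes first. Returns positions 1..n.
#' @keywords internal
ordinal_position <- function(values, ids) {
  ord <- order(values, ids)
  pos <- integer(length(values))
  pos[ord] <- seq_along(values)
  pos
}

#' @keywords internal
md5_of_object <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), tf)
  unname(tools::md5sum(tf))
}
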
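# Rank-sum underreporting index: each municipality is ranked on six
# deprivation / health-access variables (rank n = most favourable value),
# the six ranks are summed with equal weight, and the sums are cut into five
# ordered categories used as a categorical term in the incidence model.

#' Rank municipalities on each index variable
#'
#' For every variable, municipalities are ranked 1..n with rank n for the most
#' favourable value (e.g. the lowest poverty percentage when higher raw values
#' are worse). Ranks are ordinal: ties are broken by ascending
#' `municipality_id`, with the smaller id receiving the better (higher) rank,
#' so each column is an exact permutation of 1..n and the rank sum stays
#' integer-valued.
#'
#' @param municipalities Municipality table.
#' @param variables Character vector of the six variable columns
#'   (default [deprivation_variables()]).
#' @param higher_is_worse Logical, recycled over variables: whether a higher
#'   raw value means worse standing (default TRUE for all six defaults:
#'   distances, poverty, illiteracy, roadlessness, out-of-system births).
#' @return `data.frame`: `municipality_id` plus one rank column per variable.
#' @export
rank_variables <- function(municipalities,
                           variables = deprivation_variables(),
                           higher_is_worse = TRUE) {
  check_columns(municipalities, c("municipality_id", variables),
                "municipalities")
  n <- nrow(municipalities)
  if (n < 1L) {
    stop_snakemap("snakemap_parameter_error", "no municipalities to rank")
  }
  higher_is_worse <- rep_len(higher_is_worse, length(variables))
  ids <- municipalities$municipality_id

  ranks <- data.frame(municipality_id = ids, stringsAsFactors = FALSE)
  for (j in seq_along(variables)) {
    v <- municipalities[[variables[j]]]
    if (!is.numeric(v)) {
      stop_snakemap("snakemap_schema_error",
                    "variable '%s' is not numeric", variables[j])
    }
    if (anyNA(v)) {
      stop_snakemap("snakemap_schema_error",
                    "variable '%s' has missing values for: %s",
                    variables[j], paste(ids[is.na(v)], collapse = ", "))
    }
    goodness <- if (higher_is_worse[j]) -v else v
    # best municipality first; among ties the smaller id is placed first and
    # therefore receives the higher rank
    ord <- order(-goodness, ids)
    r <- integer(n)
    r[ord] <- n:1
    ranks[[variables[j]]] <- r
  }
  ranks
}

#' Sum per-variable ranks into the underreporting index
#'
#' All variables carry equal weight: the index is the plain sum of the six
#' ranks, so with n municipalities it can range from 6 (worst rank on every
#' variable) to 6n (best rank on every variable).
#'
#' @param ranks Output of [rank_variables()].
#' @return `data.frame` with `municipality_id` and integer `rank_sum`.
#' @export
compute_index <- function(ranks) {
  check_columns(ranks, "municipality_id", "ranks")
  rank_cols <- setdiff(names(ranks), "municipality_id")
  if (length(rank_cols) == 0L) {
    stop_snakemap("snakemap_schema_error", "no rank columns in 'ranks'")
  }
  data.frame(
    municipality_id = ranks$municipality_id,
    rank_sum = as.integer(rowSums(ranks[rank_cols])),
    stringsAsFactors = FALSE
  )
}

#' Cut the index into five ordered categories
#'
#' Municipalities are sorted by `rank_sum` descending (highest sum = best
#' standing; ties broken by ascending `municipality_id`) and split into the
#' categories best / good / medium / bad / worst. Category sizes are
#' `round(fraction x n)`; any remainder from rounding is absorbed by the
#' "good" category, which serves as the reference in the incidence model. The
#' extreme categories are deliberately small so that effects at the ends of
#' the deprivation distribution remain discernible; the default fractions
#' reproduce sizes (32, 45, 45, 20, 10) at n = 152.
#'
#' @param index Output of [compute_index()].
#' @param category_fractions Five fractions (best to worst) summing to 1.
#' @return The input with an ordered factor column `category` added.
#' @export
categorize_index <- function(index,
                             category_fractions = c(32, 45, 45, 20, 10) / 152) {
  check_columns(index, c("municipality_id", "rank_sum"), "index")
  n <- nrow(index)
  if (n < 5L) {
    stop_snakemap("snakemap_parameter_error",
                  "cannot form five categories from %d municipalities", n)
  }
  if (length(category_fractions) != 5L ||
      abs(sum(category_fractions) - 1) > 1e-8 ||
      any(category_fractions < 0)) {
    stop_snakemap("snakemap_parameter_error",
                  "'category_fractions' must be five non-negative values summing to 1")
  }
  labels <- c("best", "good", "medium", "bad", "worst")
  sizes <- round(category_fractions * n)
  sizes[2] <- sizes[2] + (n - sum(sizes))  # remainder to the reference class
  if (any(sizes < 1)) {
    stop_snakemap("snakemap_parameter_error",
                  "category fractions leave an empty category at n = %d", n)
  }

  ord <- order(-index$rank_sum, index$municipality_id)
  category <- character(n)
  category[ord] <- rep(labels, times = sizes)
  index$category <- factor(category, levels = labels, ordered = TRUE)
  index
}

#' Construct the full underreporting index table
#'
#' Runs [rank_variables()], [compute_index()] and [categorize_index()] and
#' returns one table with the per-variable ranks, the rank sum and the
#' category.
#'
#' @inheritParams rank_variables
#' @inheritParams categorize_index
#' @return `data.frame`: `municipality_id`, six rank columns, `rank_sum`,
#'   `category`.
#' @export
underreporting_index <- function(municipalities,
                                 variables = deprivation_variables(),
                                 higher_is_worse = TRUE,
                                 category_fractions = c(32, 45, 45, 20, 10) / 152) {
  ranks <- rank_variables(municipalities, variables, higher_is_worse)
  idx <- categorize_index(compute_index(ranks), category_fractions)
  merge(ranks, idx, by = "municipality_id", sort = TRUE)
}
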
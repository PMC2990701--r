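# Poisson regression of municipality case counts with log-population offset.
# Counts over the study period are modelled as
#   cases_m ~ Poisson(pop_m * exp(x_m' beta)),
# i.e. a log-linear model of the rate with population as rate multiplier.
# Exponentiated coefficients are incidence ratios (IR); 95% confidence
# intervals are Wald intervals exp(beta +/- 1.96 SE) from the inverse
# expected information. Fitting is iteratively reweighted least squares.

#' Specify the incidence model terms
#'
#' Mirrors the three model columns reported for this analysis: each term
#' entered separately, a model adjusted for environmental region and the
#' demographic variables, and a fully adjusted model adding the
#' underreporting-index category.
#'
#' @param region Include the categorical environmental-region term.
#' @param demographics Include the continuous demographic terms.
#' @param index Include the categorical underreporting-index term.
#' @param region_ref Reference region; default NULL picks the region with the
#'   most municipalities (ties broken alphabetically), the same rule that
#'   selects the Mountain region in the national data.
#' @param index_ref Reference index category (default "good", the largest
#'   category).
#' @param continuous Continuous covariate columns, untransformed percentages
#'   (default rural population, population under 15, male surplus).
#' @return List of class `model_spec`.
#' @export
model_spec <- function(region = TRUE, demographics = TRUE, index = TRUE,
                       region_ref = NULL, index_ref = "good",
                       continuous = c("pct_rural", "pct_under15",
                                      "pct_male_surplus")) {
  structure(list(
    region = isTRUE(region),
    demographics = isTRUE(demographics),
    index = isTRUE(index),
    region_ref = region_ref,
    index_ref = index_ref,
    continuous = continuous
  ), class = "model_spec")
}

index_levels <- function() c("best", "good", "medium", "bad", "worst")

# Pick the reference level: stated reference, else the largest level
# (ties by level name).
reference_level <- function(x, ref) {
  tab <- table(x)
  if (!is.null(ref)) {
    if (!ref %in% names(tab)) {
      stop_snakemap("snakemap_parameter_error",
                    "reference level '%s' not present in the data", ref)
    }
    return(ref)
  }
  names(tab)[order(-tab, names(tab))][1]
}

#' Build the design matrix for the incidence model
#'
#' One indicator column per non-reference category plus the untransformed
#' continuous covariates and an intercept; the offset is log population.
#' Reference categories are excluded from the design and recorded in the
#' bookkeeping. The design is checked for full column rank; collinear columns
#' are named in the error.
#'
#' @param data Analysis table: one row per municipality with `cases`,
#'   `population`, and the columns required by `spec` (`region`,
#'   `index_category`, continuous covariates).
#' @param spec A [model_spec()].
#' @param template Optional design returned by a previous call; category
#'   levels are then taken from the template and unknown levels in `data` are
#'   an error (prediction-time check).
#' @return List: `X` (matrix), `y`, `offset`, `terms` (bookkeeping
#'   `data.frame`: column, term, level, reference flag), `references`.
#' @export
build_design <- function(data, spec = model_spec(), template = NULL) {
  check_columns(data, c("cases", "population"), "data")
  needed <- c(if (spec$region) "region",
              if (spec$index) "index_category",
              if (spec$demographics) spec$continuous)
  check_columns(data, needed, "data")
  n <- nrow(data)

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  terms <- data.frame(column = "(Intercept)", term = "(Intercept)",
                      level = NA_character_, reference = FALSE,
                      stringsAsFactors = FALSE)
  references <- list()

  add_categorical <- function(term, values, ref, known_levels) {
    values <- as.character(values)
    if (!is.null(known_levels)) {
      bad <- setdiff(unique(values), known_levels$levels)
      if (length(bad) > 0L) {
        stop_snakemap("snakemap_schema_error",
                      "unknown %s level(s): %s", term,
                      paste(bad, collapse = ", "))
      }
      levels <- known_levels$levels
      ref <- known_levels$ref
    } else {
      ref <- reference_level(values, ref)
      levels <- if (term == "index_category") {
        intersect(index_levels(), unique(values))
      } else {
        sort(unique(values))
      }
      bad <- if (term == "index_category") {
        setdiff(unique(values), index_levels())
      } else character(0)
      if (length(bad) > 0L) {
        stop_snakemap("snakemap_schema_error",
                      "unknown %s level(s): %s", term,
                      paste(bad, collapse = ", "))
      }
    }
    for (lvl in setdiff(levels, ref)) {
      col <- paste0(term, lvl)
      X <<- cbind(X, as.numeric(values == lvl))
      colnames(X)[ncol(X)] <<- col
      terms <<- rbind(terms, data.frame(column = col, term = term,
                                        level = lvl, reference = FALSE,
                                        stringsAsFactors = FALSE))
    }
    terms <<- rbind(terms, data.frame(column = NA_character_, term = term,
                                      level = ref, reference = TRUE,
                                      stringsAsFactors = FALSE))
    references[[term]] <<- list(levels = levels, ref = ref)
  }

  if (spec$region) {
    add_categorical("region", data$region, spec$region_ref,
                    template$references$region)
  }
  if (spec$index) {
    add_categorical("index_category", data$index_category, spec$index_ref,
                    template$references$index_category)
  }
  if (spec$demographics) {
    for (v in spec$continuous) {
      if (!is.numeric(data[[v]])) {
        stop_snakemap("snakemap_schema_error", "covariate '%s' is not numeric", v)
      }
      X <- cbind(X, data[[v]])
      colnames(X)[ncol(X)] <- v
      terms <- rbind(terms, data.frame(column = v, term = v,
                                       level = NA_character_,
                                       reference = FALSE,
                                       stringsAsFactors = FALSE))
    }
  }

  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1L):ncol(X)]]
    stop_snakemap("snakemap_parameter_error",
                  "design matrix is rank deficient; collinear column(s): %s",
                  paste(dropped, collapse = ", "))
  }

  list(X = X, y = data$cases, offset = log(data$population),
       terms = terms, references = references)
}

#' Fit the Poisson rate model by IRLS
#'
#' Maximizes the Poisson log-likelihood with log link and log-population
#' offset. Iteration starts from the pooled rate (intercept =
#' log(total cases / total population), other coefficients 0) and stops when
#' the largest absolute coefficient change falls below `tol`. Standard errors
#' are Wald, from the inverse expected information at the optimum; an
#' optional robust (sandwich) variance is available for overdispersed data
#' but is off by default, matching a plain Poisson analysis.
#'
#' Non-convergence within `max_iter` produces a fit flagged
#' `converged = FALSE` with a warning, not an error.
#'
#' @param data Analysis table (see [build_design()]).
#' @param spec A [model_spec()].
#' @param tol Convergence tolerance on coefficients (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param robust Use sandwich standard errors (default FALSE).
#' @return Object of class `rate_model_fit`: `coefficients` table (term,
#'   level, estimate, se, ir, ci_lo, ci_hi, reference), `vcov`, `loglik`,
#'   `iterations`, `converged`, `spec`, `design` bookkeeping.
#' @export
fit_poisson_rates <- function(data, spec = model_spec(), tol = 1e-8,
                              max_iter = 100L, robust = FALSE) {
  if (any(data$cases < 0) || any(data$cases != round(data$cases))) {
    stop_snakemap("snakemap_schema_error",
                  "'cases' must be non-negative integers")
  }
  if (any(data$population <= 0)) {
    stop_snakemap("snakemap_schema_error", "'population' must be positive")
  }
  design <- build_design(data, spec)
  X <- design$X
  y <- design$y
  off <- design$offset
  p <- ncol(X)
  if (nrow(X) <= p) {
    stop_snakemap("snakemap_parameter_error",
                  "more parameters (%d) than observations (%d) allow", p, nrow(X))
  }

  beta <- c(log(sum(y) / sum(exp(off))), rep(0, p - 1L))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta) + off
    mu <- pmax(exp(eta), 1e-300)
    z <- (eta - off) + (y - mu) / mu
    XtW <- t(X * mu)
    beta_new <- tryCatch(
      solve(XtW %*% X, XtW %*% z),
      error = function(e) {
        stop_snakemap("snakemap_parameter_error",
                      "IRLS normal equations are singular: %s",
                      conditionMessage(e))
      }
    )
    beta_new <- drop(beta_new)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("IRLS did not converge in %d iterations (last step %.3g)",
                    max_iter, delta), call. = FALSE)
  }

  eta <- drop(X %*% beta) + off
  mu <- exp(eta)
  info <- t(X * mu) %*% X
  vcov_model <- solve(info)
  if (robust) {
    meat <- t(X * (y - mu)^2) %*% X
    vcov_model <- vcov_model %*% meat %*% vcov_model
  }
  se <- sqrt(diag(vcov_model))
  names(beta) <- colnames(X)
  dimnames(vcov_model) <- list(colnames(X), colnames(X))

  tb <- design$terms
  est <- ifelse(tb$reference, 0, beta[tb$column])
  sev <- ifelse(tb$reference, 0, se[tb$column])
  coefficients <- data.frame(
    term = tb$term, level = tb$level,
    estimate = unname(est), se = unname(sev),
    ir = exp(unname(est)),
    ci_lo = exp(unname(est) - 1.96 * unname(sev)),
    ci_hi = exp(unname(est) + 1.96 * unname(sev)),
    reference = tb$reference,
    stringsAsFactors = FALSE
  )

  structure(list(
    coefficients = coefficients,
    beta = beta,
    vcov = vcov_model,
    loglik = sum(stats::dpois(y, mu, log = TRUE)),
    iterations = iter,
    converged = converged,
    n = nrow(X),
    spec = spec,
    design = design[c("terms", "references")]
  ), class = "rate_model_fit")
}

#' @export
print.rate_model_fit <- function(x, ...) {
  cat(sprintf("Poisson rate model (%d municipalities, log-population offset)\n",
              x$n))
  cat(sprintf("log-likelihood %.2f after %d IRLS iterations (%s)\n\n",
              x$loglik, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cf <- x$coefficients
  lab <- ifelse(is.na(cf$level), cf$term, paste(cf$term, cf$level))
  cell <- ifelse(cf$reference, "1 (reference)",
                 sprintf("%.2f (%.2f-%.2f)", cf$ir, cf$ci_lo, cf$ci_hi))
  print(data.frame(term = lab, `IR (95% CI)` = cell, check.names = FALSE),
        row.names = FALSE)
  invisible(x)
}

#' Fit one of the three reported model columns
#'
#' `"full"` adjusts for all terms; `"region_demo"` adjusts for environmental
#' region and the demographic variables only (the index rows then read "not
#' included" in the comparison table); `"separate"` enters each term in its
#' own single-term model and returns a list of fits.
#'
#' @param data Analysis table.
#' @param model One of "full", "region_demo", "separate".
#' @param ... Passed to [fit_poisson_rates()].
#' @return A `rate_model_fit`, or for "separate" a list of them (class
#'   `rate_model_fit_list`).
#' @export
fit_incidence_model <- function(data,
                                model = c("full", "region_demo", "separate"),
                                ...) {
  model <- match.arg(model)
  if (model == "full") {
    return(fit_poisson_rates(data, model_spec(), ...))
  }
  if (model == "region_demo") {
    return(fit_poisson_rates(data, model_spec(index = FALSE), ...))
  }
  specs <- c(
    list(region = model_spec(region = TRUE, demographics = FALSE, index = FALSE),
         index_category = model_spec(region = FALSE, demographics = FALSE,
                                     index = TRUE)),
    lapply(c("pct_rural", "pct_under15", "pct_male_surplus"), function(v) {
      model_spec(region = FALSE, demographics = TRUE, index = FALSE,
                 continuous = v)
    })
  )
  fits <- lapply(specs, function(s) fit_poisson_rates(data, s, ...))
  structure(fits, class = "rate_model_fit_list")
}

fit_coef_rows <- function(fit) {
  if (inherits(fit, "rate_model_fit_list")) {
    do.call(rbind, lapply(unclass(fit), function(f) f$coefficients))
  } else {
    fit$coefficients
  }
}

#' Side-by-side incidence-ratio comparison table
#'
#' Aligns several fitted models (e.g. terms entered separately, adjusted for
#' region and demographics, fully adjusted) into one table with a formatted
#' "IR (95% CI)" column per model. Terms absent from a model are rendered
#' "not included"; reference categories are rendered "1 (reference)".
#' Continuous-term ratios are shown with 3 decimals, categorical with 2.
#'
#' @param fits Named list of `rate_model_fit` (or, for the separate-terms
#'   column, `rate_model_fit_list`) objects.
#' @return `data.frame`: term, level, one column per model.
#' @export
model_comparison_report <- function(fits) {
  if (!is.list(fits) || length(fits) == 0L) {
    stop_snakemap("snakemap_parameter_error", "'fits' must be a non-empty list")
  }
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model_", seq_along(fits))
  }
  rows_by_fit <- lapply(fits, fit_coef_rows)
  all_rows <- unique(do.call(rbind, lapply(rows_by_fit, function(r) {
    r[!(r$term %in% "(Intercept)"), c("term", "level")]
  })))
  # canonical ordering: region levels, continuous terms, index categories
  ord_key <- function(term, level) {
    if (term == "index_category") {
      2000 + match(level, index_levels())
    } else if (term %in% c("pct_rural", "pct_under15", "pct_male_surplus")) {
      1000 + match(term, c("pct_rural", "pct_under15", "pct_male_surplus"))
    } else {
      match(level, sort(unique(all_rows$level[all_rows$term == term])))
    }
  }
  all_rows <- all_rows[order(mapply(ord_key, all_rows$term, all_rows$level)), ]

  out <- all_rows
  for (nm in names(fits)) {
    r <- rows_by_fit[[nm]]
    cells <- character(nrow(all_rows))
    for (i in seq_len(nrow(all_rows))) {
      m <- which(r$term == all_rows$term[i] &
                   (is.na(all_rows$level[i]) & is.na(r$level) |
                      !is.na(all_rows$level[i]) & !is.na(r$level) &
                      r$level %in% all_rows$level[i]))
      if (length(m) == 0L) {
        cells[i] <- "not included"
      } else if (r$reference[m[1]]) {
        cells[i] <- "1 (reference)"
      } else {
        digits <- if (is.na(all_rows$level[i])) 3L else 2L
        fmt <- sprintf("%%.%df (%%.%df-%%.%df)", digits, digits, digits)
        cells[i] <- sprintf(fmt, r$ir[m[1]], r$ci_lo[m[1]], r$ci_hi[m[1]])
      }
    }
    out[[nm]] <- cells
  }
  rownames(out) <- NULL
  out
}
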
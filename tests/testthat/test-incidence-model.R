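# Poisson rate model: closed-form checks, equivalence with an independent
# likelihood maximizer (grid oracle) and with stats::glm, design bookkeeping,
# and the offset identity.

test_that("the intercept-only model recovers the pooled rate", {
  d <- data.frame(cases = c(3, 7, 12, 0), population = c(1e4, 2e4, 5e4, 1e3))
  fit <- fit_poisson_rates(d, model_spec(region = FALSE, demographics = FALSE,
                                         index = FALSE))
  expect_true(fit$converged)
  expect_equal(exp(unname(fit$beta["(Intercept)"])),
               sum(d$cases) / sum(d$population), tolerance = 1e-10)
})

test_that("a two-group model reproduces the exact closed-form incidence ratio", {
  d <- data.frame(
    cases = c(5, 5, 15, 15),
    population = rep(5e4, 4),
    region = rep(c("A", "B"), each = 2)
  )
  fit <- fit_poisson_rates(d, model_spec(demographics = FALSE, index = FALSE,
                                         region_ref = "A"))
  ir_b <- fit$coefficients$ir[fit$coefficients$term == "region" &
                                fit$coefficients$level == "B"]
  expect_equal(ir_b, 3, tolerance = 1e-8)
})

test_that("IRLS matches a brute-force likelihood grid and stats::glm", {
  set.seed(51)
  d <- data.frame(
    population = round(runif(8, 2e4, 2e5)),
    pct_rural = runif(8, 10, 90)
  )
  d$cases <- rpois(8, d$population * 4e-4 * exp(0.012 * (d$pct_rural - 50)))
  spec <- model_spec(region = FALSE, index = FALSE, continuous = "pct_rural")
  fit <- fit_poisson_rates(d, spec)
  expect_true(fit$converged)

  oracle <- oracle_grid_poisson(d$cases, d$pct_rural, log(d$population))
  expect_equal(unname(fit$beta), oracle, tolerance = 1e-4)

  ref <- glm(cases ~ pct_rural + offset(log(population)), poisson, data = d)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

make_analysis <- function(n = 60, seed = 52) {
  set.seed(seed)
  d <- data.frame(
    cases = rpois(n, 20),
    population = round(runif(n, 1e4, 3e5)),
    region = sample(paste0("R", 1:7), n, replace = TRUE),
    index_category = sample(c("best", "good", "medium", "bad", "worst"), n,
                            replace = TRUE),
    pct_rural = runif(n, 0, 100),
    pct_under15 = runif(n, 25, 50),
    pct_male_surplus = rnorm(n, 1, 2)
  )
  d
}

test_that("the design has one column per non-reference level plus covariates", {
  d <- make_analysis()
  full <- build_design(d, model_spec())
  expect_equal(ncol(full$X), 1 + 6 + 4 + 3)
  no_index <- build_design(d, model_spec(index = FALSE))
  expect_equal(ncol(no_index$X), 1 + 6 + 3)
  expect_false(any(grepl("index_category", colnames(no_index$X))))
  # reference categories never appear as columns
  expect_false(any(full$X[, grepl("index_category", colnames(full$X))] %*%
                     rep(1, 4) > 1))
  refs <- full$terms[full$terms$reference, ]
  expect_setequal(refs$term, c("region", "index_category"))
  expect_equal(refs$level[refs$term == "index_category"], "good")
})

test_that("the default reference is the largest category", {
  d <- make_analysis()
  d$region <- rep(c("Mountains", "Coast"), c(40, 20))
  des <- build_design(d, model_spec(index = FALSE))
  expect_equal(des$references$region$ref, "Mountains")
})

test_that("unknown category levels are rejected, also at predict time", {
  d <- make_analysis()
  d$index_category[1] <- "terrible"
  expect_error(build_design(d, model_spec()), "terrible",
               class = "snakemap_schema_error")

  d2 <- make_analysis()
  template <- build_design(d2, model_spec())
  d3 <- d2
  d3$region[5] <- "R99"
  expect_error(build_design(d3, model_spec(), template = template), "R99",
               class = "snakemap_schema_error")
})

test_that("rank-deficient designs name the collinear columns", {
  d <- make_analysis()
  d$pct_under15 <- 2 * d$pct_rural
  expect_error(fit_poisson_rates(d, model_spec(index = FALSE)), "pct_under15",
               class = "snakemap_parameter_error")
})

test_that("scaling all populations shifts only the intercept, by -log(scale)", {
  d <- make_analysis()
  spec <- model_spec()
  fit1 <- fit_poisson_rates(d, spec)
  d2 <- d
  d2$population <- d2$population * 10
  fit2 <- fit_poisson_rates(d2, spec)
  expect_equal(unname(fit2$beta["(Intercept)"] - fit1$beta["(Intercept)"]),
               -log(10), tolerance = 1e-7)
  other <- setdiff(names(fit1$beta), "(Intercept)")
  expect_equal(fit1$beta[other], fit2$beta[other], tolerance = 1e-7)
})

test_that("confidence intervals bracket the incidence ratios", {
  fit <- fit_poisson_rates(make_analysis(), model_spec())
  cf <- fit$coefficients[!fit$coefficients$reference, ]
  expect_true(all(cf$ci_lo <= cf$ir & cf$ir <= cf$ci_hi))
  expect_true(all(cf$ir > 0))
})

test_that("model columns line up in the comparison report", {
  d <- make_analysis()
  fits <- list(separate = fit_incidence_model(d, "separate"),
               region_demo = fit_incidence_model(d, "region_demo"),
               full = fit_incidence_model(d, "full"))
  rep_ <- model_comparison_report(fits)
  idx_rows <- rep_[rep_$term == "index_category", ]
  expect_equal(idx_rows$level, c("best", "good", "medium", "bad", "worst"))
  expect_true(all(idx_rows$region_demo == "not included"))
  expect_equal(idx_rows$full[idx_rows$level == "good"], "1 (reference)")
  expect_true(all(grepl("^\\d+\\.\\d{3} \\(", rep_$full[rep_$term == "pct_rural"])))
  expect_error(model_comparison_report(list()),
               class = "snakemap_parameter_error")
})

test_that("counts and populations are validated before fitting", {
  d <- make_analysis()
  d$cases[1] <- -1
  expect_error(fit_poisson_rates(d), class = "snakemap_schema_error")
  d2 <- make_analysis()
  d2$population[1] <- 0
  expect_error(fit_poisson_rates(d2), class = "snakemap_schema_error")
})
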
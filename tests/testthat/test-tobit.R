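test_that("with no censoring the MLE collapses to the OLS solution", {
  s <- generate_tobit_sample(400, c(0.2, 0.1, -0.2), 0.05, seed = 3)
  expect_equal(sum(s$censored), 0)
  tab <- data.frame(efficiency = s$y, x1 = s$X[, 2], x2 = s$X[, 3])
  fit <- fit_tobit(tab)
  ols <- stats::lm(efficiency ~ x1 + x2, data = tab)
  expect_equal(unname(fit$coefficients), unname(stats::coef(ols)),
               tolerance = 1e-6)
  expect_equal(fit$sigma, sqrt(sum(stats::resid(ols)^2) / nrow(tab)),
               tolerance = 1e-6)
})

test_that("the reported likelihood matches an independent evaluation", {
  s <- generate_tobit_sample(800, c(0.7, 0.15, -0.2), 0.12, seed = 5)
  tab <- data.frame(efficiency = s$y, x1 = s$X[, 2], x2 = s$X[, 3])
  fit <- fit_tobit(tab)
  expect_gt(fit$n_censored, 0)
  ll <- loglik_oracle(fit$coefficients, fit$sigma, fit$y, fit$X, fit$censored)
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
  # ascent property: the optimum dominates the OLS starting point
  ols <- stats::lm(efficiency ~ x1 + x2, data = tab)
  ll0 <- loglik_oracle(stats::coef(ols), sqrt(sum(stats::resid(ols)^2) / nrow(tab)),
                       fit$y, fit$X, fit$censored)
  expect_gte(fit$loglik, ll0)
  # first-order condition at the optimum
  expect_lt(max(abs(fit$gradient)), 1e-5 * fit$n)
})

test_that("estimates agree with the survival-regression cross-check", {
  s <- generate_tobit_sample(1500, c(0.6, 0.2, -0.25), 0.15, seed = 11)
  tab <- data.frame(efficiency = s$y, x1 = s$X[, 2], x2 = s$X[, 3])
  fit <- fit_tobit(tab)
  sv <- survival::survreg(
    survival::Surv(efficiency, !s$censored) ~ x1 + x2,
    data = tab, dist = "gaussian"
  )
  expect_equal(unname(fit$coefficients), unname(stats::coef(sv)),
               tolerance = 1e-5)
  expect_equal(fit$sigma, sv$scale, tolerance = 1e-5)
  expect_equal(fit$loglik, sv$loglik[2], tolerance = 1e-6)
})

test_that("true coefficients are recovered within sampling error", {
  s <- generate_tobit_sample(2000, c(0.5, 0.2, -0.3), 0.1, seed = 7)
  tab <- data.frame(efficiency = s$y, x1 = s$X[, 2], x2 = s$X[, 3])
  fit <- fit_tobit(tab)
  for (k in 1:3) {
    expect_lt(abs(fit$coefficients[k] - s$beta[k]), 3 * fit$se[k])
  }
})

test_that("rescaling a covariate rescales its coefficient but not inference", {
  s <- generate_tobit_sample(800, c(0.7, 0.15, -0.2), 0.12, seed = 13)
  tab <- data.frame(efficiency = s$y, x1 = s$X[, 2], x2 = s$X[, 3])
  fit <- fit_tobit(tab)
  tab2 <- tab; tab2$x1 <- tab2$x1 * 50
  fit2 <- fit_tobit(tab2)
  expect_equal(unname(fit2$coefficients["x1"]), unname(fit$coefficients["x1"]) / 50,
               tolerance = 1e-6)
  expect_equal(unname(fit2$z), unname(fit$z), tolerance = 1e-4)
  expect_equal(unname(fit2$p), unname(fit$p), tolerance = 1e-4)
})

test_that("degenerate designs are rejected with useful messages", {
  s <- generate_tobit_sample(100, c(0.5, 0.2), 0.1, seed = 17)
  tab <- data.frame(efficiency = s$y, x1 = s$X[, 2], x1_copy = 2 * s$X[, 2])
  expect_error(fit_tobit(tab), "collinear.*x1_copy")
  tab_cens <- data.frame(efficiency = rep(1, 50), x1 = stats::rnorm(50))
  expect_error(fit_tobit(tab_cens), "censored")
})

test_that("the report formats inference columns and significance stars", {
  fake <- structure(
    list(coefficients = c(a = 0, b = 1, c = 1),
         se = c(a = 1, b = 1 / 2.576, c = 1 / 1.5),
         z = c(0, 2.576, 1.5),
         p = 2 * stats::pnorm(-abs(c(0, 2.576, 1.5)))),
    class = "tobit_fit"
  )
  rep <- tobit_report(fake)
  expect_equal(rep$p[1], 1)
  expect_equal(rep$stars, c("", "***", ""))
  expect_equal(nrow(rep), 3)
})

test_that("the regression table assembles responses and covariates per rule", {
  sim <- generate_panel(synthetic_config(
    n_units = 9L, n_years = 2L,
    region_sizes = c(eastern = 3L, central = 3L, western = 3L), seed = 19
  ))
  p <- sim$panel
  cfg <- analysis_config()
  dea <- dea_all_years(p, cfg)
  tab <- build_regression_table(p, dea, cfg)
  expect_equal(nrow(tab), 18)
  expect_setequal(setdiff(names(tab), c("unit_id", "year")),
                  c("efficiency", "lngdp", "lnpd", "urban", "lnpeople",
                    "lnbed", "lnassets", "people", "bed", "assets"))
  expect_equal(tab$lngdp, log(p$gdp_per_capita), tolerance = 1e-12)
  expect_equal(tab$urban, p$urbanization_rate)
  # provinces of one region share the fairness covariates in a year
  for (yr in unique(tab$year)) {
    for (r in unique(p$region)) {
      sel <- tab$year == yr & p$region[match(tab$unit_id, p$unit_id)] == r
      expect_equal(length(unique(tab$people[sel])), 1)
      expect_equal(length(unique(tab$assets[sel])), 1)
    }
  }
  # national rule assigns the overall index to every province
  cfg_nat <- analysis_config(theil_covariate_rule = "national")
  tab_nat <- build_regression_table(p, dea, cfg_nat)
  d <- theil_decompose(p, "X1", p$year[1])
  expect_equal(unique(tab_nat$people[tab_nat$year == p$year[1]]), d$total,
               tolerance = 1e-12)
  # mismatched coverage is rejected
  expect_error(build_regression_table(p, dea[-1, ], cfg), "same unit-year")
})
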
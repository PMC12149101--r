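test_that("theil_index matches closed forms and the direct-summation oracle", {
  # equal per-capita allocation: zero inequality
  w <- c(10, 20, 30, 40)
  expect_equal(theil_index(3 * w, w), 0, tolerance = 1e-15)
  # full concentration over equal weights: log(n)
  expect_equal(theil_index(c(1, 0, 0, 0), rep(1, 4)), log(4), tolerance = 1e-12)
  # worked example against the oracle
  a <- c(30, 10, 40, 20); w2 <- c(10, 10, 20, 20)
  expect_equal(theil_index(a, w2), theil_oracle(a, w2), tolerance = 1e-14)
})

test_that("theil_index rejects invalid domains", {
  expect_error(theil_index(c(-1, 2), c(1, 1)), "non-negative")
  expect_error(theil_index(c(0, 0), c(1, 1)), "zero")
  expect_error(theil_index(c(1, 1), c(0, 1)), "zero-weight")
  expect_error(theil_index(c(1, 2, 3), c(1, 2)), "equal-length")
})

test_that("decomposition matches the brute-force oracle and is additive", {
  # 2 regions x 2 provinces, amounts (30,10 | 40,20), weights (10,10 | 20,20)
  p <- panel_from_xy(c(1, 1, 1, 1, 1, 1), c(1, 1, 1, 1, 1, 1))
  p <- as.data.frame(p)
  p <- p[p$unit_id %in% c("u01", "u02", "u03", "u04"), ]
  p$region <- c("eastern", "eastern", "central", "central")
  p$X1 <- c(30, 10, 40, 20)
  p$population <- c(10, 10, 20, 20)
  p <- validate_panel(p)
  d <- theil_decompose(p, "X1", 2014)
  o <- theil_decomp_oracle(c(30, 10, 40, 20), c(10, 10, 20, 20),
                           c("e", "e", "c", "c"))
  expect_equal(d$total, o$total, tolerance = 1e-14)
  expect_equal(d$within, o$within, tolerance = 1e-14)
  expect_equal(d$between, o$between, tolerance = 1e-14)
  # additivity against the pooled single-level index
  expect_equal(d$total, theil_index(p$X1, p$population), tolerance = 1e-12)
})

test_that("degenerate decompositions behave as the formulas dictate", {
  # identical per-capita everywhere: all components zero, contributions NA
  p <- random_panel(seed = 5)
  p <- as.data.frame(p)
  p$X1 <- 2.5 * p$population
  p <- validate_panel(p)
  d <- theil_decompose(p, "X1", 2014)
  expect_equal(d$total, 0, tolerance = 1e-14)
  expect_true(is.na(d$within_contribution) && is.na(d$between_contribution))

  # internally equal regions at different levels: pure between inequality
  p2 <- as.data.frame(random_panel(seed = 6))
  lev <- c(eastern = 5, central = 2, western = 1)
  p2$X1 <- lev[p2$region] * p2$population
  p2 <- validate_panel(p2)
  d2 <- theil_decompose(p2, "X1", 2014)
  expect_equal(d2$within, 0, tolerance = 1e-14)
  expect_equal(d2$total, d2$between, tolerance = 1e-14)
  expect_equal(d2$between_contribution, 100, tolerance = 1e-9)
})

test_that("additivity, scale and permutation invariance hold on random panels", {
  for (seed in 1:25) {
    p <- random_panel(seed = seed, n_per_region = 2 + seed %% 3)
    d <- theil_decompose(p, "X5", 2014)
    pooled <- theil_index(p$X5[p$year == 2014], p$population[p$year == 2014])
    expect_equal(d$total, pooled, tolerance = 1e-12)
    expect_true(all(c(d$total, d$within, d$between, d$regions$theil) >= -1e-15))
    expect_equal(d$within_contribution + d$between_contribution, 100,
                 tolerance = 1e-9)

    # scaling all amounts (or all weights) changes nothing
    p_sc <- as.data.frame(p); p_sc$X5 <- p_sc$X5 * 7.3
    d_sc <- theil_decompose(validate_panel(p_sc), "X5", 2014)
    expect_equal(d_sc$total, d$total, tolerance = 1e-12)
    p_w <- as.data.frame(p); p_w$population <- p_w$population * 0.013
    d_w <- theil_decompose(validate_panel(p_w), "X5", 2014)
    expect_equal(d_w$total, d$total, tolerance = 1e-12)

    # permuting units within a region changes nothing
    p_pm <- as.data.frame(p)
    idx <- which(p_pm$region == "eastern" & p_pm$year == 2014)
    p_pm[idx, c("X5", "population")] <- p_pm[rev(idx), c("X5", "population")]
    d_pm <- theil_decompose(validate_panel(p_pm), "X5", 2014)
    expect_equal(d_pm$total, d$total, tolerance = 1e-12)
  }
})

test_that("a mean-preserving concentration never decreases the region index", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      w <- rep(1, 4)
      a <- stats::runif(4, 1, 10)
    })
    hi <- which.max(a); lo <- which.min(a)
    t0 <- theil_index(a, w)
    shift <- 0.5 * a[lo]
    a2 <- a; a2[hi] <- a2[hi] + shift; a2[lo] <- a2[lo] - shift
    expect_gte(theil_index(a2, w), t0 - 1e-12)
  }
})

test_that("theil_table has one row per indicator-year with consistent rates", {
  p <- random_panel(seed = 7, n_years = 3)
  tab <- theil_table(p, indicators = c("X1", "X2", "X3", "X4", "X5"))
  expect_equal(nrow(tab), 15)
  expect_equal(tab$within_contribution + tab$between_contribution,
               rep(100, 15), tolerance = 1e-9)
  expect_error(theil_table(p, indicators = character()), "non-empty")
  expect_error(theil_decompose(p, "X9", 2014), "unknown")
  expect_error(theil_decompose(p, "X1", 1999), "year")
})
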
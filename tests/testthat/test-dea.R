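test_that("the worked 1x1 example solves exactly under CCR and BCC", {
  X <- matrix(c(2, 4, 5), 1, dimnames = list(NULL, c("A", "B", "C")))
  Y <- matrix(c(2, 2, 10), 1, dimnames = list(NULL, c("A", "B", "C")))
  ccr <- sapply(1:3, function(j) solve_envelopment(X[, j], Y[, j], X, Y)$theta)
  expect_equal(ccr, c(0.5, 0.25, 1), tolerance = 1e-8)
  bcc <- sapply(1:3, function(j) solve_envelopment(X[, j], Y[, j], X, Y, vrs = TRUE)$theta)
  expect_equal(bcc, c(1, 0.5, 1), tolerance = 1e-8)

  # single unit against itself: theta 1, self peer weight, no slack
  self <- solve_envelopment(X[, 1], Y[, 1], X[, 1, drop = FALSE], Y[, 1, drop = FALSE])
  expect_equal(self$theta, 1, tolerance = 1e-9)
  expect_equal(unname(self$lambda), 1, tolerance = 1e-8)
  expect_equal(sum(self$slack_input) + sum(self$slack_output), 0, tolerance = 1e-7)
})

test_that("score_unit decomposes TE into PTE x SE and classifies RTS", {
  p <- panel_from_xy(c(2, 4, 5), c(2, 2, 10), units = c("A", "B", "C"))
  sa <- score_unit(p, "A", 2014, config_1x1())
  expect_equal(sa$te, 0.5, tolerance = 1e-8)
  expect_equal(sa$pte, 1, tolerance = 1e-8)
  expect_equal(sa$se, 0.5, tolerance = 1e-8)
  expect_equal(sa$rts, "irs")
  expect_equal(unname(sa$lambda_crs["C"]), 0.2, tolerance = 1e-8)

  sc <- score_unit(p, "C", 2014, config_1x1())
  expect_equal(c(sc$te, sc$pte, sc$se), c(1, 1, 1), tolerance = 1e-8)
  expect_true(sc$efficient)
  tab <- dea_year_table(p, 2014, config_1x1())
  expect_equal(tab$rts[tab$unit_id == "C"], "-")
})

test_that("stage 2 maximizes slacks left after the radial contraction", {
  # B dominates A in input 2 at equal radial efficiency: A keeps a slack of 1
  X <- matrix(c(1, 2, 1, 1), 2, 2, dimnames = list(NULL, c("A", "B")))
  Y <- matrix(c(1, 1), 1, 2, dimnames = list(NULL, c("A", "B")))
  sol <- solve_envelopment(X[, 1], Y[, 1], X, Y)
  expect_equal(sol$theta, 1, tolerance = 1e-8)
  expect_equal(sol$slack_input, c(0, 1), tolerance = 1e-6)
  expect_equal(unname(sol$lambda), c(0, 1), tolerance = 1e-6)
})

test_that("CCR equals the ratio closed form on random 1x1 panels", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(3:8, 1)
      x <- stats::rlnorm(n, 1, 0.6)
      y <- stats::rlnorm(n, 1, 0.6)
    })
    p <- panel_from_xy(x, y)
    d <- dea_year_table(p, 2014, config_1x1())
    expect_equal(d$te, ccr_1x1_oracle(x, y), tolerance = 1e-6)
    expect_true(all(d$te <= d$pte + 1e-8))
  }
})

test_that("the LP agrees with dual-vertex enumeration on small panels", {
  for (seed in 1:12) {
    withr::with_seed(seed, {
      n <- sample(4:6, 1)
      m <- sample(2:3, 1); s <- sample(1:2, 1)
      X <- matrix(stats::rlnorm(m * n, 1, 0.5), m, n)
      Y <- matrix(stats::rlnorm(s * n, 1, 0.5), s, n)
    })
    j <- 1 + seed %% 3
    lp_crs <- solve_envelopment(X[, j], Y[, j], X, Y, vrs = FALSE)$theta
    expect_equal(lp_crs, dea_vertex_oracle(X[, j], Y[, j], X, Y, vrs = FALSE),
                 tolerance = 1e-4)
    lp_vrs <- solve_envelopment(X[, j], Y[, j], X, Y, vrs = TRUE)$theta
    expect_equal(lp_vrs, dea_vertex_oracle(X[, j], Y[, j], X, Y, vrs = TRUE),
                 tolerance = 1e-4)
  }
})

test_that("scores are invariant to the units of any single dimension", {
  p <- random_panel(seed = 11)
  cfg <- analysis_config()
  base <- dea_year_table(p, 2014, cfg)
  p2 <- as.data.frame(p); p2$X2 <- p2$X2 * 1000
  scaled_in <- dea_year_table(validate_panel(p2), 2014, cfg)
  expect_equal(scaled_in$te, base$te, tolerance = 1e-6)
  expect_equal(scaled_in$pte, base$pte, tolerance = 1e-6)
  p3 <- as.data.frame(p); p3$Y2 <- p3$Y2 / 5000
  scaled_out <- dea_year_table(validate_panel(p3), 2014, cfg)
  expect_equal(scaled_out$te, base$te, tolerance = 1e-6)
})

test_that("adding a dominated unit changes no other unit's score", {
  x <- c(2, 4, 5); y <- c(2, 2, 10)
  p <- panel_from_xy(x, y, units = c("A", "B", "C"))
  base <- dea_year_table(p, 2014, config_1x1())
  # D uses more input than C for less output: dominated by C
  p2 <- panel_from_xy(c(x, 7), c(y, 8), units = c("A", "B", "C", "D"))
  ext <- dea_year_table(p2, 2014, config_1x1())
  expect_equal(ext$te[match(c("A", "B", "C"), ext$unit_id)],
               base$te[match(c("A", "B", "C"), base$unit_id)],
               tolerance = 1e-7)
})

test_that("projection reports redundancy and insufficiency consistently", {
  p <- panel_from_xy(c(2, 4, 5), c(2, 2, 10), units = c("A", "B", "C"))
  sb <- score_unit(p, "B", 2014, config_1x1())
  pr <- projection(sb)
  red <- pr[pr$kind == "input_redundancy" & pr$indicator == "X1", ]
  expect_equal(red$value, (1 - sb$pte) * 4, tolerance = 1e-6)
  expect_equal(red$value, 2, tolerance = 1e-6)
  expect_equal(red$rate_percent, 50, tolerance = 1e-4)

  # efficient units project onto themselves
  sc <- score_unit(p, "C", 2014, config_1x1())
  prc <- projection(sc)
  expect_equal(prc$value, rep(0, nrow(prc)), tolerance = 1e-6)
  expect_equal(prc$rate_percent, rep(0, nrow(prc)), tolerance = 1e-4)

  # rescaling one input scales the value but not the rate
  p_sc <- as.data.frame(p); p_sc$X1 <- p_sc$X1 * 10
  sb2 <- score_unit(validate_panel(p_sc), "B", 2014, config_1x1())
  pr2 <- projection(sb2)
  red2 <- pr2[pr2$kind == "input_redundancy" & pr2$indicator == "X1", ]
  expect_equal(red2$value, 10 * red$value, tolerance = 1e-5)
  expect_equal(red2$rate_percent, red$rate_percent, tolerance = 1e-4)
})

test_that("TE <= PTE and SE in (0,1] across random panels", {
  for (seed in 13:18) {
    p <- random_panel(seed = seed, n_per_region = 3)
    d <- dea_year_table(p, 2014, analysis_config())
    expect_true(all(d$te <= d$pte + 1e-8))
    expect_true(all(d$te > 0))
    expect_true(all(d$se > 0 & d$se <= 1 + 1e-8))
  }
})

test_that("projection_table keeps only units below the VRS frontier", {
  p <- panel_from_xy(c(2, 4, 5), c(2, 2, 10), units = c("A", "B", "C"))
  pt <- projection_table(p, 2014, config_1x1())
  expect_setequal(unique(pt$unit_id), "B")
  # all-efficient panels yield an empty table
  p_eff <- panel_from_xy(c(1, 2), c(1, 2), units = c("A", "B"))
  expect_equal(nrow(projection_table(p_eff, 2014, config_1x1())), 0)
})
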
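# Independent oracles and panel builders used across the test files. The
# oracles deliberately avoid the package's computational paths: direct
# summation for the Theil index, ratio arithmetic for single-dimension DEA,
# and dual-vertex enumeration for small envelopment programs.

# Direct term-by-term evaluation of the entropy inequality formula.
theil_oracle <- function(amounts, weights) {
  total_a <- sum(amounts)
  total_w <- sum(weights)
  acc <- 0
  for (j in seq_along(amounts)) {
    sj <- unname(amounts[j]) / total_a
    wj <- unname(weights[j]) / total_w
    if (sj > 0) acc <- acc + sj * log(sj / wj)
  }
  acc
}

# Brute-force nested evaluation of the two-level decomposition.
theil_decomp_oracle <- function(amounts, weights, region) {
  regs <- unique(region)
  t_i <- sapply(regs, function(r) theil_oracle(amounts[region == r], weights[region == r]))
  y_i <- sapply(regs, function(r) sum(amounts[region == r]))
  w_i <- sapply(regs, function(r) sum(weights[region == r]))
  tb <- theil_oracle(y_i, w_i)
  tw <- sum((y_i / sum(y_i)) * t_i)
  list(total = tw + tb, within = tw, between = tb, t_i = t_i)
}

# Closed-form CCR efficiency for a 1-input 1-output technology.
ccr_1x1_oracle <- function(x, y) {
  ratio <- y / x
  ratio / max(ratio)
}

# Vertex enumeration of the multiplier (dual) program:
#   max v'y0  s.t.  u'x0 = 1,  v'y_j - u'x_j (+ w0) <= 0,  u, v >= 0
# (w0 free only under VRS). The optimum equals the envelopment theta*.
dea_vertex_oracle <- function(x0, y0, X, Y, vrs = FALSE) {
  m <- nrow(X); s <- nrow(Y); n <- ncol(X)
  d <- m + s + as.integer(vrs)
  eqrow <- c(x0, rep(0, s + as.integer(vrs)))
  unit_rows <- lapply(seq_len(n), function(j) {
    c(-X[, j], Y[, j], if (vrs) 1 else NULL)
  })
  nn_rows <- lapply(seq_len(m + s), function(k) {
    e <- rep(0, d); e[k] <- 1; e
  })
  cand <- c(unit_rows, nn_rows)
  best <- -Inf
  for (cb in utils::combn(length(cand), d - 1, simplify = FALSE)) {
    A <- rbind(eqrow, do.call(rbind, cand[cb]))
    w <- tryCatch(solve(A, c(1, rep(0, d - 1))), error = function(e) NULL)
    if (is.null(w)) next
    if (any(w[seq_len(m + s)] < -1e-9)) next
    viol <- vapply(unit_rows, function(r) sum(r * w), numeric(1))
    if (any(viol > 1e-8)) next
    obj <- sum(w[m + seq_len(s)] * y0) + (if (vrs) w[d] else 0)
    if (obj > best) best <- obj
  }
  best
}

# A valid random panel built directly (independent of the synthetic module),
# with >= 2 units per region and all invariants satisfied.
random_panel <- function(seed, n_per_region = 2, n_years = 2,
                         start_year = 2014) {
  withr::with_seed(seed, {
    regions <- rep(c("eastern", "central", "western"), each = n_per_region)
    n <- length(regions)
    units <- sprintf("u%02d", seq_len(n))
    rows <- list()
    for (k in seq_len(n_years)) {
      rows[[k]] <- data.frame(
        unit_id = units, region = regions, year = start_year + k - 1L,
        X1 = stats::rlnorm(n, 10, 0.5), X2 = stats::rlnorm(n, 9, 0.5),
        X3 = stats::rlnorm(n, 9, 0.5), X4 = stats::rlnorm(n, 10, 0.5),
        X5 = stats::rlnorm(n, 13, 0.7), X6 = stats::rlnorm(n, 5, 0.5),
        Y1 = stats::runif(n, 60, 95), Y2 = stats::rlnorm(n, 16, 0.5),
        Y3 = stats::rlnorm(n, 13, 0.5),
        population = stats::rlnorm(n, 17, 0.4),
        gdp_per_capita = stats::rlnorm(n, 11, 0.3),
        population_density = stats::rlnorm(n, 6, 0.8),
        urbanization_rate = stats::runif(n, 0.3, 0.9),
        stringsAsFactors = FALSE
      )
    }
    validate_panel(do.call(rbind, rows))
  })
}

# Minimal panel holding given 1-input/1-output DEA data in X1/Y1 (all other
# columns constant and positive).
panel_from_xy <- function(x, y, units = NULL, years = 2014L, region = NULL) {
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (is.null(units)) units <- sprintf("u%02d", seq_len(n))
  if (is.null(region)) {
    region <- rep(c("eastern", "central", "western"), length.out = n)
  }
  rows <- lapply(seq_along(years), function(k) {
    data.frame(
      unit_id = units, region = region, year = years[k],
      X1 = if (is.matrix(x)) x[k, ] else x,
      X2 = 1, X3 = 1, X4 = 1, X5 = 1, X6 = 1,
      Y1 = if (is.matrix(y)) y[k, ] else y,
      Y2 = 1, Y3 = 1,
      population = 1, gdp_per_capita = 1, population_density = 1,
      urbanization_rate = 0.5, stringsAsFactors = FALSE
    )
  })
  validate_panel(do.call(rbind, rows))
}

config_1x1 <- function() analysis_config(input_indicators = "X1",
                                         output_indicators = "Y1")

# Direct evaluation of the censored-Gaussian log-likelihood, written out
# independently of tobit_loglik().
loglik_oracle <- function(beta, sigma, y, X, censored, limit = 1) {
  mu <- as.vector(X %*% beta)
  acc <- 0
  for (i in seq_along(y)) {
    if (censored[i]) {
      acc <- acc + log(1 - stats::pnorm((limit - mu[i]) / sigma))
    } else {
      acc <- acc + log(stats::dnorm((y[i] - mu[i]) / sigma) / sigma)
    }
  }
  acc
}
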
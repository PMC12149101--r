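# Seeded synthetic panel generator with known ground truth. The generator
# targets the assumptions the analysis methods require: strictly positive
# right-skewed indicators, region-structured inequality in per-capita
# resources, a convex production frontier with one-sided (half-normal)
# inefficiency, and covariates on realistic scales. It is not calibrated to
# any real provincial magnitudes.

#' Configuration for the synthetic panel generator
#'
#' @param n_units number of units (provinces).
#' @param n_years number of consecutive years.
#' @param region_sizes named integer vector over `eastern`, `central`,
#'   `western`, summing to `n_units`.
#' @param start_year first calendar year.
#' @param seed integer seed; identical seeds give byte-identical panels.
#' @param technology `"cobb_douglas"` (diminishing returns, varying input
#'   mixes) or `"linear_crs"` (ray technology with a common input mix, under
#'   which frontier efficiency is exactly recoverable by DEA).
#' @param returns_to_scale scale elasticity of the Cobb-Douglas frontier
#'   (sum of input elasticities).
#' @param sigma_u scale of the half-normal inefficiency term; 0 puts every
#'   unit on the frontier.
#' @param region_multipliers named positive vector of per-capita resource
#'   multipliers driving between-region inequality.
#' @param within_dispersion log-scale standard deviation of unit-level
#'   per-capita resource noise within a region; 0 makes per-capita resources
#'   identical within each region (zero within-region Theil).
#' @param frontier_growth proportional outward frontier shift per year.
#' @param tobit_beta,tobit_sigma ground-truth coefficients and noise scale
#'   carried along for censored-regression experiments (see
#'   [generate_tobit_sample()]).
#' @return List with class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_units = 31L,
                             n_years = 6L,
                             region_sizes = c(eastern = 11L, central = 8L, western = 12L),
                             start_year = 2014L,
                             seed = 1L,
                             technology = c("cobb_douglas", "linear_crs"),
                             returns_to_scale = 0.9,
                             sigma_u = 0.1,
                             region_multipliers = c(eastern = 1.35, central = 1.0, western = 0.8),
                             within_dispersion = 0.15,
                             frontier_growth = 0.01,
                             tobit_beta = c(0.5, 0.2, -0.3),
                             tobit_sigma = 0.1) {
  technology <- match.arg(technology)
  if (!setequal(names(region_sizes), PANEL_REGIONS)) {
    stop("region_sizes must be named eastern/central/western")
  }
  if (sum(region_sizes) != n_units) {
    stop("region sizes must sum to n_units (", sum(region_sizes), " != ", n_units, ")")
  }
  if (sigma_u < 0 || tobit_sigma <= 0) stop("sigma_u must be >= 0 and tobit_sigma > 0")
  if (any(region_multipliers <= 0)) stop("region multipliers must be positive")
  structure(
    list(
      n_units = as.integer(n_units), n_years = as.integer(n_years),
      region_sizes = region_sizes[PANEL_REGIONS],
      start_year = as.integer(start_year), seed = as.integer(seed),
      technology = technology, returns_to_scale = returns_to_scale,
      sigma_u = sigma_u, region_multipliers = region_multipliers[PANEL_REGIONS],
      within_dispersion = within_dispersion, frontier_growth = frontier_growth,
      tobit_beta = tobit_beta, tobit_sigma = tobit_sigma
    ),
    class = "synthetic_config"
  )
}

# typical per-capita levels of the six input indicators (persons, beds,
# 10^4 yuan and 10^8 yuan units respectively -- cosmetic scales only)
PC_BASE <- c(X1 = 0.0065, X2 = 0.0026, X3 = 0.0028, X4 = 0.0060,
             X5 = 0.60, X6 = 4e-5)
OUT_BASE <- c(Y1 = 85, Y2 = 2.0e8, Y3 = 6.0e6)

#' Generate a synthetic panel with known ground truth
#'
#' Resources are allocated as
#' `amount = per-capita base x region multiplier x unit noise x population`,
#' so the configured multipliers drive between-region inequality and
#' `within_dispersion` drives within-region inequality. Outputs sit on a
#' known production frontier scaled down by `exp(-u)` with half-normal
#' inefficiency `u`. Under `"linear_crs"` all units share one input mix (a
#' ray technology), making the constant-returns DEA score exactly
#' `exp(-u) / max(exp(-u))` within a year; under `"cobb_douglas"` input mixes
#' vary and efficiency is only approximately recoverable.
#'
#' @param config a [synthetic_config()].
#' @return List with `panel` (validated panel data frame) and `truth` (list
#'   with per unit-year `efficiency = exp(-u)` and the generating config).
#' @export
generate_panel <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_panel_impl(config))
}

generate_panel_impl <- function(config) {
  n <- config$n_units
  years <- config$start_year + seq_len(config$n_years) - 1L
  region <- rep(PANEL_REGIONS, times = config$region_sizes)
  unit_id <- sprintf("unit%02d", seq_len(n))
  mult <- config$region_multipliers[region]

  pop0 <- stats::rlnorm(n, log(4.4e7), 0.35)
  # unit-level per-capita noise: a persistent unit effect plus a yearly
  # innovation, so within-region inequality (and hence the Theil covariates
  # of the efficiency regression) varies over years as in real panels
  unit_effect <- matrix(stats::rnorm(n * length(PC_BASE), 0, config$within_dispersion),
                        n, length(PC_BASE), dimnames = list(NULL, names(PC_BASE)))
  gdp0 <- 6e4 * unname(mult)^1.5 * exp(stats::rnorm(n, 0, 0.25))
  dens <- 450 * unname(mult) * exp(stats::rnorm(n, 0, 0.7))
  urb <- stats::plogis(stats::qlogis(0.55) + 0.6 * log(unname(mult)) +
                         stats::rnorm(n, 0, 0.3))

  rows <- vector("list", config$n_years)
  truth_rows <- vector("list", config$n_years)
  for (k in seq_len(config$n_years)) {
    growth <- (1 + 0.005)^(k - 1)
    tech_level <- (1 + config$frontier_growth)^(k - 1)
    pop <- pop0 * growth
    innovation <- matrix(stats::rnorm(n * length(PC_BASE), 0, config$within_dispersion / 3),
                         n, length(PC_BASE))
    noise <- exp(unit_effect + innovation)
    if (config$technology == "linear_crs") {
      # common input mix: one size scalar per unit scales every indicator
      noise[] <- noise[, 1]
    }
    X <- sweep(noise, 1, unname(mult) * pop, `*`)
    X <- sweep(X, 2, PC_BASE, `*`)

    u <- abs(stats::rnorm(n, 0, config$sigma_u))
    if (config$sigma_u == 0) u <- rep(0, n)
    eff <- exp(-u)

    # frontier output level per unit, relative to a typical bundle
    typical <- PC_BASE * 4.4e7
    if (config$technology == "linear_crs") {
      g <- as.vector(X[, "X1"] / typical["X1"])
    } else {
      alpha <- rep(config$returns_to_scale / 5, 5)
      dea_in <- c("X1", "X2", "X3", "X4", "X6")
      lg <- sweep(log(X[, dea_in, drop = FALSE]), 2,
                  log(typical[dea_in]), `-`) %*% alpha
      g <- as.vector(exp(lg))
    }
    Y <- outer(g * eff * tech_level, OUT_BASE)
    colnames(Y) <- names(OUT_BASE)

    rows[[k]] <- data.frame(
      unit_id = unit_id, region = region, year = years[k],
      X1 = X[, "X1"], X2 = X[, "X2"], X3 = X[, "X3"], X4 = X[, "X4"],
      X5 = X[, "X5"], X6 = X[, "X6"],
      Y1 = Y[, "Y1"], Y2 = Y[, "Y2"], Y3 = Y[, "Y3"],
      population = pop,
      gdp_per_capita = gdp0 * (1 + 0.06)^(k - 1),
      population_density = dens * growth,
      urbanization_rate = pmin(urb + 0.005 * (k - 1), 1),
      stringsAsFactors = FALSE
    )
    truth_rows[[k]] <- data.frame(
      unit_id = unit_id, year = years[k], efficiency = eff,
      stringsAsFactors = FALSE
    )
  }
  panel <- validate_panel(do.call(rbind, rows))
  truth_eff <- do.call(rbind, truth_rows)
  truth_eff <- truth_eff[order(truth_eff$unit_id, truth_eff$year), ]
  rownames(truth_eff) <- NULL
  list(panel = panel, truth = list(efficiency = truth_eff, config = config))
}

#' Generate a censored-regression sample with known coefficients
#'
#' Draws a design matrix (intercept plus standard-normal covariates),
#' latent responses `X beta + e` with Gaussian noise, and censors them from
#' above at `upper_limit`. The analytically expected censoring fraction
#' `mean(Phi((X beta - limit) / sigma))` is returned alongside.
#'
#' @param n number of observations (must exceed `length(beta)`).
#' @param beta coefficient vector; the first element is the intercept.
#' @param sigma positive noise standard deviation.
#' @param seed integer seed.
#' @param upper_limit censoring limit (default 1).
#' @return List with `X` (including the intercept column), `y` (censored),
#'   `latent`, `censored` (logical), `expected_censoring`, and the truth
#'   (`beta`, `sigma`).
#' @export
generate_tobit_sample <- function(n, beta, sigma, seed = 1L, upper_limit = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  p <- length(beta)
  if (n <= p) stop("n must exceed the number of coefficients")
  withr::with_seed(seed, {
    X <- cbind(1, matrix(stats::rnorm(n * (p - 1)), n, p - 1))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
    mu <- as.vector(X %*% beta)
    latent <- mu + stats::rnorm(n, 0, sigma)
    y <- pmin(latent, upper_limit)
    list(
      X = X, y = y, latent = latent, censored = latent >= upper_limit,
      expected_censoring = mean(stats::pnorm((mu - upper_limit) / sigma)),
      beta = beta, sigma = sigma
    )
  })
}
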
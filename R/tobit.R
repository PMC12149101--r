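# Right-censored (upper limit) Gaussian Tobit regression of DEA efficiency
# scores on development, resource-quantity and fairness covariates, fitted by
# maximum likelihood from OLS starting values.

#' Build the efficiency-determinants regression table
#'
#' Joins the DEA comprehensive-efficiency scores (response) with context
#' covariates and fairness (Theil) covariates, one row per unit-year.
#' Logs are applied to per-capita GDP, population density, health technical
#' personnel, beds and total assets (`lngdp`, `lnpd`, `lnpeople`, `lnbed`,
#' `lnassets`); the urbanization rate enters untransformed as a fraction.
#' The fairness covariates `people`, `bed` and `assets` are the Theil indices
#' of personnel (`X1`), beds (`X4`) and total assets (`X5`): by default the
#' within index of the unit's own region for that year (so all provinces of
#' one region share the value), or the national overall index when the
#' config's `theil_covariate_rule` is `"national"`.
#'
#' @param panel validated panel data frame.
#' @param dea_scores data frame from [dea_all_years()] (needs `unit_id`,
#'   `year`, `te`).
#' @param config [analysis_config()].
#' @return Data frame with `unit_id`, `year`, response `efficiency`, and
#'   covariates `lngdp`, `lnpd`, `urban`, `lnpeople`, `lnbed`, `lnassets`,
#'   `people`, `bed`, `assets`.
#' @export
build_regression_table <- function(panel, dea_scores,
                                   config = analysis_config()) {
  panel <- validate_panel(panel, require_regions = TRUE)
  need <- c("unit_id", "year", "te")
  if (!all(need %in% names(dea_scores))) {
    stop("dea_scores must have columns: ", paste(need, collapse = ", "))
  }
  key_panel <- paste(panel$unit_id, panel$year)
  key_dea <- paste(dea_scores$unit_id, dea_scores$year)
  if (!setequal(key_panel, key_dea)) {
    stop("panel and dea_scores must cover the same unit-year pairs")
  }
  te <- dea_scores$te[match(key_panel, key_dea)]

  safe_log <- function(v, nm) {
    bad <- which(v <= 0)
    if (length(bad) > 0) {
      stop(sprintf("non-positive value under log for %s (unit '%s', year %d)",
                   nm, panel$unit_id[bad[1]], panel$year[bad[1]]))
    }
    log(v)
  }

  # fairness covariates: Theil index per (indicator, year), assigned per row
  theil_ind <- c(people = "X1", bed = "X4", assets = "X5")
  years <- sort(unique(panel$year))
  theil_cov <- sapply(theil_ind, function(ind) {
    per_year <- lapply(years, function(y) theil_decompose(panel, ind, y))
    names(per_year) <- as.character(years)
    vapply(seq_len(nrow(panel)), function(i) {
      d <- per_year[[as.character(panel$year[i])]]
      if (config$theil_covariate_rule == "national") {
        d$total
      } else {
        d$regions$theil[match(panel$region[i], d$regions$region)]
      }
    }, numeric(1))
  })

  data.frame(
    unit_id = panel$unit_id,
    year = panel$year,
    efficiency = te,
    lngdp = safe_log(panel$gdp_per_capita, "gdp_per_capita"),
    lnpd = safe_log(panel$population_density, "population_density"),
    urban = panel$urbanization_rate,
    lnpeople = safe_log(panel$X1, "X1"),
    lnbed = safe_log(panel$X4, "X4"),
    lnassets = safe_log(panel$X5, "X5"),
    people = theil_cov[, "people"],
    bed = theil_cov[, "bed"],
    assets = theil_cov[, "assets"],
    stringsAsFactors = FALSE
  )
}

#' Censored-Gaussian log-likelihood
#'
#' Log-likelihood of a Tobit model with an upper censoring limit: uncensored
#' observations contribute the Gaussian density, censored ones the upper-tail
#' probability `P(latent >= limit)`.
#'
#' @param beta coefficient vector (matching columns of `X`).
#' @param sigma positive scale.
#' @param y response vector.
#' @param X design matrix.
#' @param censored logical vector marking observations at the limit.
#' @param upper_limit censoring limit.
#' @return Scalar log-likelihood.
#' @export
tobit_loglik <- function(beta, sigma, y, X, censored, upper_limit = 1) {
  mu <- as.vector(X %*% beta)
  ll_unc <- stats::dnorm(y[!censored], mu[!censored], sigma, log = TRUE)
  ll_cen <- stats::pnorm((mu[censored] - upper_limit) / sigma, log.p = TRUE)
  sum(ll_unc) + sum(ll_cen)
}

#' Fit an upper-censored Tobit model
#'
#' Maximum-likelihood fit of `y = min(X beta + e, limit)`, `e ~ N(0, s^2)`.
#' Observations with `y >= limit - censor_tol` are treated as censored.
#' Optimization is BFGS on `(beta, log s)` with analytic gradient, started
#' from the OLS solution; standard errors come from the inverse observed
#' information at the optimum (delta method for `s`). z statistics and
#' two-sided p values use the normal reference distribution.
#'
#' @param table regression table from [build_regression_table()], or any data
#'   frame with a response column and numeric covariate columns.
#' @param response name of the response column.
#' @param covariates covariate column names; default all numeric columns
#'   except the response, `unit_id` and `year`. An intercept is always added.
#' @param upper_limit censoring limit (default 1, the DEA frontier).
#' @param censor_tol responses within this distance of the limit count as
#'   censored.
#' @return Object of class `"tobit_fit"`: list with `coefficients`, `sigma`,
#'   `se` (including `sigma`'s), `z`, `p`, `loglik`, `n`, `n_censored`,
#'   `converged`, `gradient`, and the data used.
#' @export
fit_tobit <- function(table, response = "efficiency", covariates = NULL,
                      upper_limit = 1, censor_tol = 1e-6) {
  table <- as.data.frame(table)
  if (!response %in% names(table)) stop("response column not found: ", response)
  if (is.null(covariates)) {
    covariates <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                          c(response, "year"))
  }
  y <- table[[response]]
  X <- cbind(`(Intercept)` = 1, as.matrix(table[, covariates, drop = FALSE]))
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("need more rows than parameters")
  qr_X <- qr(X)
  if (qr_X$rank < p) {
    keep <- qr_X$pivot[seq_len(qr_X$rank)]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(setdiff(colnames(X), colnames(X)[keep]), collapse = ", "))
  }
  censored <- y >= upper_limit - censor_tol
  if (all(censored)) stop("all observations censored; model not identifiable")

  # OLS start
  beta0 <- qr.coef(qr_X, y)
  sigma0 <- sqrt(sum((y - X %*% beta0)^2) / n)
  if (sigma0 <= 0) sigma0 <- 1e-6
  theta0 <- c(beta0, log(sigma0))

  negll <- function(theta) {
    beta <- theta[seq_len(p)]; sigma <- exp(theta[p + 1])
    -tobit_loglik(beta, sigma, y, X, censored, upper_limit)
  }
  neggrad <- function(theta) {
    beta <- theta[seq_len(p)]; sigma <- exp(theta[p + 1])
    mu <- as.vector(X %*% beta)
    g_beta <- numeric(p); g_lsig <- 0
    if (any(!censored)) {
      r <- (y[!censored] - mu[!censored]) / sigma
      g_beta <- g_beta + colSums(X[!censored, , drop = FALSE] * r) / sigma
      g_lsig <- g_lsig + sum(r^2 - 1)
    }
    if (any(censored)) {
      z <- (mu[censored] - upper_limit) / sigma
      # d/dz log Phi(z) = phi(z)/Phi(z), computed stably in logs
      lambda <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
      g_beta <- g_beta + colSums(X[censored, , drop = FALSE] * lambda) / sigma
      g_lsig <- g_lsig - sum(lambda * z)
    }
    -c(g_beta, g_lsig)
  }

  opt <- stats::optim(theta0, negll, neggrad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  # Newton-style polish via another BFGS pass from the optimum
  opt <- stats::optim(opt$par, negll, neggrad, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-14))

  theta_hat <- opt$par
  beta_hat <- theta_hat[seq_len(p)]
  sigma_hat <- unname(exp(theta_hat[p + 1]))

  hess <- stats::optimHess(theta_hat, negll, neggrad)
  vcov_theta <- tryCatch(solve(hess), error = function(e) {
    warning("observed information singular; standard errors unavailable")
    matrix(NA_real_, p + 1, p + 1)
  })
  se <- sqrt(pmax(diag(vcov_theta), 0))
  se_beta <- se[seq_len(p)]
  se_sigma <- se[p + 1] * sigma_hat   # delta method from log-sigma

  names(beta_hat) <- names(se_beta) <- colnames(X)
  z <- beta_hat / se_beta
  list_out <- list(
    coefficients = beta_hat,
    sigma = sigma_hat,
    se = c(se_beta, sigma = se_sigma),
    z = z,
    p = 2 * stats::pnorm(-abs(z)),
    loglik = unname(-opt$value),
    n = n,
    n_censored = sum(censored),
    n_uncensored = sum(!censored),
    converged = opt$convergence == 0,
    gradient = -neggrad(theta_hat),
    upper_limit = upper_limit,
    y = y, X = X, censored = censored
  )
  class(list_out) <- "tobit_fit"
  list_out
}

#' @export
print.tobit_fit <- function(x, ...) {
  cat(sprintf("Tobit fit: n = %d (%d censored at %g), logLik = %.4f, sigma = %.5f\n",
              x$n, x$n_censored, x$upper_limit, x$loglik, x$sigma))
  print(tobit_report(x))
  invisible(x)
}

#' Tobit regression report table
#'
#' One row per term with coefficient, standard error, z statistic, two-sided
#' p value and significance stars (`**` at 5%, `***` at 1%).
#'
#' @param fit a `"tobit_fit"` object.
#' @return Data frame with columns `term`, `estimate`, `se`, `z`, `p`,
#'   `stars`.
#' @export
tobit_report <- function(fit) {
  stopifnot(inherits(fit, "tobit_fit"))
  stars <- ifelse(fit$p <= 0.01, "***", ifelse(fit$p <= 0.05, "**", ""))
  data.frame(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    se = unname(fit$se[seq_along(fit$coefficients)]),
    z = unname(fit$z),
    p = unname(fit$p),
    stars = unname(stars),
    stringsAsFactors = FALSE
  )
}
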
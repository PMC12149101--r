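# Input-oriented envelopment programs (CCR / BCC), solved in two stages:
# stage 1 finds the radial contraction theta*, stage 2 fixes theta* and
# maximizes the slack sum, the standard numerically stable equivalent of the
# non-Archimedean epsilon objective. Data are rescaled dimension-wise before
# solving (DEA scores are units-invariant; slacks are scaled back).

#' Solve one input-oriented envelopment program
#'
#' Evaluates one decision-making unit against a reference technology spanned
#' by the columns of `X` (inputs) and `Y` (outputs). Stage 1 minimizes the
#' radial input contraction `theta` subject to `X lambda + s- = theta x0`,
#' `Y lambda - s+ = y0`, `lambda >= 0` (plus `sum(lambda) = 1` under variable
#' returns to scale); stage 2 fixes `theta*` and maximizes the total slack.
#'
#' Cross-period evaluations (the unit need not belong to the reference set)
#' are allowed; under constant returns the program is always feasible and
#' `theta` may exceed 1. Under variable returns a cross-period program can be
#' infeasible, in which case `theta` is `NA` and `feasible` is `FALSE`.
#'
#' @param x0,y0 positive input and output vectors of the evaluated unit.
#' @param X,Y reference input (`m x n`) and output (`s x n`) matrices,
#'   columns = reference units.
#' @param vrs logical; `TRUE` adds the convexity constraint `sum(lambda) = 1`
#'   (BCC), `FALSE` is the constant-returns CCR program.
#' @param tolerance numeric tolerance used when reporting near-zero slacks.
#' @return List with `theta`, `lambda` (named by reference column names when
#'   present), `slack_input`, `slack_output`, `lambda_sum`, `feasible`.
#' @export
solve_envelopment <- function(x0, y0, X, Y, vrs = FALSE, tolerance = 1e-9) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  m <- nrow(X); s <- nrow(Y); n <- ncol(X)
  stopifnot(length(x0) == m, length(y0) == s, ncol(Y) == n)
  if (any(X <= 0) || any(Y <= 0) || any(x0 <= 0) || any(y0 <= 0)) {
    stop("envelopment data must be strictly positive")
  }

  # dimension-wise rescaling for numerical stability (theta is invariant)
  fx <- exp(rowMeans(log(X))); fy <- exp(rowMeans(log(Y)))
  Xs <- X / fx; Ys <- Y / fy
  x0s <- x0 / fx; y0s <- y0 / fy

  # stage 1: variables (theta, lambda), minimize theta
  st1 <- lp_solve(
    obj = c(1, rep(0, n)),
    A = rbind(cbind(-x0s, Xs), cbind(0, Ys),
              if (vrs) c(0, rep(1, n))),
    b = c(rep(0, m), y0s, if (vrs) 1),
    sense = c(rep("<=", m), rep(">=", s), if (vrs) "=")
  )
  if (st1$status != "optimal") {
    if (vrs && st1$status == "infeasible") {
      return(list(theta = NA_real_, lambda = rep(NA_real_, n),
                  slack_input = rep(NA_real_, m), slack_output = rep(NA_real_, s),
                  lambda_sum = NA_real_, feasible = FALSE))
    }
    stop("envelopment LP did not solve (", st1$status, "); check the panel data")
  }
  theta <- st1$value

  # stage 2: with theta fixed the slack sum is linear in lambda alone
  # (s- = theta x0 - X lambda, s+ = Y lambda - y0), so maximize
  # (colSums(Y) - colSums(X)) lambda over the stage-1 feasible set. A tiny
  # inflation of theta keeps the stage-1 optimum feasible under floating
  # error.
  theta_use <- theta + 1e-9 * max(1, abs(theta))
  st2 <- lp_solve(
    obj = colSums(Ys) - colSums(Xs),
    A = rbind(Xs, Ys, if (vrs) rep(1, n)),
    b = c(theta_use * x0s, y0s, if (vrs) 1),
    sense = c(rep("<=", m), rep(">=", s), if (vrs) "="),
    maximize = TRUE
  )
  # stage 2 is feasible by construction (the stage-1 vertex satisfies it);
  # fall back on the stage-1 lambda if it were ever rejected numerically
  lambda <- if (st2$status == "optimal") st2$solution else st1$solution[-1]
  slack_in <- pmax(theta_use * x0s - as.vector(Xs %*% lambda), 0)
  slack_out <- pmax(as.vector(Ys %*% lambda) - y0s, 0)
  slack_in[slack_in < tolerance] <- 0
  slack_out[slack_out < tolerance] <- 0
  names(lambda) <- colnames(X)
  list(
    theta = theta,
    lambda = lambda,
    slack_input = slack_in * fx,
    slack_output = slack_out * fy,
    lambda_sum = sum(lambda),
    feasible = TRUE
  )
}

# Build the (inputs x units) and (outputs x units) matrices for one year.
year_technology <- function(panel, year, config) {
  rows <- panel[panel$year == year, , drop = FALSE]
  if (nrow(rows) == 0) stop("year not present in panel: ", year)
  rows <- rows[order(rows$unit_id), , drop = FALSE]
  X <- t(as.matrix(rows[, config$input_indicators, drop = FALSE]))
  Y <- t(as.matrix(rows[, config$output_indicators, drop = FALSE]))
  colnames(X) <- colnames(Y) <- rows$unit_id
  list(X = X, Y = Y, units = rows$unit_id, region = rows$region)
}

#' Score one unit-year under CCR and BCC
#'
#' Computes overall technical efficiency (TE, constant returns), pure
#' technical efficiency (PTE, variable returns), scale efficiency
#' SE = TE/PTE, a returns-to-scale label from the CCR peer-weight sum
#' (`sum(lambda) < 1` increasing, `> 1` decreasing, else constant), BCC
#' slacks and frontier projection targets.
#'
#' @param panel validated panel data frame.
#' @param unit unit id present in the panel.
#' @param year year present in the panel.
#' @param config [analysis_config()].
#' @return Object of class `"dea_score"`: a list with `unit`, `year`, `te`,
#'   `pte`, `se`, `rts` (`"irs"`, `"crs"` or `"drs"`), `efficient`,
#'   `lambda_crs`, `lambda_vrs`, `slack_input`, `slack_output` (BCC),
#'   `inputs`, `outputs`, `projected_inputs`, `projected_outputs`.
#' @export
score_unit <- function(panel, unit, year, config = analysis_config()) {
  panel <- validate_panel(panel)
  tech <- year_technology(panel, year, config)
  j <- match(unit, tech$units)
  if (is.na(j)) stop("unit not present in year ", year, ": ", unit)
  x0 <- stats::setNames(tech$X[, j], rownames(tech$X))
  y0 <- stats::setNames(tech$Y[, j], rownames(tech$Y))

  crs <- solve_envelopment(x0, y0, tech$X, tech$Y, vrs = FALSE,
                           tolerance = config$lp_tolerance)
  vrs <- solve_envelopment(x0, y0, tech$X, tech$Y, vrs = TRUE,
                           tolerance = config$lp_tolerance)

  te <- min(crs$theta, 1)
  pte <- min(vrs$theta, 1)
  tol <- config$lp_tolerance
  rts <- if (crs$lambda_sum < 1 - tol) "irs"
         else if (crs$lambda_sum > 1 + tol) "drs"
         else "crs"
  efficient <- pte >= 1 - config$effective_threshold &&
    sum(vrs$slack_input) + sum(vrs$slack_output) <= tol * (length(x0) + length(y0))

  structure(
    list(
      unit = unit, year = as.integer(year),
      te = te, pte = pte, se = te / pte, rts = rts, efficient = efficient,
      lambda_crs = crs$lambda, lambda_vrs = vrs$lambda,
      slack_input = vrs$slack_input, slack_output = vrs$slack_output,
      inputs = x0, outputs = y0,
      projected_inputs = pte * x0 - vrs$slack_input,
      projected_outputs = y0 + vrs$slack_output
    ),
    class = "dea_score"
  )
}

#' @export
print.dea_score <- function(x, ...) {
  cat(sprintf("DEA score %s, %d: TE = %.4f, PTE = %.4f, SE = %.4f, RTS = %s\n",
              x$unit, x$year, x$te, x$pte, x$se, x$rts))
  invisible(x)
}

#' Projection (redundancy / insufficiency) of one scored unit
#'
#' For each input, the redundancy value is the amount removable to reach the
#' BCC frontier target, `(1 - PTE) * x0 + s-`, and the redundancy rate is
#' value / actual. For each output, the insufficient value is the slack `s+`
#' and the insufficient rate is `s+ / actual`. Efficient units have all
#' values and rates zero.
#'
#' @param score a `"dea_score"` from [score_unit()].
#' @return Data frame with columns `indicator`, `kind` (`"input_redundancy"`
#'   or `"output_insufficiency"`), `actual`, `value`, `rate_percent`.
#' @export
projection <- function(score) {
  stopifnot(inherits(score, "dea_score"))
  red <- (1 - score$pte) * score$inputs + score$slack_input
  ins <- score$slack_output
  out <- data.frame(
    unit_id = score$unit,
    year = score$year,
    indicator = c(names(score$inputs), names(score$outputs)),
    kind = c(rep("input_redundancy", length(red)),
             rep("output_insufficiency", length(ins))),
    actual = c(score$inputs, score$outputs),
    value = c(red, ins),
    rate_percent = 100 * c(red / score$inputs, ins / score$outputs),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' DEA score table for one year
#'
#' One row per unit with TE, PTE, SE and the returns-to-scale label
#' (constant returns printed as `"-"`). Summary statistics (means and the
#' count of DEA-effective units) are attached as the `"summary"` attribute;
#' see [dea_summary()].
#'
#' @param panel validated panel data frame.
#' @param year year to score.
#' @param config [analysis_config()].
#' @return Data frame with columns `unit_id`, `region`, `year`, `te`, `pte`,
#'   `se`, `rts`, `efficient`.
#' @export
dea_year_table <- function(panel, year, config = analysis_config()) {
  panel <- validate_panel(panel)
  tech <- year_technology(panel, year, config)
  if (length(tech$units) < 2) stop("need at least 2 units to score a year")
  scores <- lapply(tech$units, function(u) score_unit(panel, u, year, config))
  out <- data.frame(
    unit_id = tech$units,
    region = tech$region,
    year = as.integer(year),
    te = vapply(scores, `[[`, numeric(1), "te"),
    pte = vapply(scores, `[[`, numeric(1), "pte"),
    se = vapply(scores, `[[`, numeric(1), "se"),
    rts = vapply(scores, function(s) if (s$rts == "crs") "-" else s$rts,
                 character(1)),
    efficient = vapply(scores, `[[`, logical(1), "efficient"),
    stringsAsFactors = FALSE
  )
  attr(out, "summary") <- dea_summary(out, digits = config$digits,
                                      effective_threshold = config$effective_threshold)
  attr(out, "scores") <- scores
  out
}

#' Summary row of a DEA score table
#'
#' Arithmetic means of the efficiency columns (rounded half-up) and the count
#' of DEA-effective units (TE at the frontier within the threshold). Works on
#' any data frame with a `te` column and, optionally, `pte` / `se` columns,
#' including transcriptions of published efficiency tables.
#'
#' @param scores data frame with a `te` column (optionally `pte`, `se`).
#' @param digits rounding digits for the means.
#' @param effective_threshold tolerance for counting TE as effective.
#' @return One-row data frame with `mean_te`, `mean_pte`, `mean_se`,
#'   `effective_count`, `n`.
#' @export
dea_summary <- function(scores, digits = 3L, effective_threshold = 1e-6) {
  stopifnot("te" %in% names(scores), nrow(scores) > 0)
  data.frame(
    mean_te = round_half_up(mean(scores$te), digits),
    mean_pte = if ("pte" %in% names(scores))
      round_half_up(mean(scores$pte), digits) else NA_real_,
    mean_se = if ("se" %in% names(scores))
      round_half_up(mean(scores$se), digits) else NA_real_,
    effective_count = sum(scores$te >= 1 - effective_threshold),
    n = nrow(scores)
  )
}

#' DEA scores for all years of a panel
#'
#' Runs [dea_year_table()] on every panel year and binds the rows.
#'
#' @param panel validated panel data frame.
#' @param config [analysis_config()].
#' @param years years to score; default all.
#' @return Data frame as in [dea_year_table()], all years stacked.
#' @export
dea_all_years <- function(panel, config = analysis_config(), years = NULL) {
  panel <- validate_panel(panel)
  if (is.null(years)) years <- sort(unique(panel$year))
  do.call(rbind, lapply(years, function(y) {
    tab <- dea_year_table(panel, y, config)
    attr(tab, "summary") <- NULL; attr(tab, "scores") <- NULL
    tab
  }))
}

#' Projection table for the non-pure-technically-efficient units of a year
#'
#' Input redundancy and output insufficiency values and rates for every unit
#' whose PTE is below 1, in the layout of published projection tables.
#'
#' @inheritParams dea_year_table
#' @return Data frame as in [projection()], one block per inefficient unit,
#'   with a `region` column.
#' @export
projection_table <- function(panel, year, config = analysis_config()) {
  tab <- dea_year_table(panel, year, config)
  scores <- attr(tab, "scores")
  keep <- vapply(scores, function(s) s$pte < 1 - config$effective_threshold,
                 logical(1))
  if (!any(keep)) {
    return(data.frame(unit_id = character(), year = integer(),
                      indicator = character(), kind = character(),
                      actual = numeric(), value = numeric(),
                      rate_percent = numeric(), region = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(scores[keep], projection))
  out$region <- tab$region[match(out$unit_id, tab$unit_id)]
  rownames(out) <- NULL
  out
}
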
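#' Theil-T inequality index
#'
#' Entropy measure of how unevenly a resource is distributed relative to a
#' weighting population: `T = sum_j s_j * log(s_j / w_j)` where `s_j` is
#' unit j's share of the resource and `w_j` its share of the weights.
#' `T = 0` means every unit holds exactly its population share; larger values
#' mean stronger concentration. Zero-amount units contribute 0 (the
#' `x log x -> 0` limit); a zero-weight unit holding a positive amount makes
#' the index undefined and is an error.
#'
#' @param amounts non-negative resource amounts, not all zero.
#' @param weights positive weights (typically resident population).
#' @return Non-negative scalar.
#' @export
theil_index <- function(amounts, weights) {
  if (length(amounts) != length(weights) || length(amounts) < 1) {
    stop("amounts and weights must be equal-length, non-empty vectors")
  }
  if (any(amounts < 0) || any(weights < 0)) {
    stop("amounts and weights must be non-negative")
  }
  if (sum(amounts) <= 0) stop("all amounts are zero; Theil index undefined")
  if (sum(weights) <= 0) stop("weights must have positive sum")
  if (any(weights == 0 & amounts > 0)) {
    stop("zero-weight unit with positive amount: Theil index undefined")
  }
  s <- amounts / sum(amounts)
  w <- weights / sum(weights)
  pos <- s > 0
  sum(s[pos] * log(s[pos] / w[pos]))
}

#' Within/between-region Theil decomposition
#'
#' Two-level decomposition of the Theil-T index of one indicator in one
#' year. Within each region the index `T_i` is computed over that region's
#' units; the between component `Tb` is the index over region aggregates; the
#' within component is the resource-share-weighted mean
#' `Tw = sum_i (Y_i / Y) T_i`; and the decomposition is exact:
#' `T = Tw + Tb`. Contribution rates are `Tw/T` and `Tb/T` in percent, `NA`
#' when `T = 0` (perfect equality).
#'
#' @param panel validated panel data frame ([validate_panel()]).
#' @param indicator indicator column name (e.g. `"X1"`).
#' @param year calendar year present in the panel.
#' @return An object of class `"theil_decomposition"`: a list with fields
#'   `indicator`, `year`, `total`, `within`, `between`, `within_contribution`,
#'   `between_contribution` (percent), and `regions`, a data frame of
#'   per-region indices `T_i` and resource shares.
#' @export
theil_decompose <- function(panel, indicator, year) {
  panel <- validate_panel(panel, require_regions = TRUE)
  if (!indicator %in% c(PANEL_INPUTS, PANEL_OUTPUTS)) {
    stop("unknown indicator: ", indicator)
  }
  rows <- panel[panel$year == year, , drop = FALSE]
  if (nrow(rows) == 0) stop("year not present in panel: ", year)

  amounts <- rows[[indicator]]
  weights <- rows$population
  regions <- sort(unique(rows$region))

  t_i <- vapply(regions, function(r) {
    sel <- rows$region == r
    theil_index(amounts[sel], weights[sel])
  }, numeric(1))
  y_i <- vapply(regions, function(r) sum(amounts[rows$region == r]), numeric(1))
  w_i <- vapply(regions, function(r) sum(weights[rows$region == r]), numeric(1))
  share <- y_i / sum(y_i)

  between <- theil_index(y_i, w_i)
  within <- sum(share * t_i)
  total <- within + between

  structure(
    list(
      indicator = indicator,
      year = as.integer(year),
      total = total,
      within = within,
      between = between,
      within_contribution = if (total > 0) 100 * within / total else NA_real_,
      between_contribution = if (total > 0) 100 * between / total else NA_real_,
      regions = data.frame(
        region = regions,
        theil = unname(t_i),
        resource_share = unname(share),
        population_share = unname(w_i / sum(w_i)),
        stringsAsFactors = FALSE
      )
    ),
    class = "theil_decomposition"
  )
}

#' @export
print.theil_decomposition <- function(x, ...) {
  cat(sprintf(
    "Theil decomposition of %s, %d: T = %.6f (within %.6f [%s%%], between %.6f [%s%%])\n",
    x$indicator, x$year, x$total, x$within,
    ifelse(is.na(x$within_contribution), "NA", sprintf("%.2f", x$within_contribution)),
    x$between,
    ifelse(is.na(x$between_contribution), "NA", sprintf("%.2f", x$between_contribution))
  ))
  invisible(x)
}

#' Theil decomposition table over indicators and years
#'
#' One row per indicator-year with the overall index, the within and between
#' components and their contribution rates (percent), in the layout used for
#' published inequality tables.
#'
#' @param panel validated panel data frame.
#' @param indicators character vector of indicator columns (non-empty).
#' @param years integer vector of years (non-empty); defaults to all panel
#'   years.
#' @return Data frame with columns `indicator`, `year`, `total`, `within`,
#'   `within_contribution`, `between`, `between_contribution`.
#' @export
theil_table <- function(panel, indicators = c("X1", "X2", "X3", "X4", "X5"),
                        years = NULL) {
  panel <- validate_panel(panel, require_regions = TRUE)
  if (is.null(years)) years <- sort(unique(panel$year))
  if (length(indicators) == 0 || length(years) == 0) {
    stop("indicators and years must be non-empty")
  }
  grid <- expand.grid(year = years, indicator = indicators,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    d <- theil_decompose(panel, grid$indicator[i], grid$year[i])
    data.frame(
      indicator = d$indicator, year = d$year, total = d$total,
      within = d$within, within_contribution = d$within_contribution,
      between = d$between, between_contribution = d$between_contribution,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out[order(match(out$indicator, indicators), out$year), , drop = FALSE]
}
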
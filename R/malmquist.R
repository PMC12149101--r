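# Malmquist total factor productivity index between adjacent years, with the
# standard decomposition: distances for the index, effch and techch are
# constant-returns (CRS); pech uses same-period variable-returns distances;
# sech = effch / pech. Input orientation throughout, matching the static
# analysis. Distances are Farrell efficiencies (same-period values <= 1;
# cross-period values may exceed 1).

#' Input-oriented distance of a point to a period's frontier
#'
#' Radial efficiency of the bundle `(x, y)` measured against the technology
#' spanned by the units observed in `frontier_year`. Same-period values lie
#' in (0, 1]; cross-period values can exceed 1 (the point dominates the old
#' frontier). Under variable returns a cross-period program can be
#' infeasible; `NA` is returned with a warning in that case.
#'
#' @param panel validated panel data frame.
#' @param x,y positive input/output vectors (in the order of
#'   `config$input_indicators` / `config$output_indicators`).
#' @param frontier_year year whose observed units span the technology.
#' @param config [analysis_config()].
#' @param vrs logical; variable returns to scale.
#' @return Positive scalar, or `NA` for an infeasible VRS cross-period
#'   program.
#' @export
cross_period_distance <- function(panel, x, y, frontier_year,
                                  config = analysis_config(), vrs = FALSE) {
  panel <- validate_panel(panel)
  tech <- year_technology(panel, frontier_year, config)
  sol <- solve_envelopment(x, y, tech$X, tech$Y, vrs = vrs,
                           tolerance = config$lp_tolerance)
  if (!sol$feasible) {
    warning("VRS cross-period program infeasible against frontier year ",
            frontier_year)
    return(NA_real_)
  }
  sol$theta
}

#' Malmquist decomposition for one unit and one adjacent-year pair
#'
#' Computes the four CRS distance-function values
#' `D^t(x^t, y^t)`, `D^{t+1}(x^{t+1}, y^{t+1})`, `D^t(x^{t+1}, y^{t+1})`,
#' `D^{t+1}(x^t, y^t)` and the decomposition
#' `effch = D^{t+1}(x^{t+1},y^{t+1}) / D^t(x^t,y^t)`,
#' `techch = sqrt[ D^t(t+1)/D^{t+1}(t+1) * D^t(t)/D^{t+1}(t) ]`,
#' `pech` = ratio of same-period VRS efficiencies, `sech = effch / pech`,
#' `tfpch = effch * techch`. Values above 1 indicate improvement between `t`
#' and `t + 1`.
#'
#' @param panel validated panel data frame.
#' @param unit unit id.
#' @param t first year of the adjacent pair (`t + 1` must also be present).
#' @param config [analysis_config()].
#' @return One-row data frame with the unit, the period pair, the four CRS
#'   distances (`d_tt`, `d_t1t1`, `d_t_t1`, `d_t1_t`), and `effch`,
#'   `techch`, `pech`, `sech`, `tfpch`.
#' @export
malmquist_decompose <- function(panel, unit, t, config = analysis_config()) {
  panel <- validate_panel(panel)
  years <- sort(unique(panel$year))
  t <- as.integer(t)
  if (!(t %in% years) || !((t + 1L) %in% years)) {
    stop("years ", t, " and ", t + 1L, " must both be present")
  }
  pick <- function(yr) {
    row <- panel[panel$unit_id == unit & panel$year == yr, , drop = FALSE]
    if (nrow(row) != 1) stop("unit not present: ", unit, " in ", yr)
    list(x = as.numeric(row[, config$input_indicators]),
         y = as.numeric(row[, config$output_indicators]))
  }
  b_t <- pick(t); b_t1 <- pick(t + 1L)

  d_tt   <- cross_period_distance(panel, b_t$x,  b_t$y,  t,      config, vrs = FALSE)
  d_t1t1 <- cross_period_distance(panel, b_t1$x, b_t1$y, t + 1L, config, vrs = FALSE)
  d_t_t1 <- cross_period_distance(panel, b_t1$x, b_t1$y, t,      config, vrs = FALSE)
  d_t1_t <- cross_period_distance(panel, b_t$x,  b_t$y,  t + 1L, config, vrs = FALSE)
  v_tt   <- cross_period_distance(panel, b_t$x,  b_t$y,  t,      config, vrs = TRUE)
  v_t1t1 <- cross_period_distance(panel, b_t1$x, b_t1$y, t + 1L, config, vrs = TRUE)

  effch <- d_t1t1 / d_tt
  techch <- sqrt((d_t_t1 / d_t1t1) * (d_tt / d_t1_t))
  pech <- v_t1t1 / v_tt
  sech <- effch / pech
  tfpch <- effch * techch

  data.frame(
    unit_id = unit, from = t, to = t + 1L,
    d_tt = d_tt, d_t1t1 = d_t1t1, d_t_t1 = d_t_t1, d_t1_t = d_t1_t,
    effch = effch, techch = techch, pech = pech, sech = sech, tfpch = tfpch,
    stringsAsFactors = FALSE
  )
}

#' Malmquist records for every unit and adjacent-year pair
#'
#' @param panel validated panel data frame (needs at least 2 years).
#' @param config [analysis_config()].
#' @return Data frame of [malmquist_decompose()] rows, ordered by unit then
#'   period.
#' @export
malmquist_all <- function(panel, config = analysis_config()) {
  panel <- validate_panel(panel)
  years <- sort(unique(panel$year))
  if (length(years) < 2) stop("Malmquist analysis needs at least 2 years")
  units <- sort(unique(panel$unit_id))
  pairs <- years[-length(years)]
  out <- lapply(units, function(u) {
    do.call(rbind, lapply(pairs, function(t) malmquist_decompose(panel, u, t, config)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Geometric-mean summaries of Malmquist records
#'
#' Multiplicative indices are averaged geometrically: per adjacent-year pair
#' (across units) and per unit (across year pairs). The product identities
#' `tfpch = effch * techch = techch * pech * sech` carry over to the means.
#'
#' @param records data frame from [malmquist_all()].
#' @return List of two data frames, `by_period` and `by_unit`, each with
#'   geometric means of `effch`, `techch`, `pech`, `sech`, `tfpch`.
#' @export
malmquist_summary <- function(records) {
  if (nrow(records) == 0) stop("no Malmquist records to summarize")
  comps <- c("effch", "techch", "pech", "sech", "tfpch")
  gm_by <- function(keys) {
    split_idx <- split(seq_len(nrow(records)), keys)
    rows <- lapply(names(split_idx), function(k) {
      idx <- split_idx[[k]]
      vals <- vapply(comps, function(cm) geometric_mean(records[[cm]][idx]),
                     numeric(1))
      as.data.frame(as.list(vals))
    })
    out <- do.call(rbind, rows)
    cbind(key = names(split_idx), out, stringsAsFactors = FALSE)
  }
  by_period <- gm_by(paste(records$from, records$to, sep = "-"))
  names(by_period)[1] <- "period"
  by_unit <- gm_by(records$unit_id)
  names(by_unit)[1] <- "unit_id"
  list(by_period = by_period, by_unit = by_unit)
}
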
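#' @keywords internal
"_PACKAGE"

# Canonical column layout of the tidy panel. One row per unit-year.
PANEL_INPUTS <- c("X1", "X2", "X3", "X4", "X5", "X6")
PANEL_OUTPUTS <- c("Y1", "Y2", "Y3")
PANEL_COVARIATES <- c("gdp_per_capita", "population_density", "urbanization_rate")
PANEL_REGIONS <- c("eastern", "central", "western")

PANEL_COLUMNS <- c(
  "unit_id", "region", "year",
  PANEL_INPUTS, PANEL_OUTPUTS,
  "population", PANEL_COVARIATES
)

# Indicator labels used in reports.
INDICATOR_LABELS <- c(
  X1 = "Health Technical Personnel",
  X2 = "Practicing (assistant) Physicians",
  X3 = "Registered Nurses",
  X4 = "Number of Beds",
  X5 = "Total Assets",
  X6 = "Total Health Expenses",
  Y1 = "Bed Utilization Rate",
  Y2 = "Outpatient and Emergency Visits",
  Y3 = "Discharges"
)

#' Analysis configuration
#'
#' Collects the tunable settings shared by all analysis stages: which
#' indicator columns enter the DEA envelopment programs, which are scanned by
#' the Theil inequality decomposition, numerical tolerances, and report
#' rounding.
#'
#' The default DEA input set is personnel, physicians, nurses, beds and total
#' health expenses (`X1`--`X4`, `X6`); total assets (`X5`) is kept for the
#' fairness analysis, whose default indicator set is `X1`--`X5`.
#'
#' @param input_indicators character vector of input column names for DEA.
#' @param output_indicators character vector of output column names for DEA.
#' @param theil_indicators character vector of columns scanned by the Theil
#'   decomposition.
#' @param lp_tolerance numeric feasibility/comparison tolerance for the
#'   envelopment linear programs.
#' @param effective_threshold a unit is called DEA-effective when its radial
#'   score is at least `1 - effective_threshold` and all slacks are below
#'   `lp_tolerance`.
#' @param digits number of decimals (half-up) used in written report tables.
#' @param theil_covariate_rule how region-level Theil indices are assigned to
#'   province rows of the efficiency regression: `"region"` uses the within
#'   index of the unit's own region, `"national"` the overall index of the
#'   year.
#'
#' @return A list with class `"healthalloc_config"`.
#' @export
analysis_config <- function(input_indicators = c("X1", "X2", "X3", "X4", "X6"),
                            output_indicators = c("Y1", "Y2", "Y3"),
                            theil_indicators = c("X1", "X2", "X3", "X4", "X5"),
                            lp_tolerance = 1e-6,
                            effective_threshold = 1e-6,
                            digits = 3L,
                            theil_covariate_rule = c("region", "national")) {
  theil_covariate_rule <- match.arg(theil_covariate_rule)
  stopifnot(lp_tolerance > 0, effective_threshold > 0, digits >= 0)
  known <- c(PANEL_INPUTS, PANEL_OUTPUTS)
  bad <- setdiff(c(input_indicators, output_indicators, theil_indicators), known)
  if (length(bad) > 0) {
    stop("unknown indicator name(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(
      input_indicators = input_indicators,
      output_indicators = output_indicators,
      theil_indicators = theil_indicators,
      lp_tolerance = lp_tolerance,
      effective_threshold = effective_threshold,
      digits = as.integer(digits),
      theil_covariate_rule = theil_covariate_rule
    ),
    class = "healthalloc_config"
  )
}

#' Validate a panel data frame
#'
#' Checks the invariants every analysis stage relies on: all canonical
#' columns present, indicators / population strictly positive, urbanization
#' in (0, 1], region labels among the three recognized regions, and a
#' balanced design (exactly one row per unit-year pair). Rows are returned
#' sorted by unit then year so downstream matrix orderings are deterministic.
#'
#' @param panel data frame in the canonical layout (see [read_panel()]).
#' @param require_regions if `TRUE`, additionally require at least two units
#'   per region (needed by the Theil decomposition).
#'
#' @return The validated, row-sorted panel (invisibly classed
#'   `"healthalloc_panel"`).
#' @export
validate_panel <- function(panel, require_regions = FALSE) {
  panel <- as.data.frame(panel, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PANEL_COLUMNS, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  panel <- panel[, PANEL_COLUMNS]
  panel$unit_id <- as.character(panel$unit_id)
  panel$region <- as.character(panel$region)
  panel$year <- as.integer(panel$year)

  bad_region <- setdiff(unique(panel$region), PANEL_REGIONS)
  if (length(bad_region) > 0) {
    stop("unknown region label(s): ", paste(bad_region, collapse = ", "))
  }

  num_cols <- c(PANEL_INPUTS, PANEL_OUTPUTS, "population", PANEL_COVARIATES)
  for (cl in num_cols) {
    v <- panel[[cl]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("column '", cl, "' must be numeric with no missing values")
    }
  }
  pos_cols <- c(PANEL_INPUTS, PANEL_OUTPUTS, "population",
                "gdp_per_capita", "population_density")
  for (cl in pos_cols) {
    bad <- which(panel[[cl]] <= 0)
    if (length(bad) > 0) {
      i <- bad[1]
      stop(sprintf(
        "non-positive value in column '%s' for unit '%s', year %d",
        cl, panel$unit_id[i], panel$year[i]
      ))
    }
  }
  bad_urb <- which(panel$urbanization_rate <= 0 | panel$urbanization_rate > 1)
  if (length(bad_urb) > 0) {
    i <- bad_urb[1]
    stop(sprintf(
      "urbanization_rate outside (0, 1] for unit '%s', year %d",
      panel$unit_id[i], panel$year[i]
    ))
  }

  units <- sort(unique(panel$unit_id))
  years <- sort(unique(panel$year))
  key <- paste(panel$unit_id, panel$year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate unit-year row: ", sub("\r", ", ", dup))
  }
  expected <- as.vector(outer(units, years, paste, sep = "\r"))
  miss <- setdiff(expected, key)
  if (length(miss) > 0) {
    stop(
      "unbalanced panel; missing unit-year pair(s): ",
      paste(sub("\r", " ", miss), collapse = "; ")
    )
  }

  # a unit's region must not change over time
  reg_per_unit <- tapply(panel$region, panel$unit_id, function(r) length(unique(r)))
  if (any(reg_per_unit > 1)) {
    stop("unit(s) change region across years: ",
         paste(names(reg_per_unit)[reg_per_unit > 1], collapse = ", "))
  }

  if (require_regions) {
    n_units_region <- tapply(units, panel$region[match(units, panel$unit_id)], length)
    if (any(n_units_region < 2)) {
      stop("each region needs at least 2 units for the Theil decomposition")
    }
  }

  panel <- panel[order(panel$unit_id, panel$year), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("healthalloc_panel", "data.frame")
  invisible(panel)
}

#' Read a tidy panel CSV
#'
#' Reads the canonical one-row-per-unit-year CSV (UTF-8, header row) and
#' validates it with [validate_panel()]. Errors name the offending column or
#' unit-year cell.
#'
#' @param path path to the CSV file.
#' @param require_regions passed to [validate_panel()].
#' @return A validated panel data frame, rows sorted by unit then year.
#' @export
read_panel <- function(path, require_regions = FALSE) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_panel(raw, require_regions = require_regions)
}

#' Write a panel to CSV
#'
#' Inverse of [read_panel()]: full precision, canonical column order.
#'
#' @param panel validated panel data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  utils::write.csv(as.data.frame(panel)[, PANEL_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Round half-up
#'
#' Decimal rounding with ties going away from zero (the convention used in
#' the printed report tables), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a report table as CSV
#'
#' Numeric columns are rounded half-up to `digits` decimals before writing,
#' so that re-reading the file yields exactly the rounded values.
#'
#' @param rows non-empty data frame of results.
#' @param path output path.
#' @param digits decimals for numeric columns.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(rows, path, digits = 3L) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0) stop("refusing to write an empty report table")
  for (cl in names(rows)) {
    if (is.numeric(rows[[cl]])) rows[[cl]] <- round_half_up(rows[[cl]], digits)
  }
  ok <- tryCatch({
    utils::write.csv(rows, path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write report table to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}
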
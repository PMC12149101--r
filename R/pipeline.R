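# One-command orchestration of the full study: load or simulate a panel, run
# the Theil inequality decomposition, per-year DEA with projections, the
# Malmquist decomposition, and the efficiency-determinants Tobit regression,
# writing one CSV per report table plus a JSON run manifest.

#' Run the full analysis pipeline
#'
#' Stages, in order: obtain the panel (read `config$panel`, or simulate from
#' `config$simulate` when no path is given); Theil table over
#' `theil_indicators` and all years; DEA scores for every year; projection
#' table for the last year; Malmquist records and per-period summary (skipped
#' with a warning when the panel has a single year); regression table and
#' Tobit fit. Every tabular output is written under `outdir`; rerunning with
#' identical inputs reproduces identical tables.
#'
#' @param config either a path to a JSON configuration file or a list. Keys:
#'   `panel` (path to a panel CSV) or `simulate` (list of
#'   [synthetic_config()] arguments), `outdir` (output directory, required),
#'   `analysis` (optional list of [analysis_config()] arguments),
#'   `projection_year` (optional; default the last panel year).
#' @return Invisibly, the run manifest: a list with the configuration, stage
#'   timings, output paths with MD5 digests, stage warnings, and key counts.
#' @export
run_all <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$outdir)) stop("config$outdir is required")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  acfg <- do.call(analysis_config, as.list(config$analysis))

  warnings_log <- character()
  timings <- list()
  outputs <- character()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(rows, file, digits) {
    path <- file.path(outdir, file)
    write_report_table(rows, path, digits = digits)
    outputs <<- c(outputs, path)
    path
  }

  truth <- NULL
  panel <- stage("panel", {
    if (!is.null(config$panel)) {
      read_panel(config$panel, require_regions = TRUE)
    } else if (!is.null(config$simulate)) {
      sim <- generate_panel(do.call(synthetic_config, as.list(config$simulate)))
      truth <- sim$truth
      write_panel(sim$panel, file.path(outdir, "panel.csv"))
      outputs <- c(outputs, file.path(outdir, "panel.csv"))
      sim$panel
    } else {
      stop("config needs either 'panel' (a CSV path) or 'simulate'")
    }
  })
  years <- sort(unique(panel$year))

  theil <- stage("theil", theil_table(panel, acfg$theil_indicators, years))
  emit(theil, "theil.csv", digits = 4L)

  dea <- stage("dea", dea_all_years(panel, acfg))
  emit(dea, "dea_by_year.csv", digits = 3L)

  proj_year <- if (!is.null(config$projection_year)) {
    as.integer(config$projection_year)
  } else {
    max(years)
  }
  static <- stage("dea_static", dea_year_table(panel, proj_year, acfg))
  emit(static, "dea_static.csv", digits = 3L)
  proj <- stage("projections", projection_table(panel, proj_year, acfg))
  if (nrow(proj) == 0) {
    proj <- data.frame(unit_id = NA_character_, year = proj_year,
                       indicator = NA_character_, kind = "none",
                       actual = NA_real_, value = NA_real_,
                       rate_percent = NA_real_, region = NA_character_)
    warnings_log <- c(warnings_log,
                      "projections: every unit is pure technically efficient")
  }
  emit(proj, "projections.csv", digits = 3L)

  mq_records <- NULL
  if (length(years) >= 2) {
    mq_records <- stage("malmquist", malmquist_all(panel, acfg))
    emit(mq_records[, c("unit_id", "from", "to", "effch", "techch",
                        "pech", "sech", "tfpch")],
         "malmquist.csv", digits = 3L)
    mq_sum <- malmquist_summary(mq_records)
    emit(mq_sum$by_period, "malmquist_summary.csv", digits = 3L)
  } else {
    warnings_log <- c(warnings_log,
                      "malmquist: skipped, panel has a single year")
  }

  # A structurally unidentifiable regression design (e.g. a single-year
  # panel, whose region-level fairness covariates are collinear with the
  # intercept) skips the stage with an explicit warning; other errors abort.
  tobit <- tryCatch(
    stage("tobit", {
      reg <- build_regression_table(panel, dea, acfg)
      fit <- fit_tobit(reg, upper_limit = 1)
      list(reg = reg, fit = fit)
    }),
    error = function(e) {
      msg <- conditionMessage(e)
      if (grepl("rank deficient|more rows than parameters|all observations censored",
                msg)) {
        warnings_log <<- c(warnings_log, paste0("tobit: skipped, ", msg))
        NULL
      } else {
        stop(e)
      }
    }
  )
  if (!is.null(tobit)) emit(tobit_report(tobit$fit), "tobit.csv", digits = 4L)

  manifest <- list(
    config = config,
    analysis_config = unclass(acfg),
    n_units = length(unique(panel$unit_id)),
    years = years,
    projection_year = proj_year,
    tobit = if (is.null(tobit)) list(skipped = TRUE) else list(
      loglik = tobit$fit$loglik, sigma = tobit$fit$sigma,
      n_censored = tobit$fit$n_censored, converged = tobit$fit$converged
    ),
    malmquist_records = if (is.null(mq_records)) 0L else nrow(mq_records),
    outputs = as.list(stats::setNames(
      as.character(tools::md5sum(outputs)), basename(outputs)
    )),
    warnings = warnings_log,
    timings = timings
  )
  if (!is.null(truth)) {
    manifest$truth_file <- file.path(outdir, "truth.csv")
    utils::write.csv(truth$efficiency, manifest$truth_file, row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
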
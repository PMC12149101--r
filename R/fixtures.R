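# Reference fixtures: verbatim transcriptions of published provincial
# efficiency and productivity tables (see inst/extdata/README.md). The
# underlying yearbook panel is not deposited, so these printed results are
# the only numerically checkable anchor; verify_fixtures() recomputes every
# arithmetic relationship they imply with the package's own functions.

#' Locate the shipped reference fixtures
#'
#' @return Path of the directory holding the transcribed reference tables.
#' @export
fixture_dir <- function() {
  system.file("extdata", package = "healthalloc")
}

#' Load one reference fixture table
#'
#' @param name one of `"efficiency"`, `"efficiency_summary"`, `"dea_2019"`,
#'   `"dea_2019_summary"`, `"malmquist"`.
#' @param dir directory holding the fixture CSVs.
#' @return Data frame.
#' @export
load_fixture <- function(name = c("efficiency", "efficiency_summary",
                                  "dea_2019", "dea_2019_summary", "malmquist"),
                         dir = fixture_dir()) {
  name <- match.arg(name)
  file <- switch(name,
    efficiency = "reported_efficiency_2014_2019.csv",
    efficiency_summary = "reported_efficiency_2014_2019_summary.csv",
    dea_2019 = "reported_dea_2019.csv",
    dea_2019_summary = "reported_dea_2019_summary.csv",
    malmquist = "reported_malmquist_2014_2019.csv"
  )
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("fixture file missing: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Recompute the arithmetic checks implied by the reference tables
#'
#' Recomputes, from the transcribed per-province values, every summary the
#' published tables print alongside them: per-year mean efficiency and
#' effective counts; the 2019 mean TE/PTE/SE row; the counts of effective
#' provinces (15), provinces inefficient in both the technical and the scale
#' dimension (11) and provinces under decreasing returns (8); the Malmquist
#' product identities `tfpch = effch x techch` and `effch = pech x sech`
#' within 3-decimal rounding of the printed components; and the printed
#' productivity ranks. Each check passes or fails individually.
#'
#' @param dir directory holding the fixture CSVs.
#' @return Data frame with columns `check`, `pass`, `detail`.
#' @export
verify_fixtures <- function(dir = fixture_dir()) {
  if (!nzchar(dir) || !dir.exists(dir)) {
    stop("fixture directory not found: '", dir, "'")
  }
  eff <- load_fixture("efficiency", dir = dir)
  eff_sum <- load_fixture("efficiency_summary", dir = dir)
  dea19 <- load_fixture("dea_2019", dir = dir)
  dea19_sum <- load_fixture("dea_2019_summary", dir = dir)
  mq <- load_fixture("malmquist", dir = dir)

  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE
    )
  }

  years <- paste0("y", 2014:2019)
  printed_mean <- as.numeric(eff_sum[eff_sum$statistic == "mean_value", years])
  printed_effn <- as.numeric(eff_sum[eff_sum$statistic == "effective_number", years])
  for (k in seq_along(years)) {
    s <- dea_summary(data.frame(te = eff[[years[k]]]), digits = 3L)
    add(paste0("mean_te_", sub("y", "", years[k])),
        isTRUE(all.equal(s$mean_te, round_half_up(printed_mean[k], 3))),
        sprintf("computed %.3f, printed %.3f", s$mean_te, printed_mean[k]))
    add(paste0("effective_count_", sub("y", "", years[k])),
        s$effective_count == printed_effn[k],
        sprintf("computed %d, printed %d", s$effective_count, printed_effn[k]))
  }

  s19 <- dea_summary(dea19, digits = 3L)
  add("mean_te_2019_static", s19$mean_te == dea19_sum$te,
      sprintf("computed %.3f, printed %.3f", s19$mean_te, dea19_sum$te))
  add("mean_pte_2019", s19$mean_pte == dea19_sum$pte,
      sprintf("computed %.3f, printed %.3f", s19$mean_pte, dea19_sum$pte))
  add("mean_se_2019", s19$mean_se == dea19_sum$se,
      sprintf("computed %.3f, printed %.3f", s19$mean_se, dea19_sum$se))
  add("effective_count_2019_static", s19$effective_count == 15L,
      sprintf("computed %d, expected 15", s19$effective_count))

  doubly <- sum(dea19$pte < 1 & dea19$se < 1)
  add("technical_and_scale_inefficient_count", doubly == 11L,
      sprintf("computed %d, expected 11", doubly))
  drs <- sum(dea19$rts == "drs")
  add("drs_count_2019", drs == 8L, sprintf("computed %d, expected 8", drs))

  se_dev <- max(abs(dea19$se - dea19$te / dea19$pte))
  add("se_equals_te_over_pte", se_dev <= 0.002,
      sprintf("max deviation %.4f (3-dp rounding of printed values)", se_dev))

  dev_tfp <- max(abs(mq$tfpch - mq$effch * mq$techch))
  add("tfpch_equals_effch_times_techch", dev_tfp <= 0.0025,
      sprintf("max deviation %.4f", dev_tfp))
  dev_eff <- max(abs(mq$effch - mq$pech * mq$sech))
  add("effch_equals_pech_times_sech", dev_eff <= 0.0025,
      sprintf("max deviation %.4f", dev_eff))

  bj <- mq[mq$province == "Beijing", ]
  bj_tfp <- round_half_up(bj$effch * bj$techch, 3)
  add("beijing_tfpch", bj_tfp == 1.002,
      sprintf("computed %.3f, printed 1.002", bj_tfp))

  rank_ok <- all(rank(-mq$tfpch, ties.method = "min") == mq$rank)
  add("tfpch_rank_order", rank_ok, "printed ranks follow tfpch with min-ties")

  do.call(rbind, checks)
}
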
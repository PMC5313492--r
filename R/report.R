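#' Full biomarker evaluation report for a cohort
#'
#' Runs, for each requested biomarker, the standard prognostic-evaluation
#' battery: administrative censoring at the horizon, univariate Cox
#' regression (per-unit hazard ratio with 95% CI), Harrell's C-index with
#' bootstrap CI, and a median-split Kaplan-Meier comparison (per-group
#' median survival with "not reached" semantics, log-rank test).
#'
#' @param cohort cohort data frame.
#' @param biomarkers character vector of biomarker column names.
#' @param horizon_years administrative censoring horizon (default 5).
#' @param n_boot bootstrap resamples for C-index CIs.
#' @param seed RNG seed for the bootstrap.
#' @return A `survival_report`: `table` (one row per biomarker: C-index
#'   and CI, HR and CI, Wald p), `km_summary` (median split results) and
#'   `analyses` (the underlying result objects).
#' @export
survival_report <- function(cohort, biomarkers, horizon_years = 5,
                            n_boot = 2000, seed = 1L) {
  check_cohort(cohort)
  cohort <- censor_at_horizon(cohort, horizon_years)
  rows <- list()
  km_rows <- list()
  analyses <- list()
  for (bm in biomarkers) {
    cox <- cox_univariate(cohort, bm)
    ci <- harrell_cindex(cohort, bm, n_boot = n_boot, seed = seed)
    ms <- median_split(cohort, bm)
    km_hi <- km_estimate(ms$high$time_years, ms$high$event)
    km_lo <- km_estimate(ms$low$time_years, ms$low$event)
    lr <- logrank_test(ms$high$time_years, ms$high$event,
                       ms$low$time_years, ms$low$event)
    rows[[bm]] <- data.frame(
      biomarker = bm, c_index = ci$c_index, c_ci95_low = ci$ci95_low,
      c_ci95_high = ci$ci95_high, hr = cox$hr, hr_ci95_low = cox$ci95_low,
      hr_ci95_high = cox$ci95_high, p_value = cox$p_value,
      stringsAsFactors = FALSE)
    km_rows[[bm]] <- data.frame(
      biomarker = bm, median_value = ms$median_value,
      n_high = nrow(ms$high), n_low = nrow(ms$low),
      median_survival_high = render_median(km_hi),
      median_survival_low = render_median(km_lo),
      logrank_chi2 = lr$chi2, logrank_p = lr$p_value,
      stringsAsFactors = FALSE)
    analyses[[bm]] <- list(cox = cox, cindex = ci, split = ms,
                           km_high = km_hi, km_low = km_lo, logrank = lr)
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 km_summary = do.call(rbind, c(km_rows,
                                               make.row.names = FALSE)),
                 analyses = analyses, horizon_years = horizon_years),
            class = "survival_report")
}

render_median <- function(km) {
  if (km$median_reached) format(km$median_survival_years, digits = 4)
  else "not reached"
}

#' @export
print.survival_report <- function(x, ...) {
  cat(sprintf("Biomarker evaluation (censored at %g years)\n",
              x$horizon_years))
  tab <- x$table
  tab$p_value <- vapply(tab$p_value,
                        function(p) sub("^= ", "", format_p(p)),
                        character(1))
  print(tab, row.names = FALSE, digits = 3)
  cat("\nMedian-split Kaplan-Meier comparison:\n")
  km <- x$km_summary
  km$logrank_p <- vapply(km$logrank_p,
                         function(p) sub("^= ", "", format_p(p)),
                         character(1))
  print(km, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a survival report to files
#'
#' Writes the biomarker table (`table2.csv`), the median-split summary
#' (`km_summary.csv`) and a JSON with the exact numeric results.
#'
#' @param report a `survival_report`.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_survival_report <- function(report, dir) {
  stopifnot(inherits(report, "survival_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$table, file.path(dir, "table2.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$km_summary, file.path(dir, "km_summary.csv"),
                   row.names = FALSE)
  strip <- function(x) if (is.list(x)) lapply(x, strip) else unclass(x)
  obj <- list(horizon_years = report$horizon_years, table = report$table,
              km_summary = report$km_summary,
              analyses = lapply(report$analyses, function(a)
                list(cox = unclass(a$cox),
                     cindex = unclass(a$cindex),
                     median_value = a$split$median_value,
                     logrank = a$logrank)))
  jsonlite::write_json(obj, file.path(dir, "survival.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
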
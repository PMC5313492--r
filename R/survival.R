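check_cohort <- function(cohort) {
  if (!is.data.frame(cohort))
    stop("cohort must be a data frame", call. = FALSE)
  need <- c("patient_id", "time_years", "event")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cohort$patient_id))
    stop("duplicate patient_id values", call. = FALSE)
  bad <- which(!is.finite(cohort$time_years) | cohort$time_years <= 0)
  if (length(bad))
    stop("non-positive or missing time_years in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!cohort$event %in% c(0, 1))
  if (length(bad))
    stop("event must be 0 or 1; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(cohort)
}

get_biomarker <- function(cohort, biomarker) {
  if (!biomarker %in% names(cohort))
    stop("biomarker column not found: ", biomarker, call. = FALSE)
  cohort[[biomarker]]
}

#' Administratively censor a cohort at a follow-up horizon
#'
#' Observations beyond the horizon become censored at the horizon (the
#' published analyses censor all data at 5 years); a time exactly equal
#' to the horizon keeps its recorded event status.
#'
#' @param cohort cohort data frame with `time_years` and `event` columns.
#' @param horizon_years censoring horizon (> 0), default 5.
#' @return The cohort with times truncated and events reset accordingly.
#' @examples
#' censor_at_horizon(data.frame(patient_id = "a", time_years = 6.2,
#'                              event = 1))
#' @export
censor_at_horizon <- function(cohort, horizon_years = 5) {
  check_cohort(cohort)
  stopifnot(is.numeric(horizon_years), horizon_years > 0)
  over <- cohort$time_years > horizon_years
  cohort$event[over] <- 0
  cohort$time_years[over] <- horizon_years
  cohort
}

#' Split a cohort at the median of a biomarker
#'
#' The high-risk group holds values strictly *above* the median (midpoint
#' of the two central order statistics for even n); values at or below it
#' — including ties at the median — go to the low group. Rows with a
#' missing biomarker are dropped and counted.
#'
#' @param cohort cohort data frame.
#' @param biomarker name of the biomarker column.
#' @return A list with `high`, `low` (data frames), `median_value` and
#'   `n_missing`.
#' @export
median_split <- function(cohort, biomarker) {
  check_cohort(cohort)
  x <- get_biomarker(cohort, biomarker)
  keep <- !is.na(x)
  if (sum(keep) < 2)
    stop("median split needs at least 2 non-missing values", call. = FALSE)
  cohort <- cohort[keep, , drop = FALSE]
  x <- x[keep]
  med <- stats::median(x)
  hi <- x > med
  if (!any(hi))
    warning("no values above the median (all tied); high group is empty")
  list(high = cohort[hi, , drop = FALSE], low = cohort[!hi, , drop = FALSE],
       median_value = med, n_missing = sum(!keep))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with the standard convention that events
#' precede censorings tied at the same time. The median survival is the
#' earliest time at which the survival curve drops to 0.5 or below; when
#' the curve never reaches 0.5 the median is *not reached* (reported as
#' `NA` with `median_reached = FALSE`, and printed as "not reached").
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators.
#' @return A `km_estimate` with the step function (`time`, `surv`,
#'   `n_risk`, `n_event`, `n_censor`), `median_survival_years` and
#'   `median_reached`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  # median = earliest time at which the curve reaches 0.5 or below (no
  # interval averaging when the curve sits exactly at 0.5)
  at <- which(fit$surv <= 0.5)
  med <- if (length(at)) fit$time[min(at)] else NA_real_
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 n = length(times), n_events = sum(events),
                 median_survival_years = if (is.na(med)) NA_real_ else med,
                 median_reached = !is.na(med)),
            class = "km_estimate")
}

#' Survival probability at given times from a KM estimate
#' @param km a `km_estimate`.
#' @param t times at which to evaluate the step function.
#' @return Survival probabilities (1 before the first event).
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(ti) {
    i <- which(km$time <= ti)
    if (length(i) == 0L) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d\n", x$n,
              x$n_events))
  cat(sprintf("  median survival: %s\n",
              if (x$median_reached)
                sprintf("%.3g years", x$median_survival_years)
              else "not reached"))
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param time_a,event_a follow-up times and 0/1 events of group A.
#' @param time_b,event_b same for group B.
#' @return A list with `chi2` (1 df) and `p_value`. With no events in
#'   either group the test is degenerate and returns `chi2 = 0, p = 1`
#'   with a warning.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (sum(event_a) + sum(event_b) == 0) {
    warning("no events in either group; log-rank test is degenerate")
    return(list(chi2 = 0, p_value = 1))
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(chi2 = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit of a single continuous biomarker (Efron tie
#' handling), reporting the per-unit hazard ratio with a 95% Wald
#' confidence interval, the Wald p-value and the score test (which for a
#' binary covariate equals the log-rank chi-square).
#'
#' @param cohort cohort data frame.
#' @param biomarker name of the biomarker column.
#' @return A `cox_result`: `beta`, `se`, `hr`, `ci95_low`, `ci95_high`,
#'   `p_value`, `score_chi2`, `log_likelihood`, `n`, `n_events`,
#'   `separation` flag.
#' @export
cox_univariate <- function(cohort, biomarker) {
  check_cohort(cohort)
  x <- get_biomarker(cohort, biomarker)
  keep <- !is.na(x)
  cohort <- cohort[keep, , drop = FALSE]
  x <- x[keep]
  if (sum(cohort$event) < 1)
    stop("Cox regression needs at least one event", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("biomarker is constant; hazard ratio undefined", call. = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(cohort$time_years, cohort$event) ~ x,
                    ties = "efron",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation && !is.finite(fit$coefficients[1]))
    stop("monotone partial likelihood (perfect separation); ",
         "last iterate beta = ", format(fit$coefficients[1]), call. = FALSE)
  if (separation)
    warning("possible monotone likelihood / non-convergence flagged by the ",
            "partial-likelihood maximizer")
  beta <- unname(fit$coefficients[1])
  se <- sqrt(unname(fit$var[1, 1]))
  structure(list(beta = beta, se = se, hr = exp(beta),
                 ci95_low = exp(beta - 1.96 * se),
                 ci95_high = exp(beta + 1.96 * se),
                 p_value = 2 * stats::pnorm(-abs(beta / se)),
                 score_chi2 = unname(fit$score),
                 log_likelihood = fit$loglik[2], n = fit$n,
                 n_events = fit$nevent, separation = separation),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Univariate Cox regression: n = %d, events = %d\n", x$n,
              x$n_events))
  cat(sprintf("  HR %.3g per unit (95%% CI %.3g-%.3g), p %s\n", x$hr,
              x$ci95_low, x$ci95_high, format_p(x$p_value)))
  invisible(x)
}

# Text rendering of p-values: below 0.001 shown as "<0.001" (exact values
# are kept in all returned objects and JSON).
format_p <- function(p) if (is.na(p)) "NA" else
  if (p < 0.001) "<0.001" else sprintf("= %.3g", p)
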
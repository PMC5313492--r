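# Pairwise concordance bookkeeping for right-censored data.
#
# A pair (i, j) is comparable when the shorter observed time is an event
# (including the tie case event-vs-censored at the same time); both
# events at the same time cannot be ordered and are not comparable. With
# the default orientation a pair is concordant when the shorter-lived
# patient has the HIGHER biomarker (higher index = worse prognosis,
# matching a hazard ratio above 1); biomarker ties score 0.5.
#
# Returns totals over unordered pairs plus per-patient involvement sums
# (each pair credited to both members), which the jackknife in
# compare_cindex consumes.
concordance_pair_stats <- function(time, event, x, higher_is_worse = TRUE) {
  n <- length(time)
  ti <- matrix(time, n, n)
  tj <- t(ti)
  ei <- matrix(event, n, n)
  ej <- t(ei)
  xi <- matrix(x, n, n)
  xj <- t(xi)
  comp <- (ti < tj & ei == 1) | (ti == tj & ei == 1 & ej == 0)
  diag(comp) <- FALSE
  sc <- if (higher_is_worse) ifelse(xi > xj, 1, ifelse(xi == xj, 0.5, 0))
        else ifelse(xi < xj, 1, ifelse(xi == xj, 0.5, 0))
  tied <- comp & xi == xj
  cs <- comp * sc
  list(concordant_sum = sum(cs), n_pairs = sum(comp), n_tied = sum(tied),
       per_patient_conc = rowSums(cs) + colSums(cs),
       per_patient_pairs = rowSums(comp) + colSums(comp))
}

#' Harrell's concordance index for a censored cohort
#'
#' The probability that, of a comparable patient pair, the patient with
#' the worse (higher, by default) biomarker value dies first. Computed by
#' exhaustive pair enumeration; ties in the biomarker count 1/2. The
#' confidence interval is a seeded nonparametric bootstrap (resampling
#' patients, percentile interval).
#'
#' @param cohort cohort data frame.
#' @param biomarker name of the biomarker column.
#' @param n_boot bootstrap resamples for the CI (default 2000; 0 skips
#'   the CI).
#' @param seed RNG seed for the bootstrap.
#' @param higher_is_worse orientation flag; `TRUE` (default) counts a pair
#'   concordant when the shorter-lived patient has the higher value.
#' @return A `cindex_result`: `c_index`, `ci95_low`, `ci95_high`,
#'   `n_comparable_pairs`, `n_concordant` (concordance score sum, i.e.
#'   whole pairs plus half ties), `n_tied`, `n`.
#' @export
harrell_cindex <- function(cohort, biomarker, n_boot = 2000, seed = 1L,
                           higher_is_worse = TRUE) {
  check_cohort(cohort)
  x <- get_biomarker(cohort, biomarker)
  keep <- !is.na(x)
  time <- cohort$time_years[keep]
  event <- cohort$event[keep]
  x <- x[keep]
  st <- concordance_pair_stats(time, event, x, higher_is_worse)
  if (st$n_pairs == 0L)
    stop("no comparable pairs (no usable events)", call. = FALSE)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    n <- length(time)
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      s <- concordance_pair_stats(time[i], event[i], x[i], higher_is_worse)
      if (s$n_pairs == 0L) NA_real_ else s$concordant_sum / s$n_pairs
    }, numeric(1)))
    ci <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(c_index = st$concordant_sum / st$n_pairs,
                 ci95_low = ci[1], ci95_high = ci[2],
                 n_comparable_pairs = st$n_pairs,
                 n_concordant = st$concordant_sum, n_tied = st$n_tied,
                 n = length(time), n_boot = n_boot),
            class = "cindex_result")
}

#' @export
print.cindex_result <- function(x, ...) {
  cat(sprintf("Harrell's C-index: %.3f", x$c_index))
  if (!is.na(x$ci95_low))
    cat(sprintf(" (95%% bootstrap CI %.3f-%.3f)", x$ci95_low, x$ci95_high))
  cat(sprintf("\n  %d comparable pairs (%s concordant, %d biomarker ties)\n",
              x$n_comparable_pairs, format(x$n_concordant), x$n_tied))
  invisible(x)
}

#' Paired comparison of two biomarkers' C-indices
#'
#' Tests whether two biomarkers measured on the same patients differ in
#' concordance with survival. The statistic is `delta = cA - cB`; its
#' variance is estimated by the leave-one-patient-out jackknife over the
#' per-patient concordance contributions, and the p-value uses a t
#' reference with n - 1 degrees of freedom. A seeded paired bootstrap
#' p-value is available as a cross-check (`n_boot > 0`).
#'
#' @param cohort cohort data frame.
#' @param biomarker_a,biomarker_b biomarker column names.
#' @param n_boot paired-bootstrap resamples for the cross-check p-value
#'   (0 = jackknife t-test only).
#' @param seed RNG seed for the bootstrap.
#' @param higher_is_worse orientation, as in [harrell_cindex()].
#' @return A list with `delta`, `p_value`, `c_a`, `c_b`, `se`,
#'   `statistic`, `df`, `n`, and `p_boot` when requested.
#' @export
compare_cindex <- function(cohort, biomarker_a, biomarker_b, n_boot = 0,
                           seed = 1L, higher_is_worse = TRUE) {
  check_cohort(cohort)
  a <- get_biomarker(cohort, biomarker_a)
  b <- get_biomarker(cohort, biomarker_b)
  keep <- !is.na(a) & !is.na(b)
  time <- cohort$time_years[keep]
  event <- cohort$event[keep]
  a <- a[keep]
  b <- b[keep]
  n <- length(time)
  A <- concordance_pair_stats(time, event, a, higher_is_worse)
  B <- concordance_pair_stats(time, event, b, higher_is_worse)
  if (A$n_pairs == 0L)
    stop("no comparable pairs", call. = FALSE)
  if (sum(A$per_patient_pairs > 0) < 3)
    stop("fewer than 3 patients enter comparable pairs", call. = FALSE)
  cA <- A$concordant_sum / A$n_pairs
  cB <- B$concordant_sum / B$n_pairs
  delta <- cA - cB
  # leave-one-out deltas from the pair totals minus each patient's
  # involvement
  dj <- (A$concordant_sum - A$per_patient_conc) /
          (A$n_pairs - A$per_patient_pairs) -
        (B$concordant_sum - B$per_patient_conc) /
          (B$n_pairs - B$per_patient_pairs)
  dj[!is.finite(dj)] <- delta
  se <- sqrt((n - 1) / n * sum((dj - mean(dj))^2))
  if (se == 0) {
    p <- if (delta == 0) 1 else 0
    tstat <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    tstat <- delta / se
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  }
  out <- list(delta = delta, p_value = p, c_a = cA, c_b = cB, se = se,
              statistic = tstat, df = n - 1, n = n)
  if (n_boot > 0) {
    bd <- with_seed(seed, vapply(seq_len(n_boot), function(r) {
      i <- sample.int(n, n, replace = TRUE)
      sa <- concordance_pair_stats(time[i], event[i], a[i], higher_is_worse)
      sb <- concordance_pair_stats(time[i], event[i], b[i], higher_is_worse)
      if (sa$n_pairs == 0L) return(NA_real_)
      sa$concordant_sum / sa$n_pairs - sb$concordant_sum / sb$n_pairs
    }, numeric(1)))
    bd <- bd[!is.na(bd)]
    # two-sided bootstrap p: does the resampling distribution straddle 0?
    frac <- min(mean(bd <= 0), mean(bd >= 0))
    out$p_boot <- min(1, 2 * max(frac, 1 / (length(bd) + 1)))
  }
  out
}
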
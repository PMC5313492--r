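cohort_of <- function(time, event, ...) {
  out <- data.frame(patient_id = sprintf("p%02d", seq_along(time)),
                    time_years = time, event = event,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

test_that("administrative censoring truncates only beyond the horizon", {
  co <- cohort_of(c(6.2, 2.4, 5.0, 7.1), c(1, 1, 1, 0))
  out <- censor_at_horizon(co, 5)
  expect_equal(out$time_years, c(5, 2.4, 5, 5))
  # the boundary observation keeps its event; later ones are censored
  expect_equal(out$event, c(0, 1, 1, 0))
})

test_that("median split sends ties at the median to the low group", {
  co <- cohort_of(1:4, rep(1, 4), bm = c(1, 2, 3, 4))
  sp <- median_split(co, "bm")
  expect_equal(sp$median_value, 2.5)
  expect_setequal(sp$high$bm, c(3, 4))
  expect_setequal(sp$low$bm, c(1, 2))

  co2 <- cohort_of(1:4, rep(1, 4), bm = c(0.1, 0.39, 0.39, 7))
  sp2 <- median_split(co2, "bm")
  expect_equal(sp2$median_value, 0.39)
  expect_equal(sp2$high$bm, 7)
  expect_setequal(sp2$low$bm, c(0.1, 0.39, 0.39))

  co3 <- cohort_of(1:3, rep(1, 3), bm = c(2, 2, 2))
  expect_warning(sp3 <- median_split(co3, "bm"), "high group is empty")
  expect_equal(nrow(sp3$high), 0L)
  expect_equal(nrow(sp3$low), 3L)

  co4 <- cohort_of(1:4, rep(1, 4), bm = c(1, NA, 3, 4))
  sp4 <- median_split(co4, "bm")
  expect_equal(sp4$n_missing, 1L)
  expect_error(median_split(cohort_of(1:2, c(1, 1), bm = c(NA, 2)), "bm"),
               "2 non-missing")
})

test_that("Kaplan-Meier reproduces hand-computed product limits", {
  # all events at 1,2,3,4: S = 3/4, 1/2, 1/4, 0; median = earliest S <= .5
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(3 / 4, 1 / 2, 1 / 4, 0))
  expect_equal(km_survival_at(km, 2), 0.5)
  expect_equal(km$median_survival_years, 2)
  expect_true(km$median_reached)

  # censored at 1 and 3: S(2) = 3/4 * (1 - 1/3)? hand: at t=2 risk {2,3,4}
  # -> S(2) = 2/3; at t=4 risk {4} -> S(4) = 0
  km2 <- km_estimate(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(km_survival_at(km2, 2), 2 / 3)
  expect_equal(km_survival_at(km2, 4), 0)

  # all censored: flat curve, median not reached
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  expect_false(km3$median_reached)
  expect_true(is.na(km3$median_survival_years))
  expect_output(print(km3), "not reached")

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(8)
  for (r in 1:5) {
    t <- round(rexp(40, 0.4), 2) + 0.01
    km <- km_estimate(t, rep(1, 40))
    grid <- sort(unique(t))
    expect_equal(km_survival_at(km, grid),
                 vapply(grid, function(g) mean(t > g), numeric(1)))
  }
})

test_that("log-rank matches the hand O-E/V computation and edge cases", {
  # identical groups: no difference
  lr0 <- logrank_test(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)

  # 6-patient worked example, no ties across groups
  ta <- c(1, 3, 5)
  ea <- c(1, 1, 0)
  tb <- c(2, 4, 6)
  eb <- c(1, 1, 1)
  lr <- logrank_test(ta, ea, tb, eb)
  expect_equal(lr$chi2, oracle_logrank_chi2(ta, ea, tb, eb),
               tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(lr$chi2, 1, lower.tail = FALSE))

  expect_warning(lr1 <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)),
                 "no events")
  expect_equal(lr1$p_value, 1)
  expect_error(logrank_test(numeric(0), numeric(0), 1, 1), "non-empty")
})

test_that("strongly separated groups reject, in agreement with permutation", {
  set.seed(31)
  time_a <- runif(20, 0.1, 1)   # early deaths
  event_a <- rep(1, 20)
  time_b <- rep(5, 20)          # all administratively censored
  event_b <- rep(0, 20)
  lr <- logrank_test(time_a, event_a, time_b, event_b)
  expect_lt(lr$p_value, 0.05)

  # permutation reference on the same statistic
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  obs <- lr$chi2
  set.seed(1)
  perm <- replicate(1000, {
    i <- sample(40, 20)
    suppressWarnings(logrank_test(time[i], event[i], time[-i],
                                  event[-i])$chi2)
  })
  expect_lt(mean(perm >= obs), 0.05)
})

test_that("Cox beta matches a brute-force partial-likelihood grid search", {
  co <- cohort_of(c(1, 2, 3, 4), c(1, 1, 1, 1), x = c(0, 1, 0, 1))
  fit <- cox_univariate(co, "x")
  # exact partial log-likelihood for distinct event times
  pll <- function(beta) {
    risk <- exp(beta * co$x)
    ord <- order(co$time_years)
    sum(vapply(ord, function(i) {
      at <- co$time_years >= co$time_years[i]
      beta * co$x[i] - log(sum(risk[at]))
    }, numeric(1)))
  }
  grid <- seq(-5, 5, by = 1e-4)
  beta_star <- grid[which.max(vapply(grid, pll, numeric(1)))]
  expect_equal(fit$beta, beta_star, tolerance = 1e-4)
  expect_equal(fit$hr, exp(fit$beta))
  expect_true(fit$ci95_low <= fit$hr && fit$hr <= fit$ci95_high)
})

test_that("Cox estimates are reparameterization-equivariant", {
  sim <- simulate_cohort(n = 150, beta_true = 0.6, seed = 12L)
  co <- sim$cohort
  co$double <- 2 * co$biomarker
  f1 <- cox_univariate(co, "biomarker")
  f2 <- cox_univariate(co, "double")
  expect_equal(f2$beta, f1$beta / 2, tolerance = 1e-8)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-8)
})

test_that("a null biomarker gives a small beta with CI covering HR 1", {
  sim <- simulate_cohort(n = 200, beta_true = 0, seed = 33L)
  fit <- cox_univariate(sim$cohort, "biomarker")
  expect_lt(abs(fit$beta), 0.2)
  expect_true(fit$ci95_low <= 1 && 1 <= fit$ci95_high)
})

test_that("degenerate Cox inputs are rejected or flagged", {
  co <- cohort_of(1:4, rep(0, 4), x = c(1, 2, 3, 4))
  expect_error(cox_univariate(co, "x"), "event")
  co2 <- cohort_of(1:4, rep(1, 4), x = rep(2, 4))
  expect_error(cox_univariate(co2, "x"), "constant")
  # perfect separation: high covariate dies first, always
  co3 <- cohort_of(c(1, 2, 3, 10, 11, 12), rep(1, 6),
                   x = c(1, 1, 1, 0, 0, 0))
  expect_warning(cox_univariate(co3, "x"), "monotone|converge")
})

test_that("the Cox score test equals the log-rank chi-square for groups", {
  set.seed(14)
  for (r in 1:5) {
    n <- 40
    g <- rep(0:1, each = n / 2)
    t <- rexp(n, 0.3 * exp(0.5 * g))
    e <- as.integer(runif(n) > 0.3)
    if (sum(e) == 0) next
    co <- cohort_of(t, e, g = g)
    fit <- cox_univariate(co, "g")
    lr <- logrank_test(t[g == 1], e[g == 1], t[g == 0], e[g == 0])
    expect_equal(fit$score_chi2, lr$chi2, tolerance = 1e-6)
  }
})
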
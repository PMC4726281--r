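test_that("product-limit estimate matches hand computation", {
  cv <- km_fit(c(2, 4, 4, 6), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(cv$time, c(2, 4, 6))
  expect_equal(cv$survival, c(3 / 4, 3 / 4 * 1 / 3, 1 / 4))
  expect_equal(cv$at_risk, c(4, 3, 1))
  # Greenwood: S^2 * cumsum(d / (n (n - d)))
  expect_equal(cv$variance[1], 0.75^2 * (1 / (4 * 3)))
  expect_equal(cv$variance[2], 0.25^2 * (1 / (4 * 3) + 2 / (3 * 1)))

  all_cens <- km_fit(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(all_cens$survival == 1))
  expect_true(all(all_cens$variance == 0))  # zero while S = 1

  single <- km_fit(5, TRUE)
  expect_equal(single$survival, 0)

  expect_error(km_fit(numeric(0), logical(0)),
               class = "pupsurv_input_error")
})

test_that("curve invariants hold on random data", {
  withr::with_seed(11, {
    for (i in 1:20) {
      d <- random_survival_data(sample(5:40, 1),
                                tie_heavy = i %% 2 == 0)
      cv <- km_fit(d$time, d$event)
      expect_true(all(diff(cv$survival) <= 1e-12))   # non-increasing
      expect_true(all(diff(cv$at_risk) <= 0))
      expect_true(all(cv$variance >= 0))
      # with no censoring, 1 - S is the empirical CDF
      cvu <- km_fit(d$time, rep(TRUE, length(d$time)))
      ecdf_vals <- vapply(cvu$time,
                          function(t) mean(d$time <= t), numeric(1))
      expect_equal(1 - cvu$survival, ecdf_vals, tolerance = 1e-12)
    }
  })
})

test_that("estimates agree with the reference implementation", {
  skip_if_not_installed("survival")
  withr::with_seed(42, {
    for (i in 1:100) {
      d <- random_survival_data(sample(4:25, 1),
                                tie_heavy = i %% 3 == 0)
      if (!any(d$event)) d$event[1] <- TRUE
      cv <- km_fit(d$time, d$event)
      sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
      expect_equal(cv$time, sf$time, tolerance = 1e-10)
      expect_equal(cv$survival, sf$surv, tolerance = 1e-10)
      expect_equal(cv$at_risk, sf$n.risk, tolerance = 1e-10)
      expect_equal(cv$n_events, sf$n.event, tolerance = 1e-10)
    }
  })
})

test_that("median and confidence limits invert the log(-log) bands", {
  cv <- km_fit(c(2, 4, 4, 6), c(TRUE, TRUE, TRUE, FALSE))
  med <- km_median_ci(cv)
  expect_equal(med$median_days, 4)  # first time with S <= 0.5
  expect_true(med$defined)

  # a curve that never reaches one half: undefined, flagged
  flat <- km_fit(c(1, 2, 3, 4, 5), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  m2 <- km_median_ci(flat)
  expect_false(m2$defined)
  expect_true(is.na(m2$median_days))

  skip_if_not_installed("survival")
  withr::with_seed(8, {
    d <- random_survival_data(120, tie_heavy = TRUE)
  })
  ours <- km_median_ci(km_fit(d$time, d$event))
  sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1,
                          conf.type = "log-log")
  ref <- summary(sf)$table
  expect_equal(ours$median_days, unname(ref["median"]))
  expect_equal(ours$lo, unname(ref["0.95LCL"]))
  expect_equal(ours$hi, unname(ref["0.95UCL"]))
})

test_that("KM median tracks the schedule's analytic median", {
  # constant monthly hazard q: continuous-time median 30 log(.5)/log(1-q),
  # up to the within-month uniform placement of exit days
  q <- 0.2
  h <- array(0, dim = c(5, 2, 2, 7))
  h[1, , , ] <- q
  sch <- hazard_schedule(h)
  coh <- generate_cohort(generator_config(n_litters = 8000,
                                          schedule = sch, seed = 33))
  cv <- km_fit(coh$records$exit_age_days, !coh$records$censored)
  med <- km_median_ci(cv)
  closed_form <- 30 * log(0.5) / log(1 - q)
  expect_lt(abs(med$median_days - closed_form), 2)
  expect_lt(abs(schedule_expected_median(sch) - closed_form), 1)
})

test_that("log-rank matches hand hypergeometric sums and is symmetric", {
  # group A deaths at 1, 2; group B deaths at 3, 4; no censoring
  lr <- logrank_test(c(1, 2), c(TRUE, TRUE), c(3, 4), c(TRUE, TRUE))
  expect_equal(round(lr$chisq, 2), 2.88)
  expect_equal(lr$observed - lr$expected, 2 - (2 / 4 + 1 / 3),
               tolerance = 1e-12)

  # identical groups: no signal
  t0 <- c(1, 3, 5, 7); e0 <- c(TRUE, TRUE, FALSE, TRUE)
  expect_equal(logrank_test(t0, e0, t0, e0)$chisq, 0, tolerance = 1e-12)

  # label swap leaves the statistic unchanged
  withr::with_seed(5, {
    a <- random_survival_data(30); b <- random_survival_data(25)
  })
  ab <- logrank_test(a$time, a$event, b$time, b$event)
  ba <- logrank_test(b$time, b$event, a$time, a$event)
  expect_equal(ab$chisq, ba$chisq, tolerance = 1e-12)

  expect_error(logrank_test(1, FALSE, 2, FALSE),
               class = "pupsurv_input_error")
})

test_that("log-rank agrees with the reference implementation", {
  skip_if_not_installed("survival")
  withr::with_seed(13, {
    for (i in 1:25) {
      a <- random_survival_data(sample(8:30, 1), tie_heavy = i %% 2 == 0)
      b <- random_survival_data(sample(8:30, 1), tie_heavy = i %% 2 == 0)
      if (!any(a$event)) a$event[1] <- TRUE
      if (!any(b$event)) b$event[1] <- TRUE
      ours <- logrank_test(a$time, a$event, b$time, b$event)
      sd <- survival::survdiff(
        survival::Surv(c(a$time, b$time), c(a$event, b$event)) ~
          rep(1:2, c(length(a$time), length(b$time))))
      expect_equal(ours$chisq, sd$chisq, tolerance = 1e-8)
    }
  })
})
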
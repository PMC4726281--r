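test_that("Aalen-Johansen reduces to 1 - KM with a single cause", {
  withr::with_seed(2, {
    t <- sample(1:15, 25, replace = TRUE)
  })
  inc <- cif_estimate(t, rep(1L, 25))
  km <- km_fit(t, rep(TRUE, 25))
  expect_equal(inc$cif["1", ], 1 - km$survival, tolerance = 1e-12)
  expect_true(all(inc$cif[2:5, ] == 0))
})

test_that("two-subject fixture matches the hand estimate", {
  inc <- cif_estimate(c(1, 2), c(1L, 2L))
  expect_equal(inc$times, c(1, 2))
  expect_equal(inc$cif["1", ], c(0.5, 0.5))
  expect_equal(inc$cif["2", ], c(0, 0.5))
  expect_equal(colSums(inc$cif) + inc$overall_survival, c(1, 1),
               tolerance = 1e-15)
})

test_that("all-censored data yield identically zero incidence", {
  inc <- cif_estimate(rep(210, 5), rep(0L, 5))
  expect_length(inc$times, 0)
  expect_error(cif_estimate(numeric(0), integer(0)),
               class = "pupsurv_input_error")
  expect_error(cif_estimate(c(1, 2), c(1L, 7L)),
               class = "pupsurv_input_error")
})

test_that("incidences and survival partition probability exactly", {
  withr::with_seed(23, {
    for (i in 1:15) {
      n <- sample(10:80, 1)
      t <- sample(1:12, n, replace = TRUE)
      c_codes <- sample(0:5, n, replace = TRUE)
      inc <- cif_estimate(t, c_codes)
      if (length(inc$times) == 0) next
      expect_lt(max(abs(colSums(inc$cif) + inc$overall_survival - 1)),
                1e-12)
      # each CIF is non-decreasing
      expect_true(all(apply(inc$cif, 1, function(v) all(diff(v) >= -1e-15))))
    }
  })
})

test_that("incidence agrees with the reference implementation", {
  skip_if_not_installed("cmprsk")
  withr::with_seed(31, {
    t <- sample(1:20, 60, replace = TRUE)
    codes <- sample(0:3, 60, replace = TRUE)
  })
  if (!any(codes == 1)) codes[1] <- 1L
  inc <- cif_estimate(t, codes)
  ref <- cmprsk::cuminc(t, codes)
  for (cc in intersect(unique(codes), 1:5)) {
    est <- ref[[paste("1", cc)]]
    # cuminc duplicates jump times for plotting; compare post-jump values
    keep <- !duplicated(est$time, fromLast = TRUE)
    ours <- vapply(est$time[keep], function(tt) {
      cif_at(inc, cc, tt)
    }, numeric(1))
    expect_equal(ours, est$est[keep], tolerance = 1e-10)
  }
})

test_that("Gray's test is symmetric and null at identical groups", {
  t <- c(1, 2, 3, 4, 5, 6)
  codes <- c(1L, 2L, 1L, 0L, 2L, 1L)
  # identical groups: duplicate the data across labels
  g0 <- gray_test(rep(t, 2), rep(codes, 2), rep(c("a", "b"), each = 6), 1)
  expect_equal(g0$statistic, 0, tolerance = 1e-12)

  withr::with_seed(41, {
    n <- 80
    tt <- sample(1:10, n, replace = TRUE)
    cc <- sample(0:3, n, replace = TRUE)
    gg <- sample(c("x", "y"), n, replace = TRUE)
  })
  if (!any(cc == 2)) cc[1] <- 2L
  ab <- gray_test(tt, cc, gg, 2)
  ba <- gray_test(tt, cc, ifelse(gg == "x", "y", "x"), 2)
  expect_equal(ab$statistic, ba$statistic, tolerance = 1e-10)

  expect_error(gray_test(tt, cc, rep("x", n), 2),
               class = "pupsurv_input_error")
  expect_error(gray_test(tt, cc, gg, 5), class = "pupsurv_input_error")
})

test_that("with complete follow-up Gray's test nears the count chi-square", {
  # no censoring before the horizon: the incidence comparison collapses
  # towards the 2x2 chi-square on final cause counts
  withr::with_seed(55, {
    na <- 160; nb <- 150
    ca <- sample(1:5, na, replace = TRUE, prob = c(0.3, 0.05, 0.05, 0.2, 0.4))
    cb <- sample(1:5, nb, replace = TRUE, prob = c(0.3, 0.25, 0.05, 0.05, 0.35))
    ta <- sample(1:200, na, replace = TRUE)
    tb <- sample(1:200, nb, replace = TRUE)
  })
  g <- gray_test(c(ta, tb), c(ca, cb), rep(c("a", "b"), c(na, nb)), 2)
  tab <- rbind(c(sum(ca == 2), na - sum(ca == 2)),
               c(sum(cb == 2), nb - sum(cb == 2)))
  cs <- contingency_chisq(tab)
  expect_lt(abs(g$statistic - cs$chisq) / cs$chisq, 0.05)
})

test_that("Gray's statistic agrees with the reference implementation", {
  skip_if_not_installed("cmprsk")
  withr::with_seed(99, {
    for (i in 1:4) {
      n <- 400
      g <- rep(0:1, each = n / 2)
      c1 <- ifelse(g == 1, sample(1:2, n, TRUE, c(0.7, 0.3)),
                   sample(1:2, n, TRUE, c(0.35, 0.65)))
      t <- rexp(n, 0.012)
      cens <- runif(n, 30, 300)
      cause <- ifelse(t <= cens, c1, 0L)
      time <- pmin(t, cens)
      ours <- gray_test(time, cause, g, 1)
      ref <- cmprsk::cuminc(time, cause, g)$Tests["1", "stat"]
      expect_lt(abs(ours$statistic - ref) / ref, 0.1)
    }
  })
})

test_that("permuted group labels give a uniform p-value distribution", {
  withr::with_seed(123, {
    n <- 240
    tt <- sample(1:210, n, replace = TRUE)
    cc <- sample(c(0L, 1L, 2L, 5L), n, replace = TRUE,
                 prob = c(0.2, 0.3, 0.3, 0.2))
    ps <- vapply(1:120, function(i) {
      gg <- sample(rep(c("a", "b"), n / 2))
      gray_test(tt, cc, gg, 2)$p
    }, numeric(1))
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(ps < 0.5), 0.3)
  expect_lt(mean(ps < 0.5), 0.7)
})

test_that("contingency chi-square reproduces the census sex contrasts", {
  counts <- observed_cause_counts()
  n_f <- sum(counts["female", ]); n_m <- sum(counts["male", ])
  taken <- contingency_chisq(rbind(
    c(counts["female", "2"], n_f - counts["female", "2"]),
    c(counts["male", "2"], n_m - counts["male", "2"])))
  expect_equal(round(taken$chisq, 2), 25.83)
  road <- contingency_chisq(rbind(
    c(counts["female", "4"], n_f - counts["female", "4"]),
    c(counts["male", "4"], n_m - counts["male", "4"])))
  expect_equal(round(road$chisq, 2), 11.87)

  # equal row proportions: exactly zero
  expect_equal(contingency_chisq(rbind(c(10, 30), c(20, 60)))$chisq, 0,
               tolerance = 1e-12)
  expect_error(contingency_chisq(rbind(c(0, 0), c(5, 5))),
               class = "pupsurv_input_error")
})

test_that("cause tables tally age classes and sexes correctly", {
  coh <- as_cohort(fixture_records())
  tabs <- cause_tables(coh)
  by_age <- tabs$by_age
  # hand tally of the fixture: removals at ages 15,45,80,12,130,200,95
  # -> classes 0,1,2,0,4,6,3
  expect_equal(by_age$n_removals, c(2L, 1L, 1L, 1L, 1L, 0L, 1L))
  expect_equal(by_age$natural[1], 100)            # ages 15 and 12
  expect_equal(by_age$human_influenced[2], 100)   # age 45: taken
  expect_equal(by_age$human_influenced[3], 100)   # age 80: road accident
  expect_equal(by_age$human_influenced[4], 100)   # age 95: road accident
  expect_equal(by_age$missing_or_unknown[5], 100) # age 130: no information
  expect_equal(by_age$human_influenced[7], 100)   # age 200: murdered
  expect_true(all(is.na(by_age[6, c("human_influenced",
                                    "missing_or_unknown", "natural")])))
  rows_ok <- !is.na(by_age$natural)
  expect_equal(rowSums(by_age[rows_ok, c("human_influenced",
                                         "missing_or_unknown",
                                         "natural")]),
               rep(100, sum(rows_ok)), ignore_attr = TRUE)
  # sex table counts every sexed pup exactly once
  expect_equal(sum(tabs$by_sex), 9)

  # all removals natural: the natural column is 100 everywhere observed
  rec <- fixture_records()[c(1, 5), ]
  rec$exit_category <- "natural_death"
  t2 <- cause_tables(as_cohort(rec))
  obs <- !is.na(t2$by_age$natural)
  expect_true(all(t2$by_age$natural[obs] == 100))
})

test_that("generated cohorts reproduce the schedule's age-class mix", {
  cfg <- generator_config(n_litters = 8000, seed = 64)
  coh <- generate_cohort(cfg)
  tabs <- cause_tables(coh)
  sch <- cfg$schedule
  # expected per-class aggregate shares from the schedule itself
  # (equal sex mix at birth, habitats identical)
  sb <- vapply(c("female", "male"), function(s) {
    schedule_expected_survival(sch, s)$surv_before
  }, numeric(7))
  for (m in 0:6) {
    h_fm <- sch$h[, , "urban", m + 1]  # causes x sex
    w <- sb[m + 1, ]  # P(alive at class m) per sex
    removals <- h_fm %*% (0.5 * w)
    shares <- 100 * c(
      human_influenced = sum(removals[2:4]),
      missing_or_unknown = removals[5],
      natural = removals[1]) / sum(removals)
    n_m <- tabs$by_age$n_removals[m + 1]
    for (a in names(shares)) {
      p <- shares[[a]] / 100
      se <- sqrt(p * (1 - p) / n_m)
      # degenerate cells (share 0 or 1) must be hit exactly
      expect_lte(abs(tabs$by_age[[a]][m + 1] / 100 - p),
                 3.5 * se + 1e-12)
    }
  }
})
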
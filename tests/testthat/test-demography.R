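test_that("litter summaries use n-1 sd and inclusive quartiles", {
  s <- litter_summary(c(3, 4, 5))
  expect_equal(s$mean, 4)
  expect_equal(s$median, 4)
  expect_equal(s$sd, 1)
  expect_equal(s$n, 3)
  expect_false(s$degenerate)

  s1 <- litter_summary(4)
  expect_true(s1$degenerate)
  expect_true(is.na(s1$sd))
  expect_equal(s1$mean, 4)

  expect_error(litter_summary(numeric(0)), class = "pupsurv_input_error")

  # a large draw from the default litter-size distribution recovers its
  # calibrated mean within Monte-Carlo error
  pmf <- litter_size_default_pmf()
  withr::with_seed(21, {
    draw <- sample(as.numeric(names(pmf)), 5000, replace = TRUE,
                   prob = pmf)
  })
  se <- sd(draw) / sqrt(length(draw))
  expect_lt(abs(mean(draw) - 3.98), 2 * se)
})

test_that("Mann-Whitney U follows the pair-count definition with ties", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 1 / 3)  # enumeration of C(4,2) assignments
  expect_identical(r$method, "exact")

  x <- c(1, 3, 5, 7)
  same <- mann_whitney_u(x, x)
  expect_equal(same$U_x, length(x)^2 / 2)
  expect_equal(same$U_y, length(x)^2 / 2)

  tie <- mann_whitney_u(1, 1)
  expect_equal(tie$U, 0.5)  # single tied pair counts one half

  expect_error(mann_whitney_u(numeric(0), 1),
               class = "pupsurv_input_error")
})

test_that("normal approximation converges to the permutation law", {
  # at sizes where the CLT applies, the tie-corrected normal p tracks a
  # Monte-Carlo estimate of the exact permutation p within 0.02
  withr::with_seed(31, {
    for (i in 1:6) {
      x <- sample(1:8, 20, replace = TRUE)
      y <- sample(1:8, 20, replace = TRUE) + rbinom(20, 1, 0.4)
      pn <- mann_whitney_u(x, y, exact = FALSE)$p_two_sided
      pool <- c(x, y)
      mu <- 20 * 20 / 2
      u_stat <- function(idx) {
        r <- rank(c(pool[idx], pool[-idx]))
        sum(r[1:20]) - 20 * 21 / 2
      }
      uobs <- u_stat(1:20)
      us <- replicate(4000, u_stat(sample(40, 20)))
      pmc <- mean(abs(us - mu) >= abs(uobs - mu) - 1e-9)
      expect_lt(abs(pn - pmc), 0.02)
    }
  })
})

test_that("exact U p-values match the reference implementation", {
  skip_if_not_installed("stats")
  x <- c(1.1, 2.3, 4.7, 5.2)
  y <- c(0.4, 3.3, 6.8)
  ours <- mann_whitney_u(x, y, exact = TRUE)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(ours$U_x, unname(ref$statistic))
  expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-12)
})

test_that("simple regression summaries follow the sign conventions", {
  f <- ols_fit(1:5, 2 * (1:5))
  expect_equal(f$r_squared, 1)
  expect_equal(f$std_beta, 1)
  expect_equal(f$slope, 2)

  g <- ols_fit(1:5, -(1:5))
  expect_equal(g$std_beta, -1)

  h <- ols_fit(c(0, 1, 2), c(0, 1, 0))
  expect_equal(h$slope, 0)
  expect_equal(h$r_squared, 0)

  expect_error(ols_fit(rep(2, 5), 1:5), class = "pupsurv_input_error")

  # shifting and scaling x changes neither R^2 nor the p-value
  withr::with_seed(3, {
    x <- rnorm(30)
    y <- 1.5 * x + rnorm(30)
  })
  a <- ols_fit(x, y)
  b <- ols_fit(10 + 3 * x, y)
  expect_equal(a$r_squared, b$r_squared, tolerance = 1e-12)
  expect_equal(a$p_slope, b$p_slope, tolerance = 1e-12)
  expect_equal(a$std_beta, b$std_beta, tolerance = 1e-12)
})

test_that("slope-homogeneity F-test matches direct SSE arithmetic", {
  d1 <- list(x = c(0, 1, 2, 3), y = c(0.1, 1.2, 1.9, 3.1))
  d2 <- list(x = c(0, 1, 2, 3), y = c(5.0, 4.2, 3.1, 1.8))
  res <- compare_regressions(list(d1, d2))
  expect_equal(res$F, oracle_slope_homogeneity_F(list(d1, d2)),
               tolerance = 1e-10)
  expect_equal(res$df1, 1L)
  expect_equal(res$df2, 4L)

  # the same dataset twice: identical slopes, F = 0
  same <- compare_regressions(list(d1, d1))
  expect_equal(same$F, 0, tolerance = 1e-10)

  # noise-free opposite slopes: unbounded statistic, capped and flagged
  e1 <- list(x = 0:3, y = 0:3)
  e2 <- list(x = 0:3, y = -(0:3))
  deg <- compare_regressions(list(e1, e2))
  expect_true(deg$degenerate)
  expect_identical(deg$F, Inf)
  expect_equal(deg$p, 0)

  expect_error(compare_regressions(list(d1)),
               class = "pupsurv_input_error")
  expect_error(compare_regressions(list(d1, list(x = rep(1, 4),
                                                 y = 1:4))),
               class = "pupsurv_input_error")
})

test_that("net pup counts accumulate births minus removals per bin", {
  # no removals: the series is just cumulative births
  rec <- data.frame(
    pup_id = c("a", "b"), litter_id = c("l1", "l2"),
    sex = "female", habitat = "urban", birth_day = c(5L, 65L),
    exit_age_days = 210L, exit_category = "survived",
    stringsAsFactors = FALSE)
  nc <- monthly_net_counts(rec)
  expect_equal(nc$net[1], 1)
  expect_true(all(nc$net == nc$births))

  # one pup born in bin 0, removed in bin 2: 1, 1, 0, ...
  one <- data.frame(
    pup_id = "a", litter_id = "l1", sex = "male", habitat = "urban",
    birth_day = 10L, exit_age_days = 65L,
    exit_category = "natural_death", stringsAsFactors = FALSE)
  nc1 <- monthly_net_counts(one)
  expect_equal(nc1$net, c(1, 1, 0))

  # in expectation the synthetic series rises to a peak then declines:
  # averaged over replicates, the post-peak tail is monotone down
  nets <- sapply(1:20, function(seed) {
    coh <- generate_cohort(generator_config(n_litters = 95, seed = seed))
    v <- monthly_net_counts(coh)$net
    length(v) <- 13  # common grid; missing tail = NA
    v
  })
  mean_net <- rowMeans(nets, na.rm = TRUE)
  mean_net <- mean_net[!is.nan(mean_net)]  # drop bins past every cohort
  peak <- which.max(mean_net)
  expect_true(peak > 1 && peak < length(mean_net))
  expect_true(all(diff(mean_net[peak:length(mean_net)]) <= 0))
})
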
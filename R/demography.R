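#' Litter-size summary statistics
#'
#' Sample mean, standard deviation (n-1 denominator), median and quartiles
#' (inclusive linear interpolation, i.e. `stats::quantile()` type 7) of
#' litter sizes.
#'
#' @param litters A `pup_cohort`, a litter data frame with a
#'   `size_at_birth` column, or a numeric vector of sizes.
#' @return List with elements `mean`, `sd`, `median`, `q1`, `q3`, `n` and
#'   `degenerate` (`TRUE` when `n = 1`, in which case `sd` is `NA`).
#' @examples
#' litter_summary(c(3, 4, 5))
#' @export
litter_summary <- function(litters) {
  sizes <- if (inherits(litters, "pup_cohort")) {
    litters$litters$size_at_birth
  } else if (is.data.frame(litters)) {
    litters$size_at_birth
  } else {
    as.numeric(litters)
  }
  if (length(sizes) == 0L || anyNA(sizes)) {
    stop_pupsurv("litter sizes must be non-empty and non-missing",
                 class = "pupsurv_input_error")
  }
  qs <- quantile(sizes, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(mean = mean(sizes),
       sd = if (length(sizes) > 1L) sd(sizes) else NA_real_,
       median = qs[2], q1 = qs[1], q3 = qs[3],
       n = length(sizes),
       degenerate = length(sizes) == 1L)
}

#' Mann-Whitney U test for two samples
#'
#' Computes the U statistic by the pair-count definition
#' `U_x = sum over pairs of [x_i > y_j] + 1/2 [x_i = y_j]` (ties counted
#' as one half), reporting `U = min(U_x, U_y)` together with both
#' one-sided counts. When the combined sample size is at most 12 the
#' two-sided p-value is computed by exact enumeration of all group
#' assignments (valid under ties); otherwise by the tie-corrected normal
#' approximation without continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default `NULL` chooses enumeration when `length(x) + length(y) <= 12`.
#' @return List with `U`, `U_x`, `U_y`, `p_two_sided`, `n_x`, `n_y` and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L || anyNA(x) || anyNA(y)) {
    stop_pupsurv("both samples must be non-empty and non-missing",
                 class = "pupsurv_input_error")
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  u_of <- function(xs, ys) {
    # midranks give exactly the half-count tie convention
    r <- rank(c(xs, ys))
    sum(r[seq_along(xs)]) - length(xs) * (length(xs) + 1) / 2
  }
  ux <- u_of(x, y)
  uy <- nx * ny - ux
  u <- min(ux, uy)
  mu <- nx * ny / 2
  do_exact <- exact %||% (n <= 12L)
  if (do_exact) {
    pool <- c(x, y)
    combos <- combn(n, nx)
    us <- apply(combos, 2, function(idx) u_of(pool[idx], pool[-idx]))
    p <- mean(abs(us - mu) >= abs(ux - mu) - 1e-12)
    method <- "exact"
  } else {
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1  # all observations tied: no evidence either way
    } else {
      z <- (ux - mu) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal"
  }
  list(U = u, U_x = ux, U_y = uy, p_two_sided = min(p, 1),
       n_x = nx, n_y = ny, method = method)
}

#' Simple linear regression summary
#'
#' Ordinary least squares of `y` on `x` via [stats::lm()], reported in the
#' form used for the demographic trend analyses: slope, intercept, R^2,
#' the standardised slope (signed square root of R^2, the convention for
#' simple regression) and the slope's two-sided p-value on `n - 2`
#' degrees of freedom. Any transform of `y` (e.g. log10 of survivor
#' counts) is the caller's responsibility.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; `x` must not be
#'   constant.
#' @return An object of class `regression_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `std_beta`, `p_slope`, `n`.
#' @examples
#' ols_fit(1:5, c(2, 4, 6, 8, 10))
#' @export
ols_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L || anyNA(x) || anyNA(y)) {
    stop_pupsurv("x and y must be equal-length, complete, n >= 3",
                 class = "pupsurv_input_error")
  }
  if (var(x) == 0) {
    stop_pupsurv("x is constant; slope undefined",
                 class = "pupsurv_input_error")
  }
  fit <- lm(y ~ x)
  # summary.lm warns on numerically perfect fits; those are legitimate
  # inputs here (noise-free series), so the warning is not ours to pass on
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  r2 <- sm$r.squared
  p <- unname(sm$coefficients[2, 4])
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]),
         r_squared = r2, std_beta = sign(slope) * sqrt(r2),
         p_slope = p, n = length(x)),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "Linear regression (n = %d): slope %.4g, R^2 = %.3f, std beta = %.3f, P = %.3g\n",
    x$n, x$slope, x$r_squared, x$std_beta, x$p_slope))
  invisible(x)
}

#' Test of slope homogeneity across regression datasets
#'
#' ANCOVA-style F-test comparing a common-slope model (separate
#' intercepts, one slope) against separate slopes per dataset:
#' `F = [(SSE_common - SSE_separate) / (k - 1)] / [SSE_separate / (N - 2k)]`.
#' Used to ask whether the age-survival decline is the same across
#' sampling years.
#'
#' @param datasets List of `k >= 2` datasets, each a list or data frame
#'   with numeric elements `x` and `y` (each `n >= 3`, `x` non-constant).
#' @return List with `F`, `p`, `df1`, `df2` and `degenerate` (`TRUE`,
#'   with `F = Inf`, `p = 0`, when the separate-slope fit is exact so the
#'   statistic is unbounded).
#' @export
compare_regressions <- function(datasets) {
  if (!is.list(datasets) || length(datasets) < 2L) {
    stop_pupsurv("need at least two datasets to compare slopes",
                 class = "pupsurv_input_error")
  }
  k <- length(datasets)
  parts <- lapply(seq_len(k), function(i) {
    d <- datasets[[i]]
    x <- as.numeric(d$x); y <- as.numeric(d$y)
    if (length(x) < 3L || length(x) != length(y)) {
      stop_pupsurv("each dataset needs matched x, y with n >= 3",
                   class = "pupsurv_input_error")
    }
    if (var(x) == 0) {
      stop_pupsurv("dataset ", i, " has constant x",
                   class = "pupsurv_input_error")
    }
    data.frame(x = x, y = y, g = factor(i, levels = seq_len(k)))
  })
  dat <- do.call(rbind, parts)
  n_total <- nrow(dat)
  sse_separate <- sum(unlist(lapply(parts, function(p) {
    sum(lm(y ~ x, data = p)$residuals^2)
  })))
  sse_common <- sum(lm(y ~ g + x, data = dat)$residuals^2)
  df1 <- k - 1L
  df2 <- n_total - 2L * k
  if (df2 <= 0L) {
    stop_pupsurv("too few observations for the slope-homogeneity test",
                 class = "pupsurv_input_error")
  }
  if (sse_separate < 1e-12) {
    if (sse_common - sse_separate < 1e-12) {
      # all fits exact and coincident: no evidence of slope differences
      return(list(F = 0, p = 1, df1 = df1, df2 = df2, degenerate = TRUE))
    }
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2, degenerate = TRUE))
  }
  f <- ((sse_common - sse_separate) / df1) / (sse_separate / df2)
  f <- max(f, 0)  # guard tiny negative from floating-point
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, degenerate = FALSE)
}

#' Cumulative net pup counts per calendar month
#'
#' For each 30-day calendar bin of the study timeline, the cumulative
#' number of births minus the cumulative number of removals (exits with
#' any category other than `survived`) up to the end of that bin -- the
#' "net number of pups" trajectory that rises through the whelping season
#' and declines as mortality overtakes births.
#'
#' @param records A `pup_cohort` or validated records data frame.
#' @return Data frame with columns `month` (bin index from the study
#'   origin), `births`, `removals` (both cumulative) and `net`.
#' @export
monthly_net_counts <- function(records) {
  r <- if (inherits(records, "pup_cohort")) records$records else
    validate_records(records)
  if (nrow(r) == 0L) {
    return(data.frame(month = integer(0), births = integer(0),
                      removals = integer(0), net = integer(0)))
  }
  exit_day <- r$birth_day + r$exit_age_days
  last_bin <- max(c(r$birth_day, exit_day)) %/% 30
  months <- 0:last_bin
  births <- vapply(months, function(b) sum(r$birth_day < 30 * (b + 1)),
                   numeric(1))
  removals <- vapply(months, function(b) {
    sum(!r$censored & exit_day < 30 * (b + 1))
  }, numeric(1))
  data.frame(month = months, births = births, removals = removals,
             net = births - removals)
}

#' Survivor counts by month of age
#'
#' Number of pups still present at each month-of-age boundary (0..7),
#' the series whose log10 declines linearly with age under a constant
#' monthly hazard.
#'
#' @param records A `pup_cohort` or validated records data frame.
#' @return Data frame with columns `month` (0..7) and `alive` (count with
#'   `exit_age_days >= 30 * month`).
#' @export
survivors_by_age <- function(records) {
  r <- if (inherits(records, "pup_cohort")) records$records else
    validate_records(records)
  months <- 0:7
  alive <- vapply(months, function(m) sum(r$exit_age_days >= 30 * m),
                  numeric(1))
  data.frame(month = months, alive = alive)
}
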
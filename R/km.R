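#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function of right-censored lifetimes by the
#' product-limit formula `S(t) = prod over t_i <= t of (1 - d_i / n_i)`,
#' with the Greenwood variance `S(t)^2 sum d_i / (n_i (n_i - d_i))`. At
#' tied times, events are processed before censorings (both use the same
#' at-risk count; censored subjects leave the risk set after the events
#' at their time).
#'
#' @param durations Non-negative lifetimes in days.
#' @param event_observed Logical vector, `TRUE` where the removal was
#'   observed and `FALSE` where the lifetime is right-censored.
#' @return An object of class `survival_curve`: a list with `time`,
#'   `at_risk`, `n_events`, `n_censored`, `survival`, `variance`,
#'   `std_err` (one entry per distinct observed time, event or censoring)
#'   and `n_total`.
#' @examples
#' km_fit(c(2, 4, 4, 6), c(TRUE, TRUE, TRUE, FALSE))
#' @export
km_fit <- function(durations, event_observed) {
  durations <- as.numeric(durations)
  event_observed <- as.logical(event_observed)
  if (length(durations) == 0L) {
    stop_pupsurv("empty input", class = "pupsurv_input_error")
  }
  if (length(durations) != length(event_observed) ||
      anyNA(durations) || anyNA(event_observed) || any(durations < 0)) {
    stop_pupsurv("durations must be non-negative and matched with event ",
                 "flags", class = "pupsurv_input_error")
  }
  times <- sort(unique(durations))
  at_risk <- vapply(times, function(t) sum(durations >= t), numeric(1))
  d <- vapply(times, function(t) sum(durations == t & event_observed),
              numeric(1))
  cens <- vapply(times, function(t) sum(durations == t & !event_observed),
                 numeric(1))
  surv <- cumprod(1 - d / at_risk)
  gterm <- ifelse(at_risk > d, d / (at_risk * (at_risk - d)), 0)
  variance <- surv^2 * cumsum(gterm)   # 0 once S reaches 0
  structure(
    list(time = times, at_risk = at_risk, n_events = d, n_censored = cens,
         survival = surv, variance = variance, std_err = sqrt(variance),
         n_total = length(durations)),
    class = "survival_curve"
  )
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, censored = %d\n",
              x$n_total, sum(x$n_events), sum(x$n_censored)))
  df <- data.frame(time = x$time, at_risk = x$at_risk,
                   n_events = x$n_events, survival = round(x$survival, 4),
                   std_err = round(x$std_err, 4))
  print(head(df[df$n_events > 0, ], 20), row.names = FALSE)
  invisible(x)
}

#' Export a survival curve as a data frame
#'
#' @param x A `survival_curve`.
#' @param row.names,optional,... Passed over for generic consistency.
#' @return Data frame with columns `time`, `at_risk`, `n_events`,
#'   `n_censored`, `survival`, `std_err`.
#' @export
as.data.frame.survival_curve <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(time = x$time, at_risk = x$at_risk, n_events = x$n_events,
             n_censored = x$n_censored, survival = x$survival,
             std_err = x$std_err)
}

# pointwise confidence bands on the log(-log S) (complementary log-log)
# scale; the standard transform-respecting bands for survival curves
loglog_bands <- function(curve, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  s <- curve$survival
  lower <- upper <- s
  interior <- s > 0 & s < 1
  se_cll <- rep(NA_real_, length(s))
  se_cll[interior] <- curve$std_err[interior] /
    (s[interior] * abs(log(s[interior])))
  lower[interior] <- s[interior]^exp(z * se_cll[interior])
  upper[interior] <- s[interior]^exp(-z * se_cll[interior])
  list(lower = lower, upper = upper)
}

#' Median survival time with Brookmeyer-Crowley confidence limits
#'
#' The median is the smallest observed time at which the Kaplan-Meier
#' estimate falls to one half or below. Confidence limits invert the
#' pointwise bands on the log(-log) scale (the Brookmeyer-Crowley
#' construction): the lower limit is the first time at which the upper
#' band reaches 0.5, the upper limit the first time at which the lower
#' band does. Limits that never cross are reported as `NA`.
#'
#' @param curve A `survival_curve` from [km_fit()].
#' @param level Confidence level, default 0.95.
#' @return List with `median_days`, `lo`, `hi`, `level`, `defined`
#'   (`FALSE`, with `median_days = NA`, when the curve never reaches 0.5)
#'   and `conf_type = "log-log"`.
#' @examples
#' km_median_ci(km_fit(c(2, 4, 4, 6), c(TRUE, TRUE, TRUE, FALSE)))
#' @export
km_median_ci <- function(curve, level = 0.95) {
  stopifnot(inherits(curve, "survival_curve"))
  tol <- 1e-12
  crossed <- curve$survival <= 0.5 + tol
  if (!any(crossed)) {
    return(list(median_days = NA_real_, lo = NA_real_, hi = NA_real_,
                level = level, defined = FALSE, conf_type = "log-log"))
  }
  med <- curve$time[which(crossed)[1L]]
  bands <- loglog_bands(curve, level)
  first_at_or_below <- function(v) {
    ok <- !is.na(v) & v <= 0.5 + tol
    if (any(ok)) curve$time[which(ok)[1L]] else NA_real_
  }
  list(median_days = med,
       lo = first_at_or_below(bands$lower),
       hi = first_at_or_below(bands$upper),
       level = level, defined = TRUE, conf_type = "log-log")
}

#' Two-sample log-rank test
#'
#' The unweighted log-rank test: at each distinct event time the observed
#' number of group-A events is compared with its hypergeometric
#' expectation given the pooled events and at-risk counts, and the
#' statistic is `(O_A - E_A)^2 / V` with `V` the summed hypergeometric
#' variances, referred to chi-square on 1 degree of freedom.
#'
#' @param durations_a,durations_b Lifetimes in the two groups.
#' @param events_a,events_b Logical event indicators (`FALSE` =
#'   right-censored).
#' @return List with `chisq`, `df = 1`, `p`, `observed` and `expected`
#'   (group-A event totals).
#' @examples
#' logrank_test(c(1, 2), c(TRUE, TRUE), c(3, 4), c(TRUE, TRUE))
#' @export
logrank_test <- function(durations_a, events_a, durations_b, events_b) {
  da <- as.numeric(durations_a); db <- as.numeric(durations_b)
  ea <- as.logical(events_a); eb <- as.logical(events_b)
  if (length(da) == 0L || length(db) == 0L) {
    stop_pupsurv("both groups must be non-empty",
                 class = "pupsurv_input_error")
  }
  if (!any(ea) && !any(eb)) {
    stop_pupsurv("no events in either group",
                 class = "pupsurv_input_error")
  }
  times <- sort(unique(c(da[ea], db[eb])))
  o_a <- e_a <- v <- 0
  for (t in times) {
    ya <- sum(da >= t); yb <- sum(db >= t); y <- ya + yb
    dta <- sum(da == t & ea); dtb <- sum(db == t & eb)
    dt <- dta + dtb
    o_a <- o_a + dta
    e_a <- e_a + dt * ya / y
    if (y > 1) {
      v <- v + dt * (ya / y) * (yb / y) * (y - dt) / (y - 1)
    }
  }
  if (v <= 0) {
    stop_pupsurv("log-rank variance is zero (no comparable event times)",
                 class = "pupsurv_input_error")
  }
  chisq <- (o_a - e_a)^2 / v
  list(chisq = chisq, df = 1L,
       p = pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = o_a, expected = e_a, variance = v)
}
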
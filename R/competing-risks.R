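#' Aalen-Johansen cumulative incidence functions
#'
#' Estimates, for each removal cause, the probability of having been
#' removed by that cause by time `t` in the presence of the competing
#' causes: `CIF_c(t) = sum over event times t_i <= t of
#' S(t_i-) d_{c,i} / n_i`, with `S` the all-cause Kaplan-Meier estimate.
#' By construction the cause-specific incidences and overall survival
#' partition probability: `sum_c CIF_c(t) + S(t) = 1` at every time.
#'
#' @param durations Non-negative lifetimes in days.
#' @param cause_codes Integer codes: 0 = censored (survived to the
#'   horizon), 1-5 = removal cause.
#' @return Object of class `incidence_set`: `times` (distinct event
#'   times), `cif` (5 x length(times) matrix, one row per cause code),
#'   `overall_survival`, `n_total`.
#' @examples
#' cif_estimate(c(1, 2), c(1, 2))
#' @export
cif_estimate <- function(durations, cause_codes) {
  durations <- as.numeric(durations)
  cause_codes <- as.integer(cause_codes)
  if (length(durations) == 0L) {
    stop_pupsurv("empty input", class = "pupsurv_input_error")
  }
  if (length(durations) != length(cause_codes) || anyNA(durations) ||
      anyNA(cause_codes) || any(durations < 0) ||
      any(!cause_codes %in% 0:5)) {
    stop_pupsurv("durations must be non-negative and cause codes in 0..5",
                 class = "pupsurv_input_error")
  }
  times <- sort(unique(durations[cause_codes != 0L]))
  k <- length(times)
  cif <- matrix(0, nrow = 5, ncol = k,
                dimnames = list(cause = as.character(1:5), NULL))
  surv <- numeric(k)
  s <- 1
  acc <- numeric(5)
  for (i in seq_len(k)) {
    t <- times[i]
    n_risk <- sum(durations >= t)
    d_c <- vapply(1:5, function(c) {
      sum(durations == t & cause_codes == c)
    }, numeric(1))
    acc <- acc + s * d_c / n_risk
    s <- s * (1 - sum(d_c) / n_risk)
    cif[, i] <- acc
    surv[i] <- s
  }
  structure(
    list(times = times, cif = cif, overall_survival = surv,
         n_total = length(durations)),
    class = "incidence_set"
  )
}

#' @export
print.incidence_set <- function(x, ...) {
  cat(sprintf("Cumulative incidence (Aalen-Johansen): n = %d, %d event times\n",
              x$n_total, length(x$times)))
  if (length(x$times) > 0L) {
    final <- x$cif[, ncol(x$cif)]
    cat("final incidence by cause:\n")
    print(round(setNames(final, cause_label(1:5)), 4))
  }
  invisible(x)
}

#' Cumulative incidence at a time point
#'
#' @param incidence An `incidence_set`.
#' @param cause Cause code in 1..5.
#' @param t Time (days); defaults to the last event time.
#' @return The estimated `CIF_cause(t)`.
#' @export
cif_at <- function(incidence, cause, t = Inf) {
  stopifnot(inherits(incidence, "incidence_set"), cause %in% 1:5)
  idx <- which(incidence$times <= t)
  if (length(idx) == 0L) return(0)
  incidence$cif[as.character(cause), max(idx)]
}

# Kaplan-Meier estimate of the censoring distribution G(t-), per group.
# Censorings at a time are taken to occur after the events at that time,
# so the censoring risk set at t excludes subjects failing at t.
censoring_km_before <- function(time, is_event) {
  ut <- sort(unique(time))
  s <- 1
  surv <- numeric(length(ut))
  for (j in seq_along(ut)) {
    at <- sum(time >= ut[j])
    d_ev <- sum(time == ut[j] & is_event)
    d_cn <- sum(time == ut[j] & !is_event)
    denom <- at - d_ev
    if (denom > 0) s <- s * (1 - d_cn / denom)
    surv[j] <- s
  }
  # G just BEFORE each time point
  function(t) {
    idx <- ut < t
    if (!any(idx)) 1 else surv[max(which(idx))]
  }
}

#' Gray's test for a group difference in cumulative incidence
#'
#' Two-sample comparison of the cumulative incidence of one cause under
#' competing risks, in Gray's rho = 0 (unweighted) form: the score
#' contrasts the groups' subdistribution hazards, with subjects who
#' failed earlier from a competing cause retained in the risk set under
#' inverse-probability-of-censoring weights from each group's own
#' censoring Kaplan-Meier estimate. The statistic is the squared score
#' over its (weighted hypergeometric) variance, referred to chi-square on
#' 1 degree of freedom; this is the score-test form of the
#' subdistribution-hazard (Fine-Gray) model for a binary group and
#' coincides with the unweighted log-rank on the subdistribution when
#' there is no censoring before the horizon.
#'
#' @param durations Lifetimes in days.
#' @param cause_codes Integer codes: 0 = censored, 1-5 = removal cause.
#' @param group_labels Vector with exactly two distinct values.
#' @param target_cause The cause (1..5) whose incidence is compared.
#' @return List with `statistic`, `df = 1`, `p`, `score`, `variance` and
#'   the group labels compared.
#' @examples
#' gray_test(c(1, 2, 3, 4), c(1, 2, 1, 2), c("a", "a", "b", "b"), 1)
#' @export
gray_test <- function(durations, cause_codes, group_labels, target_cause) {
  time <- as.numeric(durations)
  cause <- as.integer(cause_codes)
  group <- as.character(group_labels)
  if (!target_cause %in% 1:5) {
    stop_pupsurv("target_cause must be in 1..5",
                 class = "pupsurv_input_error")
  }
  groups <- sort(unique(group))
  if (length(groups) != 2L) {
    stop_pupsurv("exactly two groups are required",
                 class = "pupsurv_input_error")
  }
  if (!any(cause == target_cause)) {
    stop_pupsurv("target cause ", target_cause, " absent from the data",
                 class = "pupsurv_input_error")
  }
  G <- lapply(groups, function(g) {
    censoring_km_before(time[group == g], cause[group == g] != 0L)
  })
  names(G) <- groups
  # per-subject censoring-KM value just before the subject's own time
  G_own <- numeric(length(time))
  for (g in groups) {
    idx <- group == g
    G_own[idx] <- vapply(time[idx], G[[g]], numeric(1))
  }
  ev_times <- sort(unique(time[cause == target_cause]))
  score <- 0
  v <- 0
  for (t in ev_times) {
    Gt <- vapply(groups, function(g) G[[g]](t), numeric(1))
    ystar <- vapply(seq_along(groups), function(k) {
      ing <- group == groups[k]
      n_atrisk <- sum(ing & time >= t)
      prior <- ing & time < t & cause != 0L & cause != target_cause
      w_prior <- if (any(prior)) {
        sum(Gt[k] / pmax(G_own[prior], 1e-300))
      } else 0
      n_atrisk + w_prior
    }, numeric(1))
    d_k <- vapply(groups, function(g) {
      sum(group == g & time == t & cause == target_cause)
    }, numeric(1))
    d <- sum(d_k)
    y <- sum(ystar)
    if (y <= 0) next
    score <- score + unname(d_k[1] - ystar[1] * d / y)
    corr <- if (y > 1) max(0, (y - d) / (y - 1)) else 0
    v <- v + unname(d * (ystar[1] * ystar[2] / y^2) * corr)
  }
  if (v <= 0) {
    stop_pupsurv("degenerate comparison: zero variance for target cause",
                 class = "pupsurv_input_error")
  }
  stat <- score^2 / v
  list(statistic = stat, df = 1L,
       p = pchisq(stat, df = 1, lower.tail = FALSE),
       score = score, variance = v, groups = groups,
       target_cause = as.integer(target_cause))
}

#' Pearson chi-square on a 2 x 2 table
#'
#' Companion approximation to [gray_test()]: with complete follow-up the
#' incidence comparison is close to the chi-square on final event
#' counts. Computed without continuity correction.
#'
#' @param table 2 x 2 matrix of non-negative counts with positive
#'   margins.
#' @return List with `chisq`, `df = 1`, `p`, `expected`.
#' @examples
#' contingency_chisq(rbind(c(8, 156), c(39, 117)))
#' @export
contingency_chisq <- function(table) {
  m <- as.matrix(table)
  if (!identical(dim(m), c(2L, 2L)) || any(m < 0) || anyNA(m)) {
    stop_pupsurv("a 2 x 2 matrix of non-negative counts is required",
                 class = "pupsurv_input_error")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_pupsurv("all table margins must be positive",
                 class = "pupsurv_input_error")
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(chisq = unname(ct$statistic), df = 1L, p = unname(ct$p.value),
       expected = ct$expected)
}

#' Age-class and sex-by-cause mortality tables
#'
#' Builds the two standard summaries of a cohort's mortality. The
#' age-class table gives, among removals in each 30-day age class, the
#' percentage attributed to each coarse cause class (human influenced,
#' missing or unknown, natural); rows sum to 100, and an age class with
#' no removals is reported as a flagged row of `NA` rather than a
#' division by zero. The sex table counts pups by sex and fine exit
#' category 0-5 (pups of unknown sex are excluded).
#'
#' @param records A `pup_cohort` or validated records data frame.
#' @return List with `by_age` (data frame: `age_class`, `n_removals`,
#'   percentage columns) and `by_sex` (2 x 6 count matrix).
#' @export
cause_tables <- function(records) {
  r <- if (inherits(records, "pup_cohort")) records$records else
    validate_records(records)
  removed <- r[!r$censored, ]
  agg_levels <- c("human_influenced", "missing_or_unknown", "natural")
  by_age <- data.frame(age_class = age_class_labels(),
                       n_removals = 0L)
  for (a in agg_levels) by_age[[a]] <- NA_real_
  if (nrow(removed) > 0L) {
    cls <- age_class_of(removed$exit_age_days)
    agg <- aggregate_cause(removed$exit_code)
    for (m in 0:6) {
      sel <- cls == m
      by_age$n_removals[m + 1L] <- sum(sel)
      if (any(sel)) {
        for (a in agg_levels) {
          by_age[[a]][m + 1L] <- 100 * sum(agg[sel] == a) / sum(sel)
        }
      }
    }
  }
  sexed <- r[r$sex != "unknown", ]
  by_sex <- matrix(0L, nrow = 2, ncol = 6,
                   dimnames = list(sex = c("female", "male"),
                                   category = as.character(0:5)))
  for (s in c("female", "male")) {
    for (code in 0:5) {
      by_sex[s, as.character(code)] <-
        sum(sexed$sex == s & sexed$exit_code == code)
    }
  }
  list(by_age = by_age, by_sex = by_sex)
}
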
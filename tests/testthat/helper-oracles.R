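# Independent oracles and fixture builders used across the suite.
# These deliberately use naive formulations (loops, direct formulas)
# so they share no code path with the package implementations.

# Efron partial log-likelihood for one covariate, written as plain loops
oracle_efron_loglik_1d <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event]))) {
    dead <- which(event & time == t)
    risk <- which(time >= t)
    d <- length(dead)
    sum_risk <- sum(exp(beta * x[risk]))
    sum_dead <- sum(exp(beta * x[dead]))
    ll <- ll + sum(beta * x[dead])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_risk - (l / d) * sum_dead)
    }
  }
  ll
}

# slope-homogeneity F by direct SSE arithmetic (closed-form simple OLS)
oracle_slope_homogeneity_F <- function(datasets) {
  sse_simple <- function(x, y) {
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a <- mean(y) - b * mean(x)
    sum((y - a - b * x)^2)
  }
  k <- length(datasets)
  sse_sep <- sum(vapply(datasets, function(d) sse_simple(d$x, d$y),
                        numeric(1)))
  # common-slope model: slope = pooled within-group covariance ratio
  sxx <- sxy <- 0
  for (d in datasets) {
    sxx <- sxx + sum((d$x - mean(d$x))^2)
    sxy <- sxy + sum((d$x - mean(d$x)) * (d$y - mean(d$y)))
  }
  b <- sxy / sxx
  sse_com <- sum(vapply(datasets, function(d) {
    a <- mean(d$y) - b * mean(d$x)
    sum((d$y - a - b * d$x)^2)
  }, numeric(1)))
  n <- sum(vapply(datasets, function(d) length(d$x), numeric(1)))
  ((sse_com - sse_sep) / (k - 1)) / (sse_sep / (n - 2 * k))
}

# a small valid records data frame built in code
fixture_records <- function() {
  data.frame(
    pup_id = sprintf("P%02d", 1:10),
    litter_id = rep(c("L1", "L2", "L3"), c(4, 3, 3)),
    sex = c("female", "male", "female", "unknown", "male", "male",
            "female", "female", "male", "female"),
    habitat = rep(c("urban", "suburban", "urban"), c(4, 3, 3)),
    birth_day = rep(c(10L, 40L, 85L), c(4, 3, 3)),
    exit_age_days = c(15L, 45L, 210L, 80L, 12L, 210L, 130L, 200L, 95L,
                      210L),
    exit_category = c("natural_death", "taken_by_human", "survived",
                      "road_accident", "natural_death", "survived",
                      "no_information", "murdered_by_human",
                      "road_accident", "survived"),
    stringsAsFactors = FALSE
  )
}

# random censored survival data for oracle cross-checks
random_survival_data <- function(n, tie_heavy = FALSE) {
  t <- if (tie_heavy) sample(1:8, n, replace = TRUE) else
    round(rexp(n, 0.05), 4)
  e <- runif(n) < 0.7
  list(time = t, event = e)
}
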
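#' Configuration for the synthetic census generator
#'
#' Bundles everything [generate_cohort()] needs to emulate the field
#' census: number of litters, litter-size distribution, birth sex ratio,
#' habitat mix, whelping window and the hazard schedule driving monthly
#' removals. Defaults reproduce the study conditions: 95 litters, the
#' calibrated litter-size distribution (mean 3.98), an unbiased birth sex
#' ratio, the observed urban share (150/364), births spread over
#' October-February (study days 0-149) and [default_hazard_schedule()].
#'
#' @param n_litters Positive integer number of litters.
#' @param litter_size_pmf Named probability vector over litter sizes 1..12.
#' @param sex_prob_female Probability a pup is female at birth.
#' @param habitat_mix Probability a litter is in urban (vs suburban)
#'   habitat.
#' @param birth_window Integer vector `c(first, last)` of study days over
#'   which litter birth days are uniform.
#' @param schedule A `hazard_schedule`.
#' @param seed Integer seed; one seed drives the whole generation.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_litters = 95L,
                             litter_size_pmf = litter_size_default_pmf(),
                             sex_prob_female = 0.5,
                             habitat_mix = 150 / 364,
                             birth_window = c(0L, 149L),
                             schedule = default_hazard_schedule(),
                             seed = 1L) {
  stopifnot(length(n_litters) == 1L, n_litters >= 1,
            n_litters == floor(n_litters))
  if (abs(sum(litter_size_pmf) - 1) > 1e-8 || any(litter_size_pmf < 0)) {
    stop_pupsurv("litter_size_pmf must be a probability vector",
                 class = "pupsurv_config_error")
  }
  if (is.null(names(litter_size_pmf))) {
    names(litter_size_pmf) <- seq_along(litter_size_pmf)
  }
  stopifnot(sex_prob_female >= 0, sex_prob_female <= 1,
            habitat_mix >= 0, habitat_mix <= 1,
            length(birth_window) == 2L, birth_window[1] <= birth_window[2])
  if (!inherits(schedule, "hazard_schedule")) {
    stop_pupsurv("schedule must be a hazard_schedule",
                 class = "pupsurv_config_error")
  }
  structure(
    list(n_litters = as.integer(n_litters),
         litter_size_pmf = litter_size_pmf,
         sex_prob_female = sex_prob_female,
         habitat_mix = habitat_mix,
         birth_window = as.integer(birth_window),
         schedule = schedule,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a synthetic pup cohort
#'
#' Draws litters (size from the configured distribution, birth day uniform
#' on the whelping window, habitat Bernoulli), assigns pup sexes, then
#' simulates each pup's life month class by month class: in class `m` a
#' pup alive at its start is removed by cause `c` with probability
#' `h[c, sex, habitat, m]` (a single categorical draw per pup-month,
#' "survive this class" taking the remaining probability). A removed pup's
#' exit day is uniform over the 30 days of its removal class; pups that
#' survive all seven classes are censored at day 210. The whole draw is a
#' deterministic function of `config$seed`, and the caller's RNG state is
#' left untouched.
#'
#' @param config A [generator_config()].
#' @return A validated `pup_cohort`.
#' @examples
#' coh <- generate_cohort(generator_config(n_litters = 10, seed = 42))
#' coh
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  # hazard_schedule() has already rejected infeasible schedules, but a
  # schedule mutated after construction must still fail before any draw
  tot <- apply(config$schedule$h, c(2, 3, 4), sum)
  if (any(tot > 1 + 1e-12)) {
    stop_pupsurv("infeasible schedule: cause hazards sum to > 1",
                 class = "pupsurv_schedule_error")
  }
  with_seed(config$seed, {
    nl <- config$n_litters
    sizes <- sample(as.integer(names(config$litter_size_pmf)), nl,
                    replace = TRUE, prob = config$litter_size_pmf)
    birth <- sample(config$birth_window[1]:config$birth_window[2], nl,
                    replace = TRUE)
    habitat <- ifelse(runif(nl) < config$habitat_mix, "urban", "suburban")
    n <- sum(sizes)
    litter_idx <- rep(seq_len(nl), sizes)
    sex <- ifelse(runif(n) < config$sex_prob_female, "female", "male")

    exit_age <- rep(210L, n)
    exit_code <- rep(0L, n)
    alive <- rep(TRUE, n)
    sex_i <- ifelse(sex == "female", 1L, 2L)
    hab_i <- ifelse(habitat[litter_idx] == "urban", 1L, 2L)
    for (m in 0:6) {
      idx <- which(alive)
      if (length(idx) == 0L) break
      # per-pup cause probabilities for this month class (4 strata only)
      P <- matrix(0, length(idx), 5)
      for (s in 1:2) {
        for (b in 1:2) {
          sel <- sex_i[idx] == s & hab_i[idx] == b
          if (any(sel)) {
            P[sel, ] <- matrix(config$schedule$h[, s, b, m + 1L],
                               sum(sel), 5, byrow = TRUE)
          }
        }
      }
      cum <- P
      for (j in 2:5) cum[, j] <- cum[, j - 1L] + P[, j]
      u <- runif(length(idx))
      drawn <- rowSums(u > cum) + 1L     # 1..5 = cause, 6 = survives class
      removed <- drawn <= 5L
      if (any(removed)) {
        who <- idx[removed]
        exit_code[who] <- drawn[removed]
        exit_age[who] <- 30L * m +
          sample(0:29, length(who), replace = TRUE)
        alive[who] <- FALSE
      }
    }
    records <- data.frame(
      pup_id = sprintf("P%05d", seq_len(n)),
      litter_id = sprintf("L%04d", litter_idx),
      sex = sex,
      habitat = habitat[litter_idx],
      birth_day = birth[litter_idx],
      exit_age_days = exit_age,
      exit_category = cause_label(exit_code),
      stringsAsFactors = FALSE
    )
    out <- as_cohort(records)
    attr(out, "seed") <- config$seed
    out
  })
}
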
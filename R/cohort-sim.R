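#' Configuration for the sex-biased-removal cohort projection
#'
#' Sets up the discrete-time projection of a pup cohort under two hazard
#' streams: a sex-specific monthly probability of being taken by humans
#' and a sex-neutral monthly probability of removal by all other causes
#' combined.
#'
#' @param n_initial Initial cohort size (default 1000; must be even in
#'   the default 1:1 configuration so both sexes get whole counts).
#' @param initial_female_fraction Fraction female at month 0.
#' @param taken_hazard 2 x 7 matrix (rows `female`, `male`) of monthly
#'   taken-by-human probabilities.
#' @param other_hazard Length-7 vector of monthly all-other-cause
#'   probabilities, applied to both sexes.
#' @param mode `"expectation"` for the deterministic recursion on
#'   expected (fractional) survivors, `"stochastic"` for per-month
#'   binomial draws.
#' @param n_replicates Number of stochastic replicates.
#' @param seed Seed for stochastic mode.
#' @return List of class `sim_config`.
#' @seealso [run_cohort_sim()], [default_sim_scenario()]
#' @export
sim_config <- function(n_initial = 1000L, initial_female_fraction = 0.5,
                       taken_hazard, other_hazard,
                       mode = c("expectation", "stochastic"),
                       n_replicates = 500L, seed = 1L) {
  mode <- match.arg(mode)
  taken_hazard <- as.matrix(taken_hazard)
  if (!identical(dim(taken_hazard), c(2L, 7L))) {
    stop_pupsurv("taken_hazard must be a 2 x 7 matrix (female/male x ",
                 "month)", class = "pupsurv_config_error")
  }
  rownames(taken_hazard) <- c("female", "male")
  other_hazard <- as.numeric(other_hazard)
  if (length(other_hazard) != 7L) {
    stop_pupsurv("other_hazard must have one entry per month class (7)",
                 class = "pupsurv_config_error")
  }
  if (any(taken_hazard < 0) || any(taken_hazard > 1) ||
      any(other_hazard < 0) || any(other_hazard > 1)) {
    stop_pupsurv("hazards must lie in [0, 1]",
                 class = "pupsurv_config_error")
  }
  tot <- sweep(taken_hazard, 2, other_hazard, "+")
  if (any(tot > 1 + 1e-12)) {
    stop_pupsurv("taken + other hazard exceeds 1 for some sex/month",
                 class = "pupsurv_config_error")
  }
  stopifnot(n_initial >= 2, initial_female_fraction >= 0,
            initial_female_fraction <= 1)
  structure(
    list(n_initial = as.integer(n_initial),
         initial_female_fraction = initial_female_fraction,
         taken_hazard = taken_hazard, other_hazard = other_hazard,
         mode = mode, n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' The calibrated selective-removal scenario
#'
#' Builds the [sim_config()] implied by a hazard schedule: the taken
#' hazards are the schedule's sex-specific taken-by-human probabilities
#' and the other-cause hazard is the (sex-neutral) sum of the remaining
#' four causes. Under [default_hazard_schedule()] this is the scenario
#' the census tables imply: an initial population of 1000 pups at a 1:1
#' sex ratio exposed to male-biased removal by humans and sex-neutral
#' mortality otherwise.
#'
#' @param schedule A `hazard_schedule`.
#' @param habitat Habitat stratum of the schedule to use.
#' @param mode,n_replicates,seed Passed to [sim_config()].
#' @return A `sim_config`.
#' @export
default_sim_scenario <- function(schedule = default_hazard_schedule(),
                                 habitat = "urban",
                                 mode = "expectation",
                                 n_replicates = 500L, seed = 1L) {
  stopifnot(inherits(schedule, "hazard_schedule"))
  taken <- rbind(female = schedule$h[2, "female", habitat, ],
                 male = schedule$h[2, "male", habitat, ])
  other_f <- colSums(schedule$h[-2, "female", habitat, ])
  other_m <- colSums(schedule$h[-2, "male", habitat, ])
  if (max(abs(other_f - other_m)) > 1e-10) {
    warning("non-taken hazards differ between sexes; using the female ",
            "profile as the sex-neutral other-cause hazard")
  }
  sim_config(n_initial = 1000L, initial_female_fraction = 0.5,
             taken_hazard = taken, other_hazard = other_f,
             mode = mode, n_replicates = n_replicates, seed = seed)
}

#' Run the cohort projection
#'
#' Expectation mode iterates the exact recursion
#' `survivors_s(m + 1) = survivors_s(m) (1 - taken_s(m) - other(m))` on
#' fractional expected counts. Stochastic mode draws, for each month and
#' sex, the number taken and the number removed by other causes from the
#' corresponding binomials (a categorical draw per individual),
#' replicated `n_replicates` times under the configured seed. The final
#' ratio is female survivors per male survivor at month 7; extinction of
#' males yields an infinite, flagged ratio rather than an error.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_result`: `survivors` (2 x 8 matrix of
#'   counts at months 0..7; in stochastic mode the replicate mean),
#'   `final_ratio_f_per_m`, `mode`, `degenerate` (no survivors of either
#'   sex), and in stochastic mode `replicate_ratios` and
#'   `replicate_final` (per-replicate survivor counts).
#' @examples
#' sc <- default_sim_scenario()
#' run_cohort_sim(sc)
#' @export
run_cohort_sim <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_f0 <- config$n_initial * config$initial_female_fraction
  n_m0 <- config$n_initial - n_f0
  months <- 0:7
  if (config$mode == "expectation") {
    surv <- matrix(0, 2, 8, dimnames = list(sex = c("female", "male"),
                                            month = months))
    surv[, 1] <- c(n_f0, n_m0)
    for (m in 1:7) {
      keep <- 1 - config$taken_hazard[, m] - config$other_hazard[m]
      surv[, m + 1] <- surv[, m] * keep
    }
    f7 <- surv["female", 8]; m7 <- surv["male", 8]
    structure(
      list(survivors = surv,
           final_ratio_f_per_m = if (m7 > 0) f7 / m7 else Inf,
           mode = "expectation",
           degenerate = f7 <= 0 && m7 <= 0),
      class = "sim_result"
    )
  } else {
    with_seed(config$seed, {
      reps <- config$n_replicates
      traj <- array(0, dim = c(reps, 2, 8))
      for (r in seq_len(reps)) {
        alive <- c(female = round(n_f0), male = round(n_m0))
        traj[r, , 1] <- alive
        for (m in 1:7) {
          for (s in 1:2) {
            pt <- config$taken_hazard[s, m]
            po <- config$other_hazard[m]
            n_taken <- rbinom(1, alive[s], pt)
            rest <- alive[s] - n_taken
            n_other <- if (pt < 1) rbinom(1, rest, po / (1 - pt)) else 0L
            alive[s] <- rest - n_other
          }
          traj[r, , m + 1] <- alive
        }
      }
      f7 <- traj[, 1, 8]; m7 <- traj[, 2, 8]
      ratios <- ifelse(m7 > 0, f7 / m7, Inf)
      surv <- apply(traj, c(2, 3), mean)
      dimnames(surv) <- list(sex = c("female", "male"), month = months)
      structure(
        list(survivors = surv,
             final_ratio_f_per_m = mean(ratios[is.finite(ratios)]),
             mode = "stochastic",
             degenerate = all(f7 + m7 == 0),
             replicate_ratios = ratios,
             replicate_final = cbind(female = f7, male = m7)),
        class = "sim_result"
      )
    })
  }
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Cohort projection (%s mode)\n", x$mode))
  print(round(x$survivors, 1))
  cat(sprintf("final survivor sex ratio (female per male): %.3f\n",
              x$final_ratio_f_per_m))
  invisible(x)
}

#' Compare a projection with an observed cohort
#'
#' Tabulates, per sex and month of age, the percentage of the initial
#' cohort surviving in the projection against the observed percentage in
#' a cohort of records, and reports the observed final survivor sex
#' ratio (category-0 counts).
#'
#' @param result A `sim_result`.
#' @param records A `pup_cohort` or validated records data frame; pups of
#'   unknown sex are excluded.
#' @return List with `table` (data frame: `sex`, `month`,
#'   `observed_pct`, `simulated_pct`, `diff`) and
#'   `observed_final_ratio_f_per_m`.
#' @export
compare_sim_to_observed <- function(result, records) {
  stopifnot(inherits(result, "sim_result"))
  r <- if (inherits(records, "pup_cohort")) records$records else
    validate_records(records)
  r <- r[r$sex != "unknown", ]
  rows <- list()
  for (s in c("female", "male")) {
    rs <- r[r$sex == s, ]
    n0 <- nrow(rs)
    for (m in 0:7) {
      obs <- if (n0 > 0) 100 * sum(rs$exit_age_days >= 30 * m) / n0 else NA
      sim <- 100 * result$survivors[s, m + 1] /
        result$survivors[s, 1]
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, month = m, observed_pct = obs, simulated_pct = sim,
        diff = sim - obs)
    }
  }
  n_surv <- c(female = sum(r$sex == "female" & r$censored),
              male = sum(r$sex == "male" & r$censored))
  list(table = do.call(rbind, rows),
       observed_final_ratio_f_per_m =
         if (n_surv["male"] > 0) unname(n_surv["female"] / n_surv["male"])
         else Inf)
}
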
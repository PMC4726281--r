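#' Configuration for the end-to-end analysis pipeline
#'
#' @param source Either `list(type = "synthetic", config =
#'   generator_config(...))` or `list(type = "csv", path = "cohort.csv")`.
#' @param analyses Character subset of `c("demography", "km", "cox",
#'   "cif", "gray", "tables", "sim")`; at least one. The shorthand
#'   `"reproduce"` selects all of them.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed recorded in every output's metadata header
#'   and used for any stochastic stage.
#' @param log_level `"info"` or `"quiet"`.
#' @return List of class `pipeline_config`.
#' @seealso [run_pipeline()]
#' @export
pipeline_config <- function(source = list(type = "synthetic",
                                          config = generator_config()),
                            analyses = "reproduce",
                            outdir = tempfile("pupsurv_run_"),
                            seed = 1L,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  all_stages <- c("demography", "km", "cox", "cif", "gray", "tables",
                  "sim")
  if (identical(analyses, "reproduce")) analyses <- all_stages
  analyses <- unique(analyses)
  if (length(analyses) == 0L || !all(analyses %in% all_stages)) {
    stop_pupsurv("analyses must be a non-empty subset of: ",
                 paste(all_stages, collapse = ", "),
                 class = "pupsurv_config_error")
  }
  if (!is.list(source) || !source$type %in% c("synthetic", "csv")) {
    stop_pupsurv("source$type must be 'synthetic' or 'csv'",
                 class = "pupsurv_config_error")
  }
  structure(
    list(source = source, analyses = analyses, outdir = outdir,
         seed = as.integer(seed), log_level = log_level),
    class = "pipeline_config"
  )
}

# every machine-readable output carries the same provenance header
write_report <- function(df, path, meta) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# pupsurv ", meta$version),
    paste0("# seed: ", meta$seed),
    paste0("# config_hash: ", meta$hash)
  ), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  path
}

pipeline_log <- function(config, ...) {
  if (config$log_level != "quiet") {
    message("[pupsurv] ", ...)
  }
}

#' Run the full cohort analysis pipeline
#'
#' Obtains a cohort (generating a synthetic census or reading a CSV),
#' runs the selected analysis stages in dependency order and writes one
#' CSV report per stage plus a summary of the headline statistics
#' (survivor percentage, survival medians, log-rank and Gray statistics,
#' the projected survivor sex ratio) to `config$outdir`. Every output
#' carries a metadata header (package version, seed, configuration
#' hash); a `MANIFEST` lists the files written, or the failure point if a
#' stage errors (partial outputs are retained and the error re-raised).
#' Runs are idempotent for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the cohort, the per-stage results and
#'   the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    version = as.character(packageVersion("pupsurv")),
    seed = config$seed,
    hash = config_hash(config[c("source", "analyses", "seed")])
  )
  manifest <- character(0)
  outputs <- list()
  results <- list()
  summary_rows <- list()
  note <- function(stat, value) {
    summary_rows[[length(summary_rows) + 1L]] <<- data.frame(
      statistic = stat, value = value, stringsAsFactors = FALSE)
  }
  emit <- function(name, df) {
    path <- file.path(config$outdir, paste0(name, ".csv"))
    write_report(df, path, meta)
    manifest <<- c(manifest, paste0(name, ".csv"))
    outputs[[name]] <<- path
  }
  fail_stage <- NULL
  run_stage <- function(name, fn) {
    if (!is.null(fail_stage)) return()
    pipeline_log(config, "stage: ", name)
    tryCatch(fn(), error = function(e) {
      fail_stage <<- list(stage = name, message = conditionMessage(e))
    })
  }

  # --- input -------------------------------------------------------------
  cohort <- NULL
  run_stage("input", function() {
    cohort <<- if (config$source$type == "synthetic") {
      gc <- config$source$config
      gc$seed <- config$seed  # the pipeline seed governs generation
      generate_cohort(gc)
    } else {
      read_cohort(config$source$path)
    }
    emit("cohort", cohort$records[cohort_columns()])
    note("n_pups", nrow(cohort$records))
    note("n_litters", nrow(cohort$litters))
    surv_pct <- 100 * mean(cohort$records$censored)
    note("pct_surviving_210d", surv_pct)
  })

  sexed <- function() {
    r <- cohort$records
    r[r$sex != "unknown", ]
  }

  if ("demography" %in% config$analyses) run_stage("demography", function() {
    ls <- litter_summary(cohort)
    r <- cohort$records
    lt <- cohort$litters
    mw <- mann_whitney_u(lt$n_female, lt$n_male)
    net <- monthly_net_counts(cohort)
    alive <- survivors_by_age(cohort)
    keep <- alive$alive > 0
    logfit <- ols_fit(alive$month[keep], log10(alive$alive[keep]))
    results$demography <<- list(litters = ls, sex_ratio_test = mw,
                                net_counts = net,
                                log_survival_fit = logfit)
    emit("net_counts", net)
    emit("survivors_by_age", alive)
    emit("demography", data.frame(
      statistic = c("litter_mean", "litter_sd", "litter_median",
                    "litter_q1", "litter_q3", "n_litters",
                    "sex_ratio_U", "sex_ratio_p",
                    "log_survival_slope", "log_survival_r2",
                    "log_survival_std_beta", "log_survival_p"),
      value = c(ls$mean, ls$sd, ls$median, ls$q1, ls$q3, ls$n,
                mw$U, mw$p_two_sided,
                logfit$slope, logfit$r_squared, logfit$std_beta,
                logfit$p_slope)))
    note("litter_size_mean", ls$mean)
    note("sex_ratio_U", mw$U)
    note("log_survival_r2", logfit$r_squared)
  })

  if ("km" %in% config$analyses) run_stage("km", function() {
    r <- cohort$records
    overall <- km_fit(r$exit_age_days, !r$censored)
    med <- km_median_ci(overall)
    rs <- sexed()
    strata <- list(overall = overall)
    curves <- cbind(group = "overall", as.data.frame(overall))
    med_rows <- data.frame(group = "overall",
                           median_days = med$median_days,
                           lo = med$lo, hi = med$hi)
    for (split in list(c("sex", "female"), c("sex", "male"),
                       c("habitat", "urban"), c("habitat", "suburban"))) {
      rr <- if (split[1] == "sex") rs[rs$sex == split[2], ] else
        r[r$habitat == split[2], ]
      if (nrow(rr) == 0L) next
      cv <- km_fit(rr$exit_age_days, !rr$censored)
      md <- km_median_ci(cv)
      strata[[split[2]]] <- cv
      curves <- rbind(curves, cbind(group = split[2],
                                    as.data.frame(cv)))
      med_rows <- rbind(med_rows, data.frame(
        group = split[2], median_days = md$median_days,
        lo = md$lo, hi = md$hi))
    }
    lr_sex <- logrank_test(
      rs$exit_age_days[rs$sex == "female"], !rs$censored[rs$sex == "female"],
      rs$exit_age_days[rs$sex == "male"], !rs$censored[rs$sex == "male"])
    lr_hab <- logrank_test(
      r$exit_age_days[r$habitat == "urban"],
      !r$censored[r$habitat == "urban"],
      r$exit_age_days[r$habitat == "suburban"],
      !r$censored[r$habitat == "suburban"])
    results$km <<- list(curves = strata, medians = med_rows,
                        logrank_sex = lr_sex, logrank_habitat = lr_hab)
    emit("km_curves", curves)
    emit("km_medians", med_rows)
    emit("km_logrank", data.frame(
      comparison = c("female_vs_male", "urban_vs_suburban"),
      chisq = c(lr_sex$chisq, lr_hab$chisq),
      df = 1L, p = c(lr_sex$p, lr_hab$p)))
    note("median_days_overall", med$median_days)
    note("logrank_sex_chisq", lr_sex$chisq)
    note("logrank_habitat_chisq", lr_hab$chisq)
  })

  if ("cox" %in% config$analyses) run_stage("cox", function() {
    frame <- cohort_cox_frame(cohort)
    fit <- cox_fit(frame$duration, frame$event,
                   frame[, c("litter_size", "sex_male", "habitat_urban")])
    lrt <- cox_lrt(fit)
    z <- fit$coefficients / fit$se
    tab <- data.frame(term = names(fit$coefficients),
                      coef = unname(fit$coefficients),
                      se = unname(fit$se), z = unname(z),
                      p = unname(2 * pnorm(-abs(z))))
    tab <- rbind(tab, data.frame(term = "model_LRT", coef = lrt$chisq,
                                 se = NA, z = NA, p = lrt$p))
    results$cox <<- list(fit = fit, lrt = lrt)
    emit("cox", tab)
    note("cox_lrt_chisq", lrt$chisq)
  })

  if ("cif" %in% config$analyses) run_stage("cif", function() {
    r <- cohort$records
    inc <- cif_estimate(r$exit_age_days, r$exit_code)
    df <- data.frame(time = inc$times, t(inc$cif),
                     overall_survival = inc$overall_survival)
    names(df) <- c("time", paste0("cif_", cause_label(1:5)),
                   "overall_survival")
    results$cif <<- inc
    emit("cif", df)
  })

  if ("gray" %in% config$analyses) run_stage("gray", function() {
    rs <- sexed()
    rows <- lapply(1:5, function(code) {
      if (!any(rs$exit_code == code)) {
        return(data.frame(category = code, statistic = NA_real_,
                          df = 1L, p = NA_real_, note = "cause absent"))
      }
      g <- gray_test(rs$exit_age_days, rs$exit_code, rs$sex, code)
      data.frame(category = code, statistic = g$statistic, df = 1L,
                 p = g$p, note = "")
    })
    tab <- do.call(rbind, rows)
    results$gray <<- tab
    emit("gray", tab)
    if (!is.na(tab$statistic[2])) note("gray_taken_chisq", tab$statistic[2])
  })

  if ("tables" %in% config$analyses) run_stage("tables", function() {
    tabs <- cause_tables(cohort)
    results$tables <<- tabs
    emit("table_age_classes", tabs$by_age)
    emit("table_sex_categories",
         cbind(sex = rownames(tabs$by_sex),
               as.data.frame(tabs$by_sex, check.names = FALSE)))
  })

  if ("sim" %in% config$analyses) run_stage("sim", function() {
    scenario <- default_sim_scenario(seed = config$seed)
    res <- run_cohort_sim(scenario)
    cmp <- compare_sim_to_observed(res, cohort)
    results$sim <<- list(result = res, comparison = cmp)
    surv <- res$survivors
    emit("sim", data.frame(
      sex = rep(rownames(surv), each = ncol(surv)),
      month = rep(0:7, times = 2),
      survivors = c(t(surv)),
      percent = c(t(100 * surv / surv[, 1]))))
    emit("sim_vs_observed", cmp$table)
    note("sim_final_ratio_f_per_m", res$final_ratio_f_per_m)
    note("observed_final_ratio_f_per_m",
         cmp$observed_final_ratio_f_per_m)
  })

  # --- summary and manifest ---------------------------------------------
  if (is.null(fail_stage)) {
    emit("summary", do.call(rbind, summary_rows))
  }
  manifest_lines <- c(
    paste0("pupsurv ", meta$version),
    paste0("seed: ", meta$seed),
    paste0("config_hash: ", meta$hash),
    paste0("status: ", if (is.null(fail_stage)) "complete" else
      paste0("FAILED at stage '", fail_stage$stage, "': ",
             fail_stage$message)),
    "files:",
    paste0("  ", manifest)
  )
  writeLines(manifest_lines, file.path(config$outdir, "MANIFEST"))
  if (!is.null(fail_stage)) {
    stop_pupsurv("pipeline failed at stage '", fail_stage$stage, "': ",
                 fail_stage$message, class = "pupsurv_pipeline_error")
  }
  pipeline_log(config, "complete: ", config$outdir)
  invisible(list(cohort = cohort, results = results, outputs = outputs,
                 outdir = config$outdir, meta = meta))
}
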
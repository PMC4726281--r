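#' Build a validated cohort object from individual records
#'
#' A cohort bundles one row per tracked pup with the litter table
#' reconstructed by grouping on `litter_id`. Records are validated against
#' the data-model invariants: exit ages in `[0, 210]`; a pup is censored
#' (still alive at the horizon) if and only if its exit category is
#' `survived`, if and only if its exit age is exactly 210 days.
#'
#' @param records Data frame with columns `pup_id`, `litter_id`, `sex`
#'   (`female`/`male`/`unknown`), `habitat` (`urban`/`suburban`),
#'   `birth_day` (integer day on the study timeline, day 0 = 1 October),
#'   `exit_age_days` (integer, 0-210) and `exit_category` (canonical cause
#'   label or integer code 0-5).
#' @return An object of class `pup_cohort`: a list with elements `records`
#'   (the validated data frame, plus derived columns `exit_code` and
#'   `censored`) and `litters` (one row per litter: `litter_id`,
#'   `size_at_birth`, `n_female`, `n_male`, `n_unknown_sex`, `birth_day`,
#'   `habitat`).
#' @seealso [read_cohort()], [write_cohort()], [generate_cohort()]
#' @export
as_cohort <- function(records) {
  records <- validate_records(records)
  structure(
    list(records = records, litters = litters_from_records(records)),
    class = "pup_cohort"
  )
}

cohort_columns <- function() {
  c("pup_id", "litter_id", "sex", "habitat", "birth_day",
    "exit_age_days", "exit_category")
}

validate_records <- function(records) {
  if (!is.data.frame(records)) {
    stop_pupsurv("records must be a data frame",
                 class = "pupsurv_schema_error")
  }
  missing_cols <- setdiff(cohort_columns(), names(records))
  if (length(missing_cols) > 0L) {
    stop_pupsurv("missing required column(s): ",
                 paste(missing_cols, collapse = ", "),
                 class = "pupsurv_schema_error")
  }
  records <- records[cohort_columns()]
  if (nrow(records) == 0L) {
    records$exit_code <- integer(0)
    records$censored <- logical(0)
    return(records)
  }
  records$pup_id <- as.character(records$pup_id)
  records$litter_id <- as.character(records$litter_id)
  records$sex <- as.character(records$sex)
  records$habitat <- as.character(records$habitat)

  bad_sex <- !records$sex %in% c("female", "male", "unknown")
  if (any(bad_sex)) {
    stop_pupsurv("invalid sex for pup_id: ",
                 paste(records$pup_id[bad_sex], collapse = ", "),
                 " (expected female/male/unknown)",
                 class = "pupsurv_validation_error")
  }
  bad_hab <- !records$habitat %in% c("urban", "suburban")
  if (any(bad_hab)) {
    stop_pupsurv("invalid habitat for pup_id: ",
                 paste(records$pup_id[bad_hab], collapse = ", "),
                 " (expected urban/suburban)",
                 class = "pupsurv_validation_error")
  }
  for (col in c("birth_day", "exit_age_days")) {
    v <- records[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v != floor(v))) {
      stop_pupsurv(col, " must be integer-valued and non-missing",
                   class = "pupsurv_validation_error")
    }
    records[[col]] <- as.integer(v)
  }
  out_of_range <- records$exit_age_days < 0L | records$exit_age_days > 210L
  if (any(out_of_range)) {
    stop_pupsurv("exit_age_days outside [0, 210] for pup_id: ",
                 paste(records$pup_id[out_of_range], collapse = ", "),
                 class = "pupsurv_validation_error")
  }
  # exit_category may arrive as label or as integer code
  if (is.numeric(records$exit_category)) {
    records$exit_code <- as.integer(records$exit_category)
    if (any(!records$exit_code %in% 0:5)) {
      stop_pupsurv("exit_category codes must lie in 0..5",
                   class = "pupsurv_validation_error")
    }
    records$exit_category <- cause_label(records$exit_code)
  } else {
    records$exit_category <- as.character(records$exit_category)
    records$exit_code <- cause_code(records$exit_category)
  }
  records$censored <- records$exit_code == 0L
  # censored <=> survived <=> exit at exactly the 210-day horizon
  inconsistent <- (records$censored & records$exit_age_days != 210L) |
    (!records$censored & records$exit_age_days == 210L)
  if (any(inconsistent)) {
    stop_pupsurv(
      "censoring invariant violated (survived <=> exit_age_days == 210) ",
      "for pup_id: ", paste(records$pup_id[inconsistent], collapse = ", "),
      class = "pupsurv_validation_error")
  }
  if (anyDuplicated(records$pup_id)) {
    dup <- unique(records$pup_id[duplicated(records$pup_id)])
    stop_pupsurv("duplicated pup_id: ", paste(dup, collapse = ", "),
                 class = "pupsurv_validation_error")
  }
  rownames(records) <- NULL
  records
}

litters_from_records <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(litter_id = character(0), size_at_birth = integer(0),
                      n_female = integer(0), n_male = integer(0),
                      n_unknown_sex = integer(0), birth_day = integer(0),
                      habitat = character(0), stringsAsFactors = FALSE))
  }
  lid <- factor(records$litter_id, levels = unique(records$litter_id))
  n_bday <- tapply(records$birth_day, lid, function(v) length(unique(v)))
  n_hab <- tapply(records$habitat, lid, function(v) length(unique(v)))
  bad <- n_bday != 1L | n_hab != 1L
  if (any(bad)) {
    stop_pupsurv("litter(s) ", paste(levels(lid)[bad], collapse = ", "),
                 " have inconsistent birth_day or habitat across pups",
                 class = "pupsurv_validation_error")
  }
  out <- data.frame(
    litter_id = levels(lid),
    size_at_birth = as.integer(tabulate(lid)),
    n_female = as.integer(tapply(records$sex == "female", lid, sum)),
    n_male = as.integer(tapply(records$sex == "male", lid, sum)),
    n_unknown_sex = as.integer(tapply(records$sex == "unknown", lid, sum)),
    birth_day = as.integer(tapply(records$birth_day, lid, `[`, 1L)),
    habitat = as.character(tapply(records$habitat, lid, `[`, 1L)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read a cohort CSV
#'
#' Reads an individual-level cohort file (UTF-8, comma-separated, header
#' required; one row per pup) and returns a validated [as_cohort()] object.
#' Dates are integer day indices on the study timeline, never calendar
#' strings, to avoid locale ambiguity.
#'
#' @param path Path to a CSV file with the columns listed in [as_cohort()].
#' @return A `pup_cohort` object.
#' @examples
#' coh <- generate_cohort(generator_config(n_litters = 5, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_cohort(coh, f)
#' coh2 <- read_cohort(f)
#' identical(coh$records, coh2$records)
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop_pupsurv("cohort file not found: ", path,
                 class = "pupsurv_io_error")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character", comment.char = "#")
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols) > 0L) {
    stop_pupsurv("missing required column(s): ",
                 paste(missing_cols, collapse = ", "),
                 class = "pupsurv_schema_error")
  }
  raw <- raw[cohort_columns()]
  for (col in c("birth_day", "exit_age_days")) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(parsed) | parsed != floor(parsed)
    if (any(bad)) {
      # +1 for the header row: report 1-based file line numbers
      stop_pupsurv("unparseable ", col, " at line(s) ",
                   paste(which(bad) + 1L, collapse = ", "), " of ", path,
                   class = "pupsurv_parse_error")
    }
    raw[[col]] <- as.integer(parsed)
  }
  as_cohort(raw)
}

#' Write a cohort CSV
#'
#' Emits exactly the schema read by [read_cohort()], so that
#' `read_cohort(write_cohort(x, f))` is the identity on validated cohorts.
#'
#' @param cohort A `pup_cohort` object or a records data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  records <- if (inherits(cohort, "pup_cohort")) cohort$records else
    validate_records(cohort)
  write.csv(records[cohort_columns()], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @export
print.pup_cohort <- function(x, ...) {
  r <- x$records
  cat("Free-ranging dog pup cohort\n")
  cat(sprintf("  %d pups in %d litters\n", nrow(r), nrow(x$litters)))
  if (nrow(r) > 0L) {
    cat(sprintf("  sex: %d female / %d male / %d unknown\n",
                sum(r$sex == "female"), sum(r$sex == "male"),
                sum(r$sex == "unknown")))
    cat(sprintf("  habitat: %d urban / %d suburban\n",
                sum(r$habitat == "urban"), sum(r$habitat == "suburban")))
    cat(sprintf("  survived to 210 d: %d (%.1f%%)\n",
                sum(r$censored), 100 * mean(r$censored)))
  }
  invisible(x)
}
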
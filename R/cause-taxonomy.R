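#' Mortality-cause taxonomy for free-ranging dog pups
#'
#' Every exit from the cohort is classified into one of six categories.
#' Code 0 marks pups still alive at the 210-day horizon (right-censored);
#' codes 1-5 are the mutually exclusive removal causes used throughout the
#' competing-risks analyses: natural death, taken by humans, murdered by
#' humans, death in a road accident, and no information (which pools
#' "missing" and "unknown" records).
#'
#' @return A data frame with columns `code` (integer 0-5), `label`
#'   (canonical category name) and `aggregate` (the coarse class used for
#'   age-class mortality tables: `survived`, `natural`, `human_influenced`
#'   or `missing_or_unknown`).
#' @examples
#' cause_categories()
#' @export
cause_categories <- function() {
  data.frame(
    code = 0:5,
    label = c("survived", "natural_death", "taken_by_human",
              "murdered_by_human", "road_accident", "no_information"),
    aggregate = c("survived", "natural", "human_influenced",
                  "human_influenced", "human_influenced",
                  "missing_or_unknown"),
    stringsAsFactors = FALSE
  )
}

#' Convert between cause codes and labels
#'
#' @param label Character vector of canonical category labels.
#' @param code Integer vector of category codes in 0-5.
#' @return `cause_code()` returns the integer code(s); `cause_label()` the
#'   canonical label(s); `aggregate_cause()` the coarse class of each code.
#' @examples
#' cause_code("road_accident")
#' cause_label(2)
#' aggregate_cause(4)
#' @export
cause_code <- function(label) {
  tab <- cause_categories()
  idx <- match(label, tab$label)
  if (anyNA(idx)) {
    stop_pupsurv("unknown cause label(s): ",
                 paste(unique(label[is.na(idx)]), collapse = ", "),
                 "; expected one of: ", paste(tab$label, collapse = ", "),
                 class = "pupsurv_taxonomy_error")
  }
  tab$code[idx]
}

#' @rdname cause_code
#' @export
cause_label <- function(code) {
  tab <- cause_categories()
  idx <- match(as.integer(code), tab$code)
  if (anyNA(idx)) {
    stop_pupsurv("cause codes must lie in 0..5",
                 class = "pupsurv_taxonomy_error")
  }
  tab$label[idx]
}

#' @rdname cause_code
#' @export
aggregate_cause <- function(code) {
  tab <- cause_categories()
  tab$aggregate[match(as.integer(code), tab$code)]
}

# controlled vocabulary of raw field-record strings, lowercased
raw_cause_vocabulary <- function() {
  list(
    survived = c("survived", "alive", "censored"),
    natural_death = c("natural death", "natural", "disease", "sick",
                      "climatic factors", "climate", "cold", "predation",
                      "predation by dogs", "predation by jackals",
                      "injury from fight", "fight injury", "fight"),
    taken_by_human = c("taken by human", "taken by humans", "taken",
                       "taken away", "adopted", "carried away"),
    murdered_by_human = c("murdered by human", "murdered by humans",
                          "murdered", "poisoning", "poisoned", "beating",
                          "beaten", "killed by human", "malnutrition"),
    road_accident = c("road accident", "death in road accident",
                      "road", "run over", "vehicle", "vehicle accident",
                      "hit by car"),
    no_information = c("no information", "missing", "unknown",
                       "disappeared", "gone missing", "lost")
  )
}

#' Classify a raw field-record cause string
#'
#' Maps free-text cause-of-exit strings from census records onto the
#' controlled six-category taxonomy (case-insensitively). Pups taken by
#' humans are treated as removed from the population -- effectively dead,
#' since taken pups are usually abandoned and rarely return -- unless
#' `returned_to_group` is `TRUE` for that record, in which case the pup is
#' classified as surviving.
#'
#' @param raw_label Character vector of raw cause strings (non-empty).
#' @param returned_to_group Logical vector (recycled): was the pup seen to
#'   return to its natal group after being taken?
#' @return Data frame with one row per input and columns `code` and `label`.
#' @examples
#' classify_cause(c("road accident", "disease", "missing"))
#' classify_cause("taken by humans", returned_to_group = TRUE)
#' @export
classify_cause <- function(raw_label, returned_to_group = FALSE) {
  if (length(raw_label) == 0L || any(!nzchar(raw_label)) ||
      anyNA(raw_label)) {
    stop_pupsurv("raw cause labels must be non-empty strings",
                 class = "pupsurv_taxonomy_error")
  }
  returned_to_group <- rep_len(as.logical(returned_to_group),
                               length(raw_label))
  vocab <- raw_cause_vocabulary()
  key <- tolower(trimws(raw_label))
  label <- rep(NA_character_, length(key))
  for (canon in names(vocab)) {
    label[key %in% vocab[[canon]]] <- canon
  }
  if (anyNA(label)) {
    accepted <- paste(unlist(vocab), collapse = "', '")
    stop_pupsurv("unrecognized cause label(s): '",
                 paste(unique(raw_label[is.na(label)]), collapse = "', '"),
                 "'. Accepted vocabulary: '", accepted, "'",
                 class = "pupsurv_taxonomy_error")
  }
  # a taken pup seen to rejoin its natal group was never removed
  label[label == "taken_by_human" & returned_to_group] <- "survived"
  data.frame(code = cause_code(label), label = label,
             stringsAsFactors = FALSE)
}

#' Age class of an exit age
#'
#' Assigns an exit age in days to one of the seven 30-day age classes
#' (0-1 month, 1-2, ..., 6-7). Classes are the half-open bins
#' `[30m, 30(m+1))`; the horizon day 210 is clamped into the last class.
#'
#' @param exit_age_days Integer vector, each in `[0, 210]`.
#' @return Integer vector of month-class indices in 0..6.
#' @examples
#' age_class_of(c(0, 45, 209, 210))
#' @export
age_class_of <- function(exit_age_days) {
  x <- as.numeric(exit_age_days)
  if (anyNA(x) || any(x < 0 | x > 210) || any(x != floor(x))) {
    stop_pupsurv("exit_age_days must be integers in [0, 210]",
                 class = "pupsurv_validation_error")
  }
  pmin(x %/% 30, 6)
}

# row labels of the seven age classes, in table order
age_class_labels <- function() {
  paste0(0:6, "-", 1:7)
}
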
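# New-user cohort construction: washout-based index fills, sequential
# eligibility predicates, and an attrition (study-flow) report.

#' Eligibility criteria for a new-user cohort
#'
#' @param compared_classes Character vector (2-4 entries) of medication-class
#'   labels compared in the emulated trial.
#' @param washout_days Washout length in days (default 730 = 2 years): a fill
#'   qualifies as an index fill only if no compared-class dispensing occurred
#'   in the washout window before it.
#' @param exclusion_predicates Named list of functions. Each predicate is
#'   called with a data.frame of candidate index fills joined to patient
#'   baseline data (columns `patient_id`, `index_day`, `index_class`, plus
#'   all columns of the patient table) and must return a logical vector
#'   (`TRUE` = exclude). Predicates are applied in list order; each fill is
#'   counted against the first predicate that excludes it.
#' @return An object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(compared_classes, washout_days = 730L,
                                 exclusion_predicates = list()) {
  if (length(compared_classes) < 2L || length(compared_classes) > 4L ||
      anyDuplicated(compared_classes))
    stop("compared_classes must hold 2-4 distinct class labels")
  if (washout_days <= 0) stop("washout_days must be positive")
  if (length(exclusion_predicates)) {
    if (is.null(names(exclusion_predicates)) ||
        any(names(exclusion_predicates) == "") ||
        anyDuplicated(names(exclusion_predicates)))
      stop("exclusion_predicates must have unique non-empty labels")
    if (!all(vapply(exclusion_predicates, is.function, logical(1))))
      stop("exclusion_predicates must be functions")
  }
  structure(list(compared_classes = compared_classes,
                 washout_days = as.integer(washout_days),
                 exclusion_predicates = exclusion_predicates),
            class = "eligibility_criteria")
}

#' Identify new-user candidate index fills
#'
#' A fill of a compared class on day `d` qualifies when no other
#' compared-class dispensing (any class, including the same one) occurred in
#' the window `(d - washout_days, d]`: a fill exactly `washout_days` before
#' does not block, a same-day fill of another compared class does. At most
#' one candidate is kept per patient: the earliest qualifying fill.
#'
#' @param dispensings Dispensing table with `patient_id`, `med_class`,
#'   `dispense_day`.
#' @param criteria An [eligibility_criteria()] object.
#' @return `data.table` of candidate index fills with columns `patient_id`,
#'   `index_day`, `index_class`.
#' @export
identify_new_users <- function(dispensings, criteria) {
  stopifnot(inherits(criteria, "eligibility_criteria"))
  classes <- criteria$compared_classes
  if (!length(classes)) stop("compared_classes must be non-empty")
  d <- data.table::as.data.table(dispensings)
  d <- unique(d[med_class %in% classes,
                list(patient_id, med_class, day = as.integer(dispense_day))])
  if (nrow(d) == 0L)
    return(data.table::data.table(patient_id = character(),
                                  index_day = integer(),
                                  index_class = character()))
  data.table::setorder(d, patient_id, day, med_class)
  d[, n_same_day := .N, by = list(patient_id, day)]
  dd <- unique(d[, list(patient_id, day)])
  dd[, prev_day := data.table::shift(day), by = "patient_id"]
  d <- merge(d, dd, by = c("patient_id", "day"), sort = FALSE)
  d[, blocked := n_same_day > 1L |
      (!is.na(prev_day) & (day - prev_day) < criteria$washout_days)]
  q <- d[blocked == FALSE]
  if (nrow(q) == 0L)
    return(data.table::data.table(patient_id = character(),
                                  index_day = integer(),
                                  index_class = character()))
  q <- q[, .SD[which.min(day)], by = "patient_id"]
  q[, list(patient_id, index_day = day, index_class = med_class)]
}

#' Apply eligibility predicates and build the attrition report
#'
#' Predicates run in listed order on candidates not excluded by an earlier
#' predicate, so each fill is attributed to the first failing predicate and
#' counts conserve exactly:
#' `n_new_fills = n_index_fills + sum(exclusions)`.
#'
#' @param candidates Candidate index fills from [identify_new_users()].
#' @param patients Patient baseline table (must contain every candidate
#'   `patient_id`).
#' @param criteria An [eligibility_criteria()] object.
#' @return List with `cohort` (a `data.table` of retained index fills joined
#'   to baseline data) and `report` (an `attrition_report`).
#' @export
apply_eligibility <- function(candidates, patients, criteria) {
  stopifnot(inherits(criteria, "eligibility_criteria"))
  cand <- data.table::as.data.table(candidates)
  pats <- data.table::as.data.table(patients)
  if (!all(cand$patient_id %in% pats$patient_id))
    stop("every candidate patient must exist in the patient table")
  df <- merge(cand, pats, by = "patient_id", sort = FALSE)
  data.table::setorder(df, patient_id)
  keep <- rep(TRUE, nrow(df))
  excl_counts <- integer(0)
  for (label in names(criteria$exclusion_predicates)) {
    pred <- criteria$exclusion_predicates[[label]]
    hit <- tryCatch(pred(as.data.frame(df[keep])),
                    error = function(e) stop("exclusion predicate '", label,
                                             "' failed: ", conditionMessage(e),
                                             call. = FALSE))
    if (!is.logical(hit) || length(hit) != sum(keep))
      stop("exclusion predicate '", label,
           "' must return one logical per remaining candidate")
    if (anyNA(hit)) {
      bad <- df[keep][which(is.na(hit))[1L], patient_id]
      stop("exclusion predicate '", label, "' returned NA for patient ", bad)
    }
    excl_counts[label] <- sum(hit)
    keep[keep] <- !hit
  }
  cohort <- df[keep]
  arm_counts <- cohort[, .N, by = "index_class"]
  report <- structure(list(
    n_new_fills = nrow(df),
    exclusions = excl_counts,
    n_index_fills = nrow(cohort),
    arm_counts = stats::setNames(arm_counts$N, arm_counts$index_class),
    followup_causes = NULL), class = "attrition_report")
  list(cohort = cohort, report = report)
}

#' @export
print.attrition_report <- function(x, ...) {
  cat("Attrition flow\n")
  cat(sprintf("  New fills:             %d\n", x$n_new_fills))
  for (label in names(x$exclusions))
    cat(sprintf("  Excluded (%s): %d\n", label, x$exclusions[[label]]))
  cat(sprintf("  Index fills (cohort):  %d\n", x$n_index_fills))
  for (a in names(x$arm_counts))
    cat(sprintf("    arm %-10s %d\n", a, x$arm_counts[[a]]))
  if (!is.null(x$followup_causes)) {
    cat("  End of follow-up by cause:\n")
    print(x$followup_causes)
  }
  invisible(x)
}

#' Write an attrition report as CSV and a plain-text flow summary
#'
#' @param report An `attrition_report`.
#' @param csv_path,txt_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the flow table written to CSV.
#' @export
write_attrition <- function(report, csv_path = NULL, txt_path = NULL) {
  excl_steps <- if (length(report$exclusions))
    paste0("excluded_", names(report$exclusions)) else character(0)
  tab <- data.table::data.table(
    step = c("new_fills", excl_steps,
             "index_fills", paste0("arm_", names(report$arm_counts))),
    count = c(report$n_new_fills, unname(report$exclusions),
              report$n_index_fills, unname(report$arm_counts)))
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w"); on.exit(close(con))
    sink(con); print(report); sink()
  }
  invisible(tab)
}
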
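# Exposure engine: pharmacy dispensings -> daily exposure episodes.
#
# A dispensing covers the half-open day interval
#   [dispense_day, dispense_day + 2 * days_supply)
# (coverage lasts twice the days' supply). Consecutive coverage periods are
# merged into one exposure episode when the refill gap -- next dispense day
# minus the running coverage end -- is at most `max_gap_days` (default 90);
# gap days inside an allowable gap count as exposed. Overlapping coverage
# periods are unioned; an early refill does not extend coverage beyond its
# own 2x window (no stockpiling).

#' Coverage period of a dispensing
#'
#' Returns the half-open day interval covered by each dispensing record:
#' coverage starts on the dispensing day and lasts twice the days' supply.
#'
#' @param dispense_day Integer vector of dispensing days (day 0 = origin).
#' @param days_supply Positive integer vector of days' supply.
#' @return A `data.table` with columns `start` and `end`; each row covers
#'   days `start, ..., end - 1`.
#' @examples
#' coverage_period(0, 30)   # [0, 60)
#' coverage_period(10, 90)  # [10, 190)
#' @export
coverage_period <- function(dispense_day, days_supply) {
  if (length(dispense_day) != length(days_supply))
    stop("dispense_day and days_supply must have equal length")
  if (any(days_supply <= 0)) stop("days_supply must be >= 1")
  if (any(dispense_day < 0)) stop("dispense_day must be >= 0")
  data.table::data.table(start = as.integer(dispense_day),
                         end = as.integer(dispense_day + 2L * days_supply))
}

#' Build an exposure timeline for one patient and one medication class
#'
#' Converts the dispensing records of a single patient for a single
#' medication into merged exposure episodes under the coverage-and-gap rule,
#' and locates the discontinuation day for the treatment regime started by
#' the first fill.
#'
#' @param records A data.frame with columns `dispense_day` and `days_supply`
#'   (optionally `patient_id` and `med_class`, which must then be constant).
#' @param max_gap_days Largest refill gap (days between the running coverage
#'   end and the next dispensing) that still counts as continuous exposure.
#' @return An object of class `exposure_timeline`: a list with
#'   `patient_id`, `med_class`, `intervals` (a `data.table` of disjoint
#'   half-open `[start, end)` episodes, gap days included), and
#'   `discontinuation_day` (end of the first episode).
#' @examples
#' f <- data.frame(dispense_day = c(0, 100), days_supply = c(30, 30))
#' build_timeline(f)  # gap 100 - 60 = 40 <= 90: single episode [0, 160)
#' @export
build_timeline <- function(records, max_gap_days = 90L) {
  records <- as.data.frame(records)
  if (!all(c("dispense_day", "days_supply") %in% names(records)))
    stop("records must have columns dispense_day and days_supply")
  pid <- if ("patient_id" %in% names(records)) unique(records$patient_id) else NA
  med <- if ("med_class" %in% names(records)) unique(records$med_class) else NA
  if (length(pid) > 1L || length(med) > 1L)
    stop("build_timeline() takes records for one patient and one medication")
  if (nrow(records) == 0L) {
    return(structure(list(patient_id = pid, med_class = med,
                          intervals = coverage_period(integer(), integer()),
                          discontinuation_day = NA_integer_),
                     class = "exposure_timeline"))
  }
  cov <- coverage_period(records$dispense_day, records$days_supply)
  data.table::setorder(cov, start, end)
  # running coverage end; a new episode starts when the gap exceeds the limit
  run_end <- cummax(cov$end)
  gap <- cov$start - data.table::shift(run_end, fill = cov$start[1L])
  epi <- cumsum(gap > max_gap_days)
  intervals <- data.table::data.table(start = cov$start, end = run_end,
                                      episode = epi)[
    , list(start = min(start), end = max(end)), by = "episode"][, episode := NULL][]
  structure(list(patient_id = pid, med_class = med, intervals = intervals,
                 discontinuation_day = intervals$end[1L]),
            class = "exposure_timeline")
}

#' @export
print.exposure_timeline <- function(x, ...) {
  cat("<exposure_timeline>", if (!is.na(x$med_class)) x$med_class else "",
      "\n  episodes:\n")
  print(x$intervals)
  cat("  discontinuation_day:", x$discontinuation_day, "\n")
  invisible(x)
}

#' Exposed-day set of a timeline
#'
#' @param timeline An `exposure_timeline`.
#' @return Sorted integer vector of exposed days.
#' @export
exposed_days <- function(timeline) {
  iv <- timeline$intervals
  if (nrow(iv) == 0L) return(integer())
  unlist(lapply(seq_len(nrow(iv)), function(i) seq.int(iv$start[i], iv$end[i] - 1L)))
}

#' Detect a treatment-protocol deviation
#'
#' A deviation is the earlier of (a) discontinuation -- the first day after
#' the index day not covered by the index-class episode containing the index
#' day -- and (b) crossover -- the first covered day of any comparator-class
#' timeline strictly after the index day. Same-day ties classify as
#' crossover. A deviation at or beyond `horizon_day` is reported as none.
#'
#' @param timelines Named list of `exposure_timeline` objects, one per
#'   medication class (names are class labels).
#' @param index_class Class initiated at the index day.
#' @param comparator_classes Character vector of comparator class labels.
#' @param index_day Index (cohort-entry) day; must be covered by the
#'   index-class timeline.
#' @param horizon_day End of follow-up; deviations at or after it are ignored.
#' @return List with `deviation_day` (integer or `NA`) and `deviation_kind`
#'   (`"discontinuation"`, `"crossover"`, or `"none"`).
#' @export
detect_deviation <- function(timelines, index_class, comparator_classes,
                             index_day, horizon_day = Inf) {
  idx <- timelines[[index_class]]
  if (is.null(idx)) stop("no timeline for index class ", index_class)
  iv <- idx$intervals
  hit <- iv$start <= index_day & index_day < iv$end
  if (!any(hit))
    stop("index day ", index_day, " is not covered by the ", index_class,
         " timeline: not a true initiator")
  disc_day <- iv$end[which(hit)[1L]]
  cross_day <- Inf
  for (cc in comparator_classes) {
    tl <- timelines[[cc]]
    if (is.null(tl) || nrow(tl$intervals) == 0L) next
    cand <- pmax(tl$intervals$start, index_day + 1L)
    cand <- cand[cand < tl$intervals$end]
    if (length(cand)) cross_day <- min(cross_day, min(cand))
  }
  dev_day <- min(disc_day, cross_day)
  if (dev_day >= horizon_day)
    return(list(deviation_day = NA_integer_, deviation_kind = "none"))
  kind <- if (cross_day <= disc_day) "crossover" else "discontinuation"
  list(deviation_day = as.integer(dev_day), deviation_kind = kind)
}

# Vectorised episode construction for a whole dispensing table.
# Returns one row per (patient_id, med_class) episode with [start, end).
build_episode_table <- function(dispensings, max_gap_days = 90L) {
  d <- data.table::as.data.table(dispensings)
  stopifnot(all(c("patient_id", "med_class", "dispense_day", "days_supply")
                %in% names(d)))
  d <- d[, list(patient_id, med_class, start = as.integer(dispense_day),
                end = as.integer(dispense_day + 2L * days_supply))]
  data.table::setorder(d, patient_id, med_class, start, end)
  d[, cov_end := cummax(end), by = list(patient_id, med_class)]
  d[, gap := start - data.table::shift(cov_end, fill = start[1L]),
    by = list(patient_id, med_class)]
  d[, episode := cumsum(gap > max_gap_days), by = list(patient_id, med_class)]
  d[, list(start = min(start), end = max(cov_end)),
    by = list(patient_id, med_class, episode)][, episode := NULL][]
}

# Vectorised deviation detection for a cohort. `cohort` needs patient_id,
# index_day, index_class; comparator classes are all other compared classes.
# Returns cohort with deviation_day (NA if none before horizon) and kind.
detect_deviation_table <- function(cohort, episodes, compared_classes,
                                   horizon_day = Inf) {
  co <- data.table::as.data.table(cohort)
  ep <- data.table::as.data.table(episodes)
  m <- merge(ep, co[, list(patient_id, index_day, index_class)],
             by = "patient_id", allow.cartesian = TRUE)
  # discontinuation: end of the index-class episode containing the index day
  idx <- m[med_class == index_class & start <= index_day & end > index_day,
           list(disc_day = min(end)), by = "patient_id"]
  out <- merge(co, idx, by = "patient_id", all.x = TRUE)
  if (anyNA(out$disc_day))
    stop("some cohort patients are not covered by their index class at the ",
         "index day")
  # crossover: first comparator-class covered day strictly after index day
  cmp <- m[med_class %in% compared_classes & med_class != index_class &
             end > index_day + 1L]
  cross <- if (nrow(cmp)) {
    cmp[, day := pmax(start, index_day + 1L)]
    cmp[, list(cross_day = as.numeric(min(day))), by = "patient_id"]
  } else data.table::data.table(patient_id = character(),
                                cross_day = numeric())
  out <- merge(out, cross, by = "patient_id", all.x = TRUE)
  out[, disc_day := as.numeric(disc_day)]
  out[is.na(cross_day), cross_day := Inf]
  out[, deviation_day := pmin(disc_day, cross_day)]
  out[, deviation_kind := data.table::fifelse(
        cross_day <= disc_day, "crossover", "discontinuation")]
  out[deviation_day >= horizon_day,
      `:=`(deviation_day = NA_real_, deviation_kind = "none")]
  out[, `:=`(disc_day = NULL, cross_day = NULL)]
  out[]
}

#' Export exposure episodes as a BED-like interval table
#'
#' @param dispensings Dispensing table with `patient_id`, `med_class`,
#'   `dispense_day`, `days_supply`.
#' @param max_gap_days Allowable refill gap in days.
#' @return `data.table` with columns `patient_id`, `start_day`, `end_day`,
#'   `med_class` (half-open day intervals).
#' @export
exposure_intervals <- function(dispensings, max_gap_days = 90L) {
  ep <- build_episode_table(dispensings, max_gap_days)
  ep[, list(patient_id, start_day = start, end_day = end, med_class)]
}
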
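# Person-time assembly: one row per patient per 30-day interval, with
# treatment, covariate (+ missingness indicator), censoring-cause and
# outcome columns, under per-protocol or ITT follow-up conventions.

#' Follow-up protocol specification
#'
#' @param mode `"PP"` (per-protocol: treatment deviations add artificial
#'   censoring) or `"ITT"` (deviations ignored).
#' @param horizon_intervals Follow-up length in 30-day intervals (default 30,
#'   i.e. 900 days, the closest interval multiple to 2.5 years).
#' @param outcome_types Event types composing the outcome. Nonfatal events
#'   come from the event table (`"MI"`, `"CVA"`); deaths enter as
#'   pseudo-types `"cv_death"`, `"noncv_death"`, `"unknown_death"` mapped
#'   from the patient table's death cause. Deaths not in the outcome set are
#'   censoring channels. The default is 3-point MACE.
#' @param covariate_kinds Named character vector declaring each analysis
#'   covariate as `"continuous"` or `"categorical"` (binary covariates are
#'   categorical); drives baseline mean/mode imputation.
#' @param baseline_window Days before the index day in which a measurement
#'   may inform the baseline (interval 0) value.
#' @param max_gap_days Allowable medication coverage gap for the exposure
#'   engine.
#' @param admin_end_day Optional administrative end-of-study day; follow-up
#'   reaching it is censored with cause `admin_end`.
#' @return Object of class `protocol_spec`.
#' @export
protocol_spec <- function(mode = c("PP", "ITT"), horizon_intervals = 30L,
                          outcome_types = c("MI", "CVA", "cv_death"),
                          covariate_kinds = NULL, baseline_window = 365L,
                          max_gap_days = 90L, admin_end_day = NULL) {
  mode <- match.arg(mode)
  if (horizon_intervals < 1L) stop("horizon_intervals must be >= 1")
  if (!length(outcome_types)) stop("outcome_types must be non-empty")
  structure(list(mode = mode,
                 horizon_intervals = as.integer(horizon_intervals),
                 outcome_types = outcome_types,
                 covariate_kinds = covariate_kinds,
                 baseline_window = as.integer(baseline_window),
                 max_gap_days = as.integer(max_gap_days),
                 admin_end_day = admin_end_day),
            class = "protocol_spec")
}

death_pseudo_type <- function(cause) {
  c(cardiovascular = "cv_death", noncardiovascular = "noncv_death",
    unknown = "unknown_death")[cause]
}

#' Encode covariates with last-observation-carried-forward and missingness
#' indicators
#'
#' For each cohort patient, analysis covariate and interval k, emits the
#' imputed value `L` and the measurement indicator `M` (1 if at least one
#' measurement of the covariate falls in interval k; the latest within the
#' interval wins). `L` is the last observed value at or before interval k;
#' when nothing was ever observed, the cohort-wide baseline mode (for
#' categorical) or mean (for continuous) of observed baselines is imputed.
#' Measurements within `baseline_window` days before the index day count as
#' interval-0 (baseline) measurements.
#'
#' @param measurements Measurement stream (`patient_id`, `day`, `covariate`,
#'   `value`).
#' @param cohort Cohort table with `patient_id` and `index_day`.
#' @param n_intervals Number of follow-up intervals to encode per patient
#'   (scalar, or named vector by patient).
#' @param covariate_kinds Named character vector (`"continuous"` /
#'   `"categorical"`); covariates absent from it are treated as continuous.
#' @param baseline_window Days of pre-index lookback for baseline values.
#' @return `data.table` keyed by (`patient_id`, `k`) with `L_<cov>` and
#'   `M_<cov>` columns.
#' @export
encode_missingness <- function(measurements, cohort, n_intervals,
                               covariate_kinds = NULL,
                               baseline_window = 365L) {
  meas <- data.table::as.data.table(measurements)
  co <- data.table::as.data.table(cohort)[, list(patient_id, index_day)]
  covars <- sort(unique(meas$covariate))
  if (!length(covars)) stop("no covariates in the measurement stream")
  m <- merge(meas, co, by = "patient_id")
  m[, rel := day - index_day]
  m <- m[rel >= -baseline_window]
  m[, k := pmax(rel %/% 30L, 0L)]
  # latest measurement within each (patient, covariate, interval)
  data.table::setorder(m, patient_id, covariate, k, day)
  obs <- m[, list(value = value[.N]), by = list(patient_id, covariate, k)]
  # cohort-wide baseline imputation basis
  base <- obs[k == 0L]
  impute <- vapply(covars, function(cv) {
    v <- base[covariate == cv, value]
    if (!length(v)) stop("covariate '", cv,
                         "' has no observed baseline values in the cohort")
    kind <- if (is.null(covariate_kinds)) NA_character_
            else covariate_kinds[cv]
    if (!is.na(kind) && kind == "categorical") {
      tt <- sort(table(v), decreasing = TRUE)
      as.numeric(names(tt)[1L])
    } else mean(v)
  }, numeric(1))
  # skeleton over patients x covariates x intervals
  if (length(n_intervals) == 1L) {
    nk <- rep(as.integer(n_intervals), nrow(co))
  } else {
    nk <- as.integer(n_intervals[co$patient_id])
    if (anyNA(nk)) stop("n_intervals must cover every cohort patient")
  }
  skel <- data.table::data.table(
    patient_id = rep(co$patient_id, nk))
  skel[, k := seq_len(.N) - 1L, by = "patient_id"]
  skel <- skel[, list(covariate = covars), by = list(patient_id, k)]
  g <- merge(skel, obs, by = c("patient_id", "covariate", "k"), all.x = TRUE)
  data.table::setorder(g, patient_id, covariate, k)
  g[, M := as.integer(!is.na(value))]
  g[, L := data.table::nafill(value, type = "locf"),
    by = list(patient_id, covariate)]
  g[is.na(L), L := impute[covariate]]
  wide <- data.table::dcast(g, patient_id + k ~ covariate,
                            value.var = c("L", "M"))
  data.table::setkey(wide, patient_id, k)
  wide
}

#' Build the discrete-time long-format analysis dataset
#'
#' One row per cohort patient per 30-day interval from the index date to the
#' earliest of the outcome interval, a censoring interval, or the horizon.
#' Censoring causes are disenrollment, non-cardiovascular death, death of
#' unknown cause, administrative end of study, and (PP mode) artificial
#' censoring at the interval containing a treatment-protocol deviation.
#' Within an interval the documented precedence is outcome > death censoring
#' > disenrollment > administrative end > artificial censoring. Rows whose
#' censoring cause is not `"none"` mark the interval in which follow-up was
#' lost and contribute no at-risk person-time.
#'
#' @param cohort Index-fill table (`patient_id`, `index_day`, `index_class`).
#' @param dispensings Dispensing table, or a pre-built episode table with
#'   columns `patient_id`, `med_class`, `start`, `end`.
#' @param measurements,events,patients Raw tables (see [generate_population()]).
#' @param spec A [protocol_spec()].
#' @param compared_classes Classes whose initiation counts as crossover;
#'   defaults to all classes present in the cohort's `index_class`.
#' @return `data.table` of class `person_time` with columns `patient_id`,
#'   `k`, `arm`, `A` (exposed to the index class at the interval start),
#'   `adherent`, `C` (censoring cause), `Y`, plus `L_*`/`M_*` covariate
#'   columns. Attribute `followup` holds each patient's end interval and
#'   cause.
#' @export
build_long_dataset <- function(cohort, dispensings, measurements, events,
                               patients, spec,
                               compared_classes = NULL) {
  stopifnot(inherits(spec, "protocol_spec"))
  co <- data.table::as.data.table(cohort)
  pats <- data.table::as.data.table(patients)
  ev <- data.table::as.data.table(events)
  K <- spec$horizon_intervals
  if (is.null(compared_classes)) compared_classes <- unique(co$index_class)
  if (!all(co$patient_id %in% pats$patient_id))
    stop("every cohort patient needs enrollment data in the patient table")

  d <- data.table::as.data.table(dispensings)
  episodes <- if (all(c("start", "end") %in% names(d))) d
              else build_episode_table(d, spec$max_gap_days)
  dev <- detect_deviation_table(co[, list(patient_id, index_day, index_class)],
                                episodes, compared_classes)

  base <- merge(dev, pats[, list(patient_id, enrollment_end, death_day,
                                 death_cause)], by = "patient_id")

  # earliest qualifying event day per patient (events + outcome-deaths)
  oev <- ev[event_type %in% spec$outcome_types,
            list(patient_id, eday = day, event_type)]
  dth <- base[!is.na(death_day),
              list(patient_id, dday = death_day,
                   dtype = death_pseudo_type(death_cause))]
  odth <- dth[dtype %in% spec$outcome_types,
              list(patient_id, eday = dday, event_type = dtype)]
  allev <- rbind(oev, odth)
  allev <- merge(allev, co[, list(patient_id, index_day)], by = "patient_id")
  if (nrow(allev) && any(allev$eday < allev$index_day))
    stop("event before index day: should have been excluded upstream")
  first_ev <- if (nrow(allev))
    allev[, list(eday = min(eday)), by = "patient_id"]
  else data.table::data.table(patient_id = character(), eday = integer())
  base <- merge(base, first_ev, by = "patient_id", all.x = TRUE)

  # censoring-death day (non-outcome deaths)
  cdth <- dth[!dtype %in% spec$outcome_types]
  base <- merge(base, cdth[, list(patient_id, dday, dtype)],
                by = "patient_id", all.x = TRUE)

  # End of follow-up. Among outcome and the real censoring causes, the
  # comparison is at interval resolution with precedence
  # outcome > death censoring > disenrollment > admin end (an outcome in
  # the same interval as a real censoring event is counted). A PP
  # treatment-protocol deviation ends follow-up at the deviation time
  # itself (day resolution, deviation winning a same-day tie): events
  # after the deviation, including later the same interval, occur
  # off-regime and are not attributed to it.
  na_inf <- function(x) data.table::fifelse(is.na(x), Inf, as.numeric(x))
  base[, d_ev := na_inf(eday)]
  base[, d_dth := na_inf(dday)]
  base[, d_dis := data.table::fifelse(
    enrollment_end >= index_day + 30 * K, Inf, as.numeric(enrollment_end))]
  adm <- if (is.null(spec$admin_end_day)) Inf else spec$admin_end_day
  base[, d_adm := data.table::fifelse(adm >= index_day + 30 * K, Inf,
                                      pmax(as.numeric(adm), index_day))]
  base[, k_ev := (d_ev - index_day) %/% 30]
  base[, k_dth := (d_dth - index_day) %/% 30]
  base[, k_dis := pmax((d_dis - index_day) %/% 30, 0)]
  base[, k_adm := pmax((d_adm - index_day) %/% 30, 0)]
  candk <- as.matrix(base[, list(k_ev, k_dth, k_dis, k_adm)])
  candd <- as.matrix(base[, list(d_ev, d_dth, d_dis, d_adm)])
  cause_order <- c("outcome", "death", "disenrollment", "admin_end")
  k0 <- apply(candk, 1L, min)
  pick <- apply(candk == k0, 1L, which.max)     # first TRUE = precedence
  day0_ <- candd[cbind(seq_len(nrow(candd)), pick)]
  end_cause <- cause_order[pick]
  # PP artificial censoring at the deviation day
  d_dev <- if (spec$mode == "PP") na_inf(base$deviation_day) else
    rep(Inf, nrow(base))
  k_dev <- pmax((d_dev - base$index_day) %/% 30, 0)
  art <- d_dev <= day0_ & k_dev < K
  k_end <- ifelse(art, k_dev, k0)
  end_cause <- ifelse(art, "artificial_pp", end_cause)
  reached_horizon <- k_end >= K
  k_end <- pmin(k_end, K - 1L)
  base[, `:=`(k_end = as.integer(k_end), end_cause = end_cause,
              reached_horizon = reached_horizon)]

  # expand to person-interval rows
  long <- base[, list(k = 0:k_end[1L]), by = "patient_id"]
  long <- merge(long,
                base[, list(patient_id, index_day, arm = index_class,
                            deviation_day, dtype, k_end, end_cause,
                            reached_horizon)],
                by = "patient_id")
  long[, Y := 0L]
  long[, C := "none"]
  terminal <- long$k == long$k_end & !long$reached_horizon
  long[terminal & end_cause == "outcome", Y := 1L]
  long[terminal & end_cause == "death", C := dtype]
  long[terminal & end_cause == "disenrollment", C := "disenrollment"]
  long[terminal & end_cause == "admin_end", C := "admin_end"]
  long[terminal & end_cause == "artificial_pp", C := "artificial_pp"]

  # exposure to the index class at the interval start day
  ep_idx <- merge(episodes, co[, list(patient_id, index_class)],
                  by = "patient_id")
  ep_idx <- ep_idx[med_class == index_class]
  long[, day0 := index_day + 30L * k]
  long[, A := 0L]
  hitkey <- ep_idx[long, on = "patient_id", allow.cartesian = TRUE,
                   nomatch = NULL][start <= day0 & end > day0,
                                   list(patient_id, day0)]
  long[unique(hitkey), on = c("patient_id", "day0"), A := 1L]
  long[, adherent := is.na(deviation_day) | day0 < deviation_day]

  # covariates
  nk <- stats::setNames(base$k_end + 1L, base$patient_id)
  LM <- encode_missingness(measurements, co, nk,
                           covariate_kinds = spec$covariate_kinds,
                           baseline_window = spec$baseline_window)
  long <- merge(long, LM, by = c("patient_id", "k"))
  data.table::setorder(long, patient_id, k)
  long[, c("deviation_day", "dtype", "k_end", "end_cause", "day0",
           "reached_horizon", "index_day") := NULL]

  followup <- base[, list(patient_id, k_end,
                          cause = data.table::fifelse(reached_horizon,
                                                      "admin_end",
                            data.table::fifelse(end_cause == "death",
                                                dtype, end_cause)))]
  covs <- sub("^L_", "", grep("^L_", names(long), value = TRUE))
  data.table::setattr(long, "followup", followup)
  data.table::setattr(long, "covariates", covs)
  data.table::setattr(long, "spec", spec)
  data.table::setattr(long, "class",
                      c("person_time", class(long)))
  long[]
}

#' End-of-follow-up counts by arm and cause
#'
#' @param long A `person_time` dataset.
#' @return `data.table` of counts by `arm` and `cause` (outcome, censoring
#'   causes, administrative end).
#' @export
followup_causes <- function(long) {
  fu <- attr(long, "followup")
  arms <- unique(data.table::as.data.table(long)[, list(patient_id, arm)])
  m <- merge(fu, arms, by = "patient_id")
  m[, .N, by = list(arm, cause)][order(arm, cause)]
}
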
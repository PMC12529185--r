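# Independent oracles and fixture builders shared across tests.

# Day-by-day exposure oracle: marks each day exposed per the documented
# coverage rule (union of per-fill 2x-supply windows; a day in a refill gap
# of <= max_gap days between the running coverage end and the next
# dispensing counts as exposed). Deliberately a different code path from
# the interval-merging engine.
oracle_exposed_days <- function(fills, max_gap = 90L) {
  if (nrow(fills) == 0L) return(integer())
  d <- fills$dispense_day
  s <- fills$days_supply
  top <- max(d + 2L * s) + max_gap + 2L
  out <- logical(top)
  for (t in seq_len(top) - 1L) {
    in_cov <- any(d <= t & t < d + 2L * s)
    if (in_cov) { out[t + 1L] <- TRUE; next }
    prior <- d <= t
    if (!any(prior)) next
    E <- max(d[prior] + 2L * s[prior])
    nxt <- d[d > t]
    if (length(nxt) && t >= E && min(nxt) - E <= max_gap)
      out[t + 1L] <- TRUE
  }
  which(out) - 1L
}

# Vectorised day-scan variant of the same oracle (per-day union marking
# plus the gap test on running coverage end and next-dispensing day).
oracle_exposed_days_fast <- function(fills, max_gap = 90L) {
  if (nrow(fills) == 0L) return(integer())
  d <- as.integer(fills$dispense_day); s <- as.integer(fills$days_supply)
  top <- max(d + 2L * s) + max_gap + 2L
  t <- 0:(top - 1L)
  cover <- logical(top)
  for (i in seq_along(d))
    cover[(d[i] + 1L):(d[i] + 2L * s[i])] <- TRUE
  o <- order(d)
  ds <- d[o]
  es <- cummax((d + 2L * s)[o])
  idx <- findInterval(t, ds)            # fills dispensed at or before t
  E <- ifelse(idx >= 1L, es[pmax(idx, 1L)], NA_integer_)
  udays <- sort(unique(d))
  nxt_i <- findInterval(t, udays) + 1L  # next dispensing strictly after t
  nxt <- ifelse(nxt_i <= length(udays), udays[pmin(nxt_i, length(udays))],
                NA_integer_)
  gap_ok <- !is.na(E) & !is.na(nxt) & t >= E & (nxt - E) <= max_gap
  which(cover | gap_ok) - 1L
}

rand_fillset <- function(m) {
  data.frame(dispense_day = sort(sample(0:600, m, replace = TRUE)),
             days_supply = sample(1:100, m, replace = TRUE))
}

# Brute-force washout oracle: a (deduplicated) fill qualifies iff no other
# compared-class fill lies in (day - washout, day].
oracle_new_users <- function(dispensings, classes, washout = 730L) {
  d <- unique(as.data.frame(dispensings)[
    dispensings$med_class %in% classes,
    c("patient_id", "med_class", "dispense_day")])
  keep <- data.frame()
  for (p in unique(d$patient_id)) {
    dp <- d[d$patient_id == p, ]
    ok <- vapply(seq_len(nrow(dp)), function(i) {
      others <- dp[-i, ]
      !any(others$dispense_day > dp$dispense_day[i] - washout &
             others$dispense_day <= dp$dispense_day[i])
    }, NA)
    q <- dp[ok, ]
    if (nrow(q)) keep <- rbind(keep, q[which.min(q$dispense_day), ])
  }
  keep
}

# Randomized 2-arm scenario with independent censoring and non-informative
# continuation; treatment protective for arm "glp1ra".
scen_randomized <- function(seed, n = 2000L, horizon_days = 300L) {
  scenario_config(
    n_patients = n,
    classes = c("glp1ra", "su"),
    treatment_model = list(su = c(intercept = 0)),
    continuation_model = list(discontinue = c(intercept = qlogis(0.05)),
                              crossover = c(intercept = qlogis(0.015))),
    censoring_model = list(disenrollment = c(intercept = qlogis(0.01)),
                           noncv_death = c(intercept = qlogis(0.002))),
    horizon_days = horizon_days, seed = seed)
}

# Confounded initiation, informative censoring and continuation; the
# validation scenario for double-robustness and coverage studies.
scen_confounded <- function(seed, n = 4000L, horizon_days = 180L) {
  scenario_config(
    n_patients = n,
    classes = c("glp1ra", "su"),
    treatment_model = list(su = c(intercept = 0.3, ascvd = -1.0,
                                  hba1c = 0.7, age = 0.4)),
    continuation_model = list(
      discontinue = c(intercept = qlogis(0.05), hba1c = 0.4),
      crossover = c(intercept = qlogis(0.015))),
    censoring_model = list(
      disenrollment = c(intercept = qlogis(0.012), hba1c = 0.4),
      noncv_death = c(intercept = qlogis(0.002), age = 0.7, hba1c = 0.4)),
    hazard_model = c(intercept = qlogis(0.008), age = 0.5, ascvd = 1.0,
                     hba1c = 0.6, `tx:glp1ra` = -0.5, `tx:su` = 0),
    horizon_days = horizon_days, seed = seed)
}

std_kinds <- c(age = "continuous", ascvd = "categorical",
               hba1c = "continuous")

std_lib <- function() learner_library(c("intercept", "glm"), cv_folds = 5L,
                                      seed = 1L)

fit_all_nuisances <- function(long, lib = std_lib(), pp = TRUE) {
  kinds <- c("censor_disenrollment", "censor_noncv_death",
             "censor_unknown_death")
  if (pp) kinds <- c(kinds, "censor_artificial_pp")
  list(initiation = fit_propensity_series(long, "initiation", lib),
       censoring = lapply(kinds, function(kd)
         fit_propensity_series(long, kd, lib)))
}

pipeline_long <- function(tables, spec,
                          criteria = eligibility_criteria(tables$classes)) {
  cand <- identify_new_users(tables$dispensings, criteria)
  el <- apply_eligibility(cand, tables$patients, criteria)
  build_long_dataset(el$cohort, tables$dispensings, tables$measurements,
                     tables$events, tables$patients, spec)
}

# Hand-constructed nuisance fits (probabilities supplied directly).
manual_init_fit <- function(long, g, arms = sort(unique(long$arm))) {
  base <- unique(data.frame(patient_id = long$patient_id, arm = long$arm))
  g <- rep_len(g, nrow(base))
  pred <- data.table::data.table(patient_id = base$patient_id, k = 0L,
                                 g_init = g)
  data.table::setkey(pred, patient_id, k)
  structure(list(kind = "initiation", pred = pred, arms = arms,
                 detail = list()), class = "nuisance_fit")
}

manual_cens_fit <- function(long, p, kind = "censor_disenrollment") {
  pred <- data.table::data.table(patient_id = long$patient_id, k = long$k,
                                 p = rep_len(p, nrow(long)))
  data.table::setkey(pred, patient_id, k)
  structure(list(kind = kind, pred = pred, detail = list()),
            class = "nuisance_fit")
}

# Empirical marginal ("intercept-only") nuisance fits: deliberately ignore
# covariates, for misspecified-g studies.
marginal_fits <- function(long) {
  dtt <- data.table::as.data.table(long)
  arms <- sort(unique(dtt$arm))
  base <- dtt[dtt$k == 0L]
  shares <- prop.table(table(base$arm))
  init_pred <- data.table::data.table(
    patient_id = base$patient_id, k = 0L,
    g_init = as.numeric(shares[as.character(base$arm)]))
  data.table::setkey(init_pred, patient_id, k)
  cens <- lapply(c("disenrollment", "noncv_death", "unknown_death",
                   "artificial_pp"), function(cc) {
    pr <- dtt[, list(p = mean(C == cc)), by = "k"]
    pred <- merge(dtt[, list(patient_id, k)], pr, by = "k")[
      , list(patient_id, k, p)]
    data.table::setkey(pred, patient_id, k)
    structure(list(kind = paste0("censor_", cc), pred = pred,
                   detail = list()), class = "nuisance_fit")
  })
  list(initiation = structure(list(kind = "initiation", pred = init_pred,
                                   arms = arms, detail = list()),
                              class = "nuisance_fit"),
       censoring = cens)
}

# Minimal hand-built person_time dataset from a row data.frame.
make_long <- function(df) {
  dt <- data.table::as.data.table(df)
  for (cl in c("L_x", "M_x")) if (!cl %in% names(dt)) dt[[cl]] <- 1
  if (!"adherent" %in% names(dt)) dt$adherent <- TRUE
  if (!"A" %in% names(dt)) dt$A <- 1L
  data.table::setattr(dt, "class", c("person_time", class(dt)))
  dt
}

# Tiny raw tables for person-time unit tests: three covariates measured at
# day 0 and every 30 days; helpers fill defaults.
tiny_tables <- function(patients, dispensings, measurements, events,
                        horizon_days = 300L,
                        classes = c("A", "B")) {
  structure(list(patients = data.table::as.data.table(patients),
                 dispensings = data.table::as.data.table(dispensings),
                 measurements = data.table::as.data.table(measurements),
                 events = data.table::as.data.table(events),
                 horizon_days = horizon_days, classes = classes),
            class = "raw_tables")
}
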
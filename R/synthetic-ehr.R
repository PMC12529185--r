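# Synthetic EHR generator with known causal structure.
#
# The generator simulates a discrete-time (30-day interval) data-generating
# world -- confounded treatment initiation, time-varying confounding of
# treatment continuation, informative right-censoring, and an exposure-
# dependent MACE hazard -- and then materialises raw EHR-style tables
# (patients, dispensings, measurements, events). Treatment and deviation
# decisions are made at interval starts and realised exactly in the
# dispensing records (coverage episodes end on 30-day boundaries, with fill
# days and refill gaps jittered inside episodes), so the exposure engine
# reconstructs the simulated exposure without misclassification.
#
# All model coefficients apply to standardised covariates: continuous
# values are z-scored with the configured mean/sd, binary values are
# centred at their prevalence. Intercepts are therefore log-odds at the
# covariate means.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scenario configuration for the synthetic EHR generator
#'
#' Defines the data-generating world: baseline covariates, confounded
#' multinomial treatment initiation, per-interval discontinuation/crossover,
#' first-order Markov covariate dynamics, an exposure-dependent discrete-time
#' MACE hazard, per-cause censoring, covariate missingness, and
#' dispensing-level structure (days' supply, refill jitter, allowable gaps).
#'
#' @param n_patients Number of patients.
#' @param classes Medication-class labels (2 or 4 treatment arms); the first
#'   class is the reference of the initiation model.
#' @param horizon_days Follow-up horizon in days; must be a multiple of 30.
#' @param baseline Named list of baseline covariate specs, each
#'   `list(kind = "continuous", mean=, sd=)` or `list(kind = "binary", p=)`.
#' @param time_varying Names of baseline covariates that evolve over time
#'   (must have entries in `covariate_dynamics`).
#' @param treatment_model Named list with one coefficient vector per
#'   non-reference class: initiation log-odds versus the reference class
#'   (`intercept` plus standardised-covariate terms).
#' @param continuation_model List with `discontinue` and `crossover`
#'   coefficient vectors: per-interval log-odds of stopping / switching,
#'   evaluated on the previous interval's covariates.
#' @param covariate_dynamics Named list per time-varying covariate:
#'   `list(rho=, drift=, exposure = c(class = effect, ...), sd=)` giving the
#'   first-order autoregression of the standardised value, with an additive
#'   shift per current exposure class.
#' @param hazard_model Coefficient vector for the per-interval MACE log-odds:
#'   `intercept`, covariate terms, and `tx:<class>` terms for current
#'   exposure.
#' @param censoring_model List of coefficient vectors per censoring cause
#'   (`disenrollment`, `noncv_death`).
#' @param unknown_death_frac Fraction of non-cardiovascular deaths recorded
#'   with unknown cause (its own censoring channel).
#' @param outcome_mix Probabilities that a MACE is a nonfatal MI, nonfatal
#'   stroke (CVA), or cardiovascular death; must sum to 1.
#' @param missingness_rate Probability that a scheduled 30-day covariate
#'   measurement is absent.
#' @param dispensing List: `days_supply` (values), `supply_prob`
#'   (probabilities), `max_jitter` (half-range, in 2-day steps, of refill
#'   overlap jitter), `gap_prob` (probability a refill arrives after an
#'   allowable 20-90 day gap).
#' @param seed Integer seed; identical configs generate identical tables.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(
    n_patients = 2000L,
    classes = c("glp1ra", "su"),
    horizon_days = 900L,
    baseline = list(
      age   = list(kind = "continuous", mean = 57, sd = 13),
      ascvd = list(kind = "binary", p = 0.10),
      hba1c = list(kind = "continuous", mean = 9.0, sd = 2.0)),
    time_varying = "hba1c",
    treatment_model = list(
      su = c(intercept = 1.0, age = 0.3, ascvd = -0.6, hba1c = 0.3)),
    continuation_model = list(
      discontinue = c(intercept = qlogis(0.05), hba1c = 0.25),
      crossover   = c(intercept = qlogis(0.015), ascvd = 0.3)),
    covariate_dynamics = list(
      hba1c = list(rho = 0.8, drift = 0, sd = 0.5,
                   exposure = c(glp1ra = -0.5, su = -0.2))),
    hazard_model = c(intercept = qlogis(0.004), age = 0.5, ascvd = 0.8,
                     hba1c = 0.3, `tx:glp1ra` = -0.5, `tx:su` = 0),
    censoring_model = list(
      disenrollment = c(intercept = qlogis(0.008)),
      noncv_death   = c(intercept = qlogis(0.0015), age = 0.8, hba1c = 0.2)),
    unknown_death_frac = 0.1,
    outcome_mix = c(MI = 0.45, CVA = 0.35, cv_death = 0.20),
    missingness_rate = 0.1,
    dispensing = list(days_supply = c(30L, 90L), supply_prob = c(0.7, 0.3),
                      max_jitter = 8L, gap_prob = 0.1),
    seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), classes = classes,
              horizon_days = as.integer(horizon_days), baseline = baseline,
              time_varying = time_varying, treatment_model = treatment_model,
              continuation_model = continuation_model,
              covariate_dynamics = covariate_dynamics,
              hazard_model = hazard_model, censoring_model = censoring_model,
              unknown_death_frac = unknown_death_frac,
              outcome_mix = outcome_mix,
              missingness_rate = missingness_rate, dispensing = dispensing,
              seed = as.integer(seed))
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  fail <- function(field, msg) stop("invalid scenario config, field '",
                                    field, "': ", msg, call. = FALSE)
  if (cfg$n_patients < 1L) fail("n_patients", "must be positive")
  if (!length(cfg$classes) %in% c(2L, 4L))
    fail("classes", "must name 2 or 4 treatment arms")
  if (cfg$horizon_days <= 0L || cfg$horizon_days %% 30L != 0L)
    fail("horizon_days", "must be a positive multiple of 30")
  if (cfg$missingness_rate < 0 || cfg$missingness_rate > 1)
    fail("missingness_rate", "must lie in [0, 1]")
  if (cfg$unknown_death_frac < 0 || cfg$unknown_death_frac > 1)
    fail("unknown_death_frac", "must lie in [0, 1]")
  if (abs(sum(cfg$outcome_mix) - 1) > 1e-8)
    fail("outcome_mix", "must sum to 1")
  covs <- names(cfg$baseline)
  for (nm in cfg$time_varying)
    if (!nm %in% covs) fail("time_varying", paste0("'", nm,
                            "' not in baseline covariates"))
  for (nm in cfg$time_varying)
    if (is.null(cfg$covariate_dynamics[[nm]]))
      fail("covariate_dynamics", paste0("missing dynamics for '", nm, "'"))
  check_coefs <- function(co, field, allow_tx = FALSE) {
    extra <- setdiff(names(co), c("intercept", covs,
                                  if (allow_tx) paste0("tx:", cfg$classes)))
    if (length(extra)) fail(field, paste0("unknown covariate term(s): ",
                                          paste(extra, collapse = ", ")))
    lp_typ <- abs(co[["intercept"]] %||% 0) +
      sum(abs(co[setdiff(names(co), "intercept")])) * 3
    if (!is.finite(lp_typ) || lp_typ > 30)
      fail(field, paste0("probability overflow: linear predictor exceeds ",
                         "+-30 over the typical (3 SD) covariate range"))
  }
  for (cl in names(cfg$treatment_model))
    check_coefs(cfg$treatment_model[[cl]], "treatment_model")
  if (!all(names(cfg$treatment_model) %in% cfg$classes[-1L]))
    fail("treatment_model", "must name non-reference classes only")
  check_coefs(cfg$continuation_model$discontinue, "continuation_model")
  check_coefs(cfg$continuation_model$crossover, "continuation_model")
  check_coefs(cfg$hazard_model, "hazard_model", allow_tx = TRUE)
  for (cs in names(cfg$censoring_model))
    check_coefs(cfg$censoring_model[[cs]], "censoring_model")
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$n_patients, "patients,",
      length(x$classes), "arms (", paste(x$classes, collapse = ", "), "),",
      x$horizon_days, "days (", x$horizon_days %/% 30L, "intervals), seed",
      x$seed, "\n")
  invisible(x)
}

#' Static treatment regime
#'
#' @param arm Class label to initiate.
#' @param sustained If `TRUE` (per-protocol), the regime requires continued
#'   exposure and no comparator initiation; if `FALSE` (ITT analogue), only
#'   initiation.
#' @return An object of class `regime`.
#' @export
regime <- function(arm, sustained = TRUE) {
  structure(list(arm = arm, sustained = isTRUE(sustained)), class = "regime")
}

lp_from <- function(coefs, z) {
  lp <- rep(coefs[["intercept"]] %||% 0, nrow(z))
  for (nm in setdiff(names(coefs), "intercept"))
    if (!startsWith(nm, "tx:")) lp <- lp + coefs[[nm]] * z[, nm]
  lp
}

# Core interval-level simulator. Decisions at interval starts:
#  - interval k event draw uses the exposure holding during k;
#  - continuation (discontinue/crossover) decided at the end of k takes
#    effect at k+1, so the first non-adherent interval is k+1;
#  - censoring draws (death first, then disenrollment) apply to
#    event-free patients.
# force_arm / sustained / censoring switch the g-computation interventions.
sim_world <- function(cfg, n, force_arm = NULL, force_sustained = FALSE,
                      censoring = TRUE) {
  K <- cfg$horizon_days %/% 30L
  ncl <- length(cfg$classes)
  covs <- names(cfg$baseline)
  # standardised baseline draw
  z <- matrix(0, n, length(covs), dimnames = list(NULL, covs))
  raw0 <- z
  for (nm in covs) {
    sp <- cfg$baseline[[nm]]
    if (sp$kind == "continuous") {
      z[, nm] <- rnorm(n)
      raw0[, nm] <- sp$mean + sp$sd * z[, nm]
    } else {
      x <- rbinom(n, 1L, sp$p)
      z[, nm] <- x - sp$p
      raw0[, nm] <- x
    }
  }
  # multinomial initiation
  lp <- matrix(0, n, ncl, dimnames = list(NULL, cfg$classes))
  for (cl in names(cfg$treatment_model))
    lp[, cl] <- lp_from(cfg$treatment_model[[cl]], z)
  g_init <- exp(lp - apply(lp, 1L, max))
  g_init <- g_init / rowSums(g_init)
  if (is.null(force_arm)) {
    u <- runif(n)
    arm <- max.col(u < t(apply(g_init, 1L, cumsum)), ties.method = "first")
  } else {
    arm <- rep(match(force_arm, cfg$classes), n)
    if (anyNA(arm)) stop("regime arm '", force_arm,
                         "' is not a configured class")
  }
  cur <- arm                      # current exposure: 0 = none, else class idx
  active <- rep(TRUE, n)
  dev_k <- rep(Inf, n); dev_kind <- rep("none", n); dev_class <- rep(NA_integer_, n)
  exp_end <- rep(K, n)            # first interval NOT exposed to index class
  exp_end2 <- rep(K, n)           # same for the crossed-to class
  ev_k <- rep(Inf, n); ev_day <- rep(NA_integer_, n); ev_type <- rep(NA_character_, n)
  cn_k <- rep(Inf, n); cn_day <- rep(NA_integer_, n); cn_cause <- rep(NA_character_, n)
  p_event <- matrix(NA_real_, n, K); p_death <- matrix(NA_real_, n, K)
  p_dis <- matrix(NA_real_, n, K); p_dev <- matrix(0, n, K)
  ztv <- lapply(cfg$time_varying, function(nm) {
    m <- matrix(NA_real_, n, K); m[, 1L] <- z[, nm]; m
  })
  names(ztv) <- cfg$time_varying
  hz <- cfg$hazard_model
  tx_eff <- vapply(cfg$classes, function(cl) hz[[paste0("tx:", cl)]] %||% 0,
                   numeric(1))
  for (k in seq_len(K) - 1L) {
    idx <- which(active)
    if (!length(idx)) break
    zi <- z[idx, , drop = FALSE]
    # event draw under current exposure
    lp_ev <- lp_from(hz, zi) + ifelse(cur[idx] > 0L, tx_eff[pmax(cur[idx], 1L)], 0)
    pe <- plogis(lp_ev)
    p_event[idx, k + 1L] <- pe
    ev <- runif(length(idx)) < pe
    if (any(ev)) {
      who <- idx[ev]
      ev_k[who] <- k
      ev_day[who] <- 30L * k + sample.int(30L, length(who), replace = TRUE) - 1L
      ev_type[who] <- sample(names(cfg$outcome_mix), length(who),
                             replace = TRUE, prob = cfg$outcome_mix)
      active[who] <- FALSE
    }
    # censoring draws (event-free patients); recorded hazards for everyone
    pd <- plogis(lp_from(cfg$censoring_model$noncv_death, zi))
    ps <- plogis(lp_from(cfg$censoring_model$disenrollment, zi))
    p_death[idx, k + 1L] <- pd
    p_dis[idx, k + 1L] <- ps
    if (censoring) {
      alive <- idx[!ev]
      if (length(alive)) {
        dth <- runif(length(alive)) < pd[!ev]
        who <- alive[dth]
        if (length(who)) {
          cn_k[who] <- k
          cn_day[who] <- 30L * k + sample.int(30L, length(who), replace = TRUE) - 1L
          cn_cause[who] <- ifelse(runif(length(who)) < cfg$unknown_death_frac,
                                  "unknown_death", "noncv_death")
          active[who] <- FALSE
        }
        rest <- alive[!dth]
        if (length(rest)) {
          dis <- runif(length(rest)) < ps[!ev][!dth]
          who <- rest[dis]
          if (length(who)) {
            cn_k[who] <- k
            cn_day[who] <- 30L * k + sample.int(30L, length(who), replace = TRUE) - 1L
            cn_cause[who] <- "disenrollment"
            active[who] <- FALSE
          }
        }
      }
    }
    # continuation decisions for interval k+1 (natural regime only)
    px <- plogis(lp_from(cfg$continuation_model$crossover, zi))
    pdis <- plogis(lp_from(cfg$continuation_model$discontinue, zi))
    if (k + 1L < K) {
      on_index <- cur[idx] == arm[idx]
      p_dev[idx, k + 2L] <- ifelse(on_index, px + (1 - px) * pdis, 0)
      if (!force_sustained) {
        u1 <- runif(length(idx)); u2 <- runif(length(idx))
        # still-active, currently on the index class: may cross or stop
        liv <- active[idx]
        cross <- liv & on_index & ncl > 1L & u1 < px
        stopi <- liv & on_index & !cross & u2 < pdis
        whoc <- idx[cross]
        if (length(whoc)) {
          others <- lapply(arm[whoc], function(a) setdiff(seq_len(ncl), a))
          newcl <- vapply(others, function(o) o[sample.int(length(o), 1L)], 1L)
          cur[whoc] <- newcl
          dev_k[whoc] <- k + 1L; dev_kind[whoc] <- "crossover"
          dev_class[whoc] <- newcl; exp_end[whoc] <- k + 1L
        }
        whos <- idx[stopi]
        if (length(whos)) {
          cur[whos] <- 0L
          dev_k[whos] <- k + 1L; dev_kind[whos] <- "discontinuation"
          exp_end[whos] <- k + 1L
        }
        # crossed-over patients may later stop their second medication
        off2 <- liv & !on_index & cur[idx] > 0L & u2 < pdis
        who2 <- idx[off2]
        if (length(who2)) {
          cur[who2] <- 0L
          exp_end2[who2] <- k + 1L
        }
      }
    }
    # covariate dynamics (first-order Markov given current exposure)
    if (k + 1L < K) {
      for (nm in cfg$time_varying) {
        dyn <- cfg$covariate_dynamics[[nm]]
        shift_tx <- ifelse(cur > 0L,
                           vapply(pmax(cur, 1L), function(ci)
                             dyn$exposure[[cfg$classes[ci]]] %||% 0, numeric(1)),
                           0)
        z[, nm] <- dyn$drift + dyn$rho * z[, nm] + shift_tx +
          rnorm(n, 0, dyn$sd)
        ztv[[nm]][, k + 2L] <- z[, nm]
      }
    }
  }
  exit_k <- pmin(ev_k, cn_k, K)
  list(K = K, arm = arm, g_init = g_init, raw0 = raw0, ztv = ztv,
       ev_k = ev_k, ev_day = ev_day, ev_type = ev_type,
       cn_k = cn_k, cn_day = cn_day, cn_cause = cn_cause,
       dev_k = dev_k, dev_kind = dev_kind, dev_class = dev_class,
       exp_end = exp_end, exp_end2 = exp_end2, exit_k = exit_k,
       p_event = p_event, p_death = p_death, p_dis = p_dis, p_dev = p_dev)
}

# Realise a continuous exposure episode [start_day, target_end) as fills.
# All days/supplies are even so the final (possibly truncated) supply hits
# the 30-day boundary exactly; fills stop at last_day (death/exit), but a
# zero-gap fill is forced when stopping early would leave the episode short
# of the patient's last at-risk day.
realize_fills <- function(start_day, target_end, last_day, disp) {
  if (target_end <= start_day) return(NULL)
  supplies <- as.integer(disp$days_supply)
  probs <- disp$supply_prob
  mj <- as.integer(disp$max_jitter %||% 8L)
  gp <- disp$gap_prob %||% 0.1
  days <- integer(0); sup <- integer(0)
  cend <- as.integer(start_day)
  repeat {
    if (!length(days)) {
      d <- as.integer(start_day)
    } else {
      g <- if (runif(1) < gp) 2L * sample(10:45, 1L)   # allowable 20..90 gap
           else -2L * (sample.int(mj + 1L, 1L) - 1L)   # overlap 0..2*mj
      d <- min(cend + g, target_end - 2L)
      if (d <= days[length(days)]) d <- days[length(days)] + 2L
      if (d > target_end - 2L) break
    }
    if (d > last_day) {
      if (cend > last_day) break
      d <- cend                                        # keep coverage unbroken
    }
    rem <- target_end - d
    s <- sample(supplies, 1L, prob = probs)
    if (2L * s >= rem) s <- rem %/% 2L
    days <- c(days, d); sup <- c(sup, s)
    cend <- max(cend, d + 2L * s)
    if (cend >= target_end) break
  }
  if (!length(days)) return(NULL)
  list(days = days, sup = sup)
}

#' Generate a synthetic raw-table EHR population
#'
#' Simulates the configured data-generating world and materialises four raw
#' tables: `patients` (baseline covariates, enrollment span, death day and
#' cause), `dispensings` (fill-level records with days' supply and refill
#' gaps), `measurements` (a 30-day covariate stream with missingness), and
#' `events` (nonfatal MI / CVA). Bit-for-bit reproducible for a given
#' config (the seed is part of the config).
#'
#' @param config A [scenario_config()].
#' @param keep_truth If `TRUE`, attach the per-interval true treatment,
#'   censoring and deviation probabilities (attribute `"truth"`) for use as
#'   oracle nuisance parameters in validation studies.
#' @return A list of class `raw_tables` with elements `patients`,
#'   `dispensings`, `measurements`, `events`, and `horizon_days`.
#' @export
generate_population <- function(config, keep_truth = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$n_patients
  K <- config$horizon_days %/% 30L
  w <- sim_world(config, n)
  pid <- sprintf("P%06d", seq_len(n))

  death_day <- rep(NA_integer_, n); death_cause <- rep(NA_character_, n)
  is_cvd <- !is.na(w$ev_type) & w$ev_type == "cv_death"
  death_day[is_cvd] <- w$ev_day[is_cvd]
  death_cause[is_cvd] <- "cardiovascular"
  is_dth <- !is.na(w$cn_cause) & w$cn_cause %in% c("noncv_death", "unknown_death")
  death_day[is_dth] <- w$cn_day[is_dth]
  death_cause[is_dth] <- ifelse(w$cn_cause[is_dth] == "noncv_death",
                                "noncardiovascular", "unknown")
  enrollment_end <- rep(config$horizon_days, n)
  is_dis <- !is.na(w$cn_cause) & w$cn_cause == "disenrollment"
  enrollment_end[is_dis] <- w$cn_day[is_dis]

  patients <- data.table::data.table(patient_id = pid,
                                     as.data.frame(w$raw0),
                                     enrollment_start = 0L,
                                     enrollment_end = enrollment_end,
                                     death_day = death_day,
                                     death_cause = death_cause)

  # events: nonfatal MI / CVA
  is_ev <- !is.na(w$ev_type) & w$ev_type %in% c("MI", "CVA")
  events <- data.table::data.table(patient_id = pid[is_ev],
                                   day = w$ev_day[is_ev],
                                   event_type = w$ev_type[is_ev])

  # measurements every 30 days while at risk, with missingness; baseline-only
  # covariates measured at day 0
  exit_day <- rep(config$horizon_days, n)
  ended <- is.finite(pmin(w$ev_k, w$cn_k))
  exit_day[ended] <- pmin(w$ev_day, w$cn_day, na.rm = TRUE)[ended]
  last_k <- pmin(w$exit_k, K - 1L)
  meas <- vector("list", length(config$time_varying) + 1L)
  tv <- config$time_varying
  for (j in seq_along(tv)) {
    nm <- tv[j]; sp <- config$baseline[[nm]]
    zt <- w$ztv[[nm]]
    rows <- which(!is.na(zt) & col(zt) <= last_k + 1L)
    i <- ((rows - 1L) %% n) + 1L
    kk <- ((rows - 1L) %/% n)
    keep <- runif(length(i)) >= config$missingness_rate
    meas[[j]] <- data.table::data.table(
      patient_id = pid[i][keep], day = 30L * kk[keep], covariate = nm,
      value = if (sp$kind == "continuous") sp$mean + sp$sd * zt[rows][keep]
              else round(zt[rows][keep] + sp$p))
  }
  stat <- setdiff(names(config$baseline), tv)
  if (length(stat)) {
    sl <- lapply(stat, function(nm) {
      keep <- runif(n) >= config$missingness_rate
      data.table::data.table(patient_id = pid[keep], day = 0L, covariate = nm,
                             value = w$raw0[keep, nm])
    })
    meas[[length(tv) + 1L]] <- data.table::rbindlist(sl)
  }
  measurements <- data.table::rbindlist(meas[!vapply(meas, is.null, NA)])
  data.table::setorder(measurements, patient_id, day, covariate)

  # dispensings: index-class episode to the exposure-end boundary; crossed
  # class (if any) from the deviation boundary
  acc <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    e_use <- min(w$exp_end[i], w$exit_k[i] + 1L, K)
    f1 <- realize_fills(0L, 30L * e_use, exit_day[i], config$dispensing)
    if (!is.null(f1))
      acc[[2L * i - 1L]] <- list(pid = pid[i],
                                 cls = config$classes[w$arm[i]],
                                 days = f1$days, sup = f1$sup)
    if (w$dev_kind[i] == "crossover" && w$dev_k[i] <= w$exit_k[i]) {
      e2 <- min(w$exp_end2[i], w$exit_k[i] + 1L, K)
      if (e2 > w$dev_k[i]) {
        f2 <- realize_fills(30L * w$dev_k[i], 30L * e2, exit_day[i],
                            config$dispensing)
        if (!is.null(f2))
          acc[[2L * i]] <- list(pid = pid[i],
                                cls = config$classes[w$dev_class[i]],
                                days = f2$days, sup = f2$sup)
      }
    }
  }
  acc <- acc[!vapply(acc, is.null, NA)]
  nf <- vapply(acc, function(a) length(a$days), integer(1))
  dispensings <- data.table::data.table(
    patient_id = rep(vapply(acc, `[[`, character(1), "pid"), nf),
    med_class = rep(vapply(acc, `[[`, character(1), "cls"), nf),
    dispense_day = unlist(lapply(acc, `[[`, "days")),
    days_supply = unlist(lapply(acc, `[[`, "sup")))
  data.table::setorder(dispensings, patient_id, med_class, dispense_day)

  out <- structure(list(patients = patients, dispensings = dispensings,
                        measurements = measurements, events = events,
                        horizon_days = config$horizon_days,
                        classes = config$classes),
                   class = "raw_tables")
  if (keep_truth) {
    truth <- list(g_init = w$g_init, arm = config$classes[w$arm],
                  patient_id = pid, p_event = w$p_event, p_death = w$p_death,
                  p_dis = w$p_dis, p_dev = w$p_dev, exit_k = w$exit_k,
                  dev_k = w$dev_k)
    attr(out, "truth") <- truth
  }
  out
}

#' @export
print.raw_tables <- function(x, ...) {
  cat("<raw_tables>", nrow(x$patients), "patients,", nrow(x$dispensings),
      "dispensings,", nrow(x$measurements), "measurements,",
      nrow(x$events), "events; horizon", x$horizon_days, "days\n")
  invisible(x)
}

#' Write raw tables as four CSV files
#'
#' @param tables A `raw_tables` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_raw_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "raw_tables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "dispensings.csv",
                            "measurements.csv", "events.csv"))
  utils::write.csv(tables$patients, paths[1], row.names = FALSE)
  utils::write.csv(tables$dispensings, paths[2], row.names = FALSE)
  utils::write.csv(tables$measurements, paths[3], row.names = FALSE)
  utils::write.csv(tables$events, paths[4], row.names = FALSE)
  invisible(paths)
}

#' True counterfactual cumulative incidence by Monte-Carlo g-computation
#'
#' Simulates `n_mc` patients with treatment forced to follow the regime
#' (initiation forced; for sustained regimes discontinuation and crossover
#' are switched off), right-censoring switched off, and covariates evolving
#' under the forced exposure. Returns the empirical counterfactual
#' cumulative incidence per 30-day interval with binomial Monte-Carlo
#' standard errors.
#'
#' @param config A [scenario_config()].
#' @param regime A [regime()] whose arm is one of the configured classes.
#' @param n_mc Number of Monte-Carlo replicates (at least 10000).
#' @return Object of class `ground_truth`: a list with `curve` (a
#'   `data.table` of `k`, `F`, `mc_se` for k = 1..K), `regime`, `n_mc`.
#' @export
true_counterfactual_risk <- function(config, regime, n_mc = 100000L) {
  stopifnot(inherits(config, "scenario_config"), inherits(regime, "regime"))
  if (!regime$arm %in% config$classes)
    stop("regime arm '", regime$arm, "' is not a configured class")
  if (n_mc < 10000L) stop("n_mc must be at least 10000")
  set.seed(config$seed + 499979L)
  w <- sim_world(config, as.integer(n_mc), force_arm = regime$arm,
                 force_sustained = regime$sustained, censoring = FALSE)
  K <- w$K
  Fk <- vapply(seq_len(K), function(k) mean(w$ev_k < k), numeric(1))
  curve <- data.table::data.table(k = seq_len(K), F = Fk,
                                  mc_se = sqrt(pmax(Fk * (1 - Fk), 1 / n_mc) / n_mc))
  structure(list(curve = curve, regime = regime, n_mc = as.integer(n_mc)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> regime", x$regime$arm,
      if (x$regime$sustained) "(sustained)" else "(initiation only)",
      "n_mc =", x$n_mc, "\n")
  print(x$curve)
  invisible(x)
}
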
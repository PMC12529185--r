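# Nuisance models: cross-validated super-learner ensembles for treatment
# initiation and each right-censoring cause, and cumulative inverse
# probability weights with truncation.

#' Learner library for the super learner
#'
#' @param learners Character vector of learner names, in order. Built-ins:
#'   `"intercept"` (weighted mean), `"glm"` (main-terms logistic),
#'   `"lasso"` (L1-penalised logistic, penalty by internal CV).
#' @param cv_folds Number of cross-validation folds for the ensemble.
#' @param seed Integer seed controlling fold assignment.
#' @return Object of class `learner_library`.
#' @export
learner_library <- function(learners = c("intercept", "glm", "lasso"),
                            cv_folds = 10L, seed = 1L) {
  if (length(learners) < 1L) stop("library needs at least 1 learner")
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  known <- c("intercept", "glm", "lasso")
  if (!all(learners %in% known))
    stop("unknown learner(s): ",
         paste(setdiff(learners, known), collapse = ", "))
  structure(list(learners = learners, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)), class = "learner_library")
}

.bound <- function(p, lo = 1e-6, hi = 1 - 1e-6) pmin(pmax(p, lo), hi)

.log_loss <- function(y, p) {
  p <- .bound(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Fit one learner; returns a function(Xnew) -> probabilities.
.fit_learner <- function(name, X, y, wts = NULL) {
  if (is.null(wts)) wts <- rep(1, length(y))
  const <- function() {
    p <- .bound(weighted.mean(y, wts))
    function(Xnew) rep(p, nrow(Xnew))
  }
  if (name == "intercept" || var(y) == 0 || ncol(X) == 0L) return(const())
  if (name == "glm" || (name == "lasso" && (ncol(X) < 2L || length(y) < 30L))) {
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, X), y, weights = wts,
                                      family = stats::binomial(),
                                      control = stats::glm.control(
                                        epsilon = 1e-12, maxit = 200))),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(coef(fit)) && all(is.na(coef(fit)[-1L])))
      return(const())
    beta <- coef(fit); beta[is.na(beta)] <- 0
    return(function(Xnew) .bound(plogis(drop(cbind(1, Xnew) %*% beta))))
  }
  # lasso
  fit <- tryCatch(
    suppressWarnings(glmnet::cv.glmnet(X, y, family = "binomial",
                                       weights = wts, nfolds = 5L,
                                       standardize = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(.fit_learner("glm", X, y, wts))
  function(Xnew) .bound(drop(predict(fit, newx = Xnew, s = "lambda.min",
                                     type = "response")))
}

#' Fit a cross-validated super learner for a binary target
#'
#' V-fold cross-validated log-loss is computed for each learner; the
#' ensemble is the convex combination of learner predictions minimising the
#' CV loss (single-learner corners are always candidates, so the ensemble
#' CV loss never exceeds the best single learner's). A constant target
#' yields a constant predictor with a warning flag rather than an error,
#' since per-interval censoring events can be absent.
#'
#' @param data A data.frame/data.table of rows to fit on.
#' @param target Name of the binary (0/1) target column.
#' @param predictors Character vector of predictor column names.
#' @param library A [learner_library()].
#' @return Object of class `super_learner` with elements `predict`
#'   (function of new data), `weights` (ensemble weights), `cv_loss`
#'   (per learner), `sl_cv_loss`, and `constant` (degenerate-target flag).
#' @export
fit_super_learner <- function(data, target, predictors,
                              library = learner_library()) {
  stopifnot(inherits(library, "learner_library"))
  df <- as.data.frame(data)
  y <- df[[target]]
  X <- as.matrix(df[, predictors, drop = FALSE])
  storage.mode(X) <- "double"
  n <- length(y)
  Ln <- library$learners
  if (var(y) == 0) {
    p <- .bound(mean(y), 1e-6, 1 - 1e-6)
    return(structure(list(
      predict = function(newdata) rep(p, nrow(as.data.frame(newdata))),
      weights = stats::setNames(rep(1 / length(Ln), length(Ln)), Ln),
      cv_loss = stats::setNames(rep(NA_real_, length(Ln)), Ln),
      sl_cv_loss = NA_real_, constant = TRUE, predictors = predictors),
      class = "super_learner"))
  }
  if (n < library$cv_folds * 5L)
    stop("need at least cv_folds * 5 rows to fit the super learner")
  set.seed(library$seed)
  folds <- sample(rep_len(seq_len(library$cv_folds), n))
  cvp <- matrix(NA_real_, n, length(Ln), dimnames = list(NULL, Ln))
  for (v in seq_len(library$cv_folds)) {
    tr <- folds != v
    if (var(y[tr]) == 0) {
      cvp[!tr, ] <- .bound(mean(y[tr]))
      next
    }
    for (l in Ln) {
      f <- .fit_learner(l, X[tr, , drop = FALSE], y[tr])
      cvp[!tr, l] <- f(X[!tr, , drop = FALSE])
    }
  }
  cv_loss <- apply(cvp, 2L, function(p) .log_loss(y, p))
  # meta-learner: convex weights minimising CV log-loss; corners included
  loss_w <- function(w) .log_loss(y, drop(cvp %*% w))
  cands <- lapply(seq_along(Ln), function(j) {
    w <- rep(0, length(Ln)); w[j] <- 1; w
  })
  cands <- c(cands, list(rep(1 / length(Ln), length(Ln))))
  softmax <- function(a) { e <- exp(a - max(a)); e / sum(e) }
  for (st in list(rep(0, length(Ln)),
                  { a <- rep(-2, length(Ln)); a[which.min(cv_loss)] <- 2; a })) {
    op <- tryCatch(optim(st, function(a) loss_w(softmax(a)),
                         method = "BFGS",
                         control = list(maxit = 200, reltol = 1e-12)),
                   error = function(e) NULL)
    if (!is.null(op)) cands <- c(cands, list(softmax(op$par)))
  }
  losses <- vapply(cands, loss_w, numeric(1))
  w_best <- cands[[which.min(losses)]]
  fits <- lapply(Ln, function(l) .fit_learner(l, X, y))
  names(fits) <- Ln
  pred_fun <- function(newdata) {
    Xn <- as.matrix(as.data.frame(newdata)[, predictors, drop = FALSE])
    storage.mode(Xn) <- "double"
    P <- vapply(fits, function(f) f(Xn), numeric(nrow(Xn)))
    if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
    .bound(drop(P %*% w_best))
  }
  structure(list(predict = pred_fun,
                 weights = stats::setNames(w_best, Ln),
                 cv_loss = cv_loss, sl_cv_loss = min(losses),
                 constant = FALSE, predictors = predictors),
            class = "super_learner")
}

#' @export
print.super_learner <- function(x, ...) {
  cat("<super_learner>", if (x$constant) "(constant target)" else "", "\n")
  if (!x$constant) {
    cat("  ensemble weights:\n"); print(round(x$weights, 4))
    cat("  CV log-loss:", round(x$sl_cv_loss, 6), "| single learners:\n")
    print(round(x$cv_loss, 6))
  }
  invisible(x)
}

default_predictors <- function(long) {
  grep("^(L|M)_", names(long), value = TRUE)
}

#' Fit a per-interval propensity series
#'
#' Fits propensity models for treatment initiation (at the index interval)
#' or for one right-censoring cause at each 30-day interval separately.
#' Intervals with fewer target events than `min_events` share a single
#' pooled fit with the interval index as a predictor. Initiation for more
#' than two arms uses one-vs-rest fits normalised to sum to one. Emitted
#' probabilities used in weight denominators are floored at `g_floor`.
#'
#' @param long A `person_time` dataset.
#' @param kind One of `"initiation"`, `"censor_disenrollment"`,
#'   `"censor_noncv_death"`, `"censor_unknown_death"`,
#'   `"censor_artificial_pp"` (treatment continuation), `"censor_admin_end"`.
#' @param library A [learner_library()].
#' @param min_events Minimum per-interval event count for a separate
#'   per-interval fit (default 25).
#' @param g_floor Lower probability bound (default 0.005).
#' @param predictors Predictor columns; defaults to all `L_*`/`M_*` columns.
#' @return Object of class `nuisance_fit`: `kind`, `pred` (a `data.table`
#'   keyed by `patient_id`, `k`; for initiation one probability column per
#'   arm plus `g_init` = probability of the patient's own arm; for censoring
#'   a column `p` = probability of that censoring event in the interval),
#'   and `detail` (per-interval fit summaries).
#' @export
fit_propensity_series <- function(long, kind, library = learner_library(),
                                  min_events = 25L, g_floor = 0.005,
                                  predictors = NULL) {
  dt <- data.table::as.data.table(long)
  if (is.null(predictors)) predictors <- default_predictors(dt)
  if (identical(kind, "continuation")) kind <- "censor_artificial_pp"
  if (kind == "initiation") {
    base <- dt[k == 0L]
    arms <- sort(unique(base$arm))
    if (length(arms) == 2L) {
      base[, tgt := as.integer(arm == arms[2L])]
      sl <- fit_super_learner(base, "tgt", predictors, library)
      p2 <- sl$predict(base)
      P <- cbind(1 - p2, p2)
      detail <- list(list(arm = arms[2L], sl = sl))
    } else {
      P <- matrix(NA_real_, nrow(base), length(arms))
      detail <- vector("list", length(arms))
      for (j in seq_along(arms)) {
        base[, tgt := as.integer(arm == arms[j])]
        sl <- fit_super_learner(base, "tgt", predictors, library)
        P[, j] <- sl$predict(base)
        detail[[j]] <- list(arm = arms[j], sl = sl)
      }
      P <- P / rowSums(P)
    }
    P <- pmin(pmax(P, g_floor), 1 - g_floor)
    P <- P / rowSums(P)
    colnames(P) <- arms
    pred <- data.table::data.table(patient_id = base$patient_id, k = 0L, P,
                                   g_init = P[cbind(seq_len(nrow(P)),
                                                    match(base$arm, arms))])
    data.table::setkey(pred, patient_id, k)
    return(structure(list(kind = kind, pred = pred, arms = arms,
                          detail = detail, g_floor = g_floor),
                     class = "nuisance_fit"))
  }
  cause <- sub("^censor_", "", kind)
  valid <- c("disenrollment", "noncv_death", "unknown_death",
             "artificial_pp", "admin_end")
  if (!cause %in% valid) stop("unknown nuisance kind: ", kind)
  dt <- data.table::copy(dt)
  dt[, tgt := as.integer(C == cause)]
  counts <- dt[, list(n_ev = sum(tgt)), by = "k"]
  sep_ks <- counts[n_ev >= min_events, k]
  pool_ks <- counts[!k %in% sep_ks, k]
  dt[, p := NA_real_]
  detail <- list()
  for (kk in sep_ks) {
    sub <- dt[k == kk]
    sl <- fit_super_learner(sub, "tgt", predictors, library)
    dt[k == kk, p := sl$predict(sub)]
    detail[[length(detail) + 1L]] <- list(k = kk, pooled = FALSE, sl = sl)
  }
  if (length(pool_ks)) {
    preds2 <- c(predictors, "k")
    if (sum(dt$tgt) == 0L || length(unique(dt$k)) == 1L)
      preds2 <- predictors
    sl <- fit_super_learner(dt, "tgt", preds2, library)
    sub <- dt[k %in% pool_ks]
    dt[k %in% pool_ks, p := sl$predict(sub)]
    detail[[length(detail) + 1L]] <- list(k = pool_ks, pooled = TRUE, sl = sl)
  }
  # survival (1 - p) is floored at g_floor; p itself is capped accordingly
  dt[, p := pmin(pmax(p, 0), 1 - g_floor)]
  pred <- dt[, list(patient_id, k, p)]
  data.table::setkey(pred, patient_id, k)
  structure(list(kind = kind, pred = pred, detail = detail,
                 g_floor = g_floor), class = "nuisance_fit")
}

#' Weight truncation specification
#'
#' @param style `"absolute"` (cap at `cap`), `"percentile"` (cap at the
#'   given percentile of the positive-weight distribution), or `"none"`.
#' @param percentile Percentile in (50, 100] used when
#'   `style = "percentile"` (default 99).
#' @param cap Absolute cap (> 1); conventional defaults are 20 for IPW and
#'   200 for TMLE.
#' @return Object of class `truncation_spec`.
#' @export
truncation_spec <- function(style = c("absolute", "percentile", "none"),
                            percentile = 99, cap = 20) {
  style <- match.arg(style)
  if (percentile <= 50 || percentile > 100)
    stop("percentile must lie in (50, 100]")
  if (cap <= 1) stop("cap must exceed 1")
  structure(list(style = style, percentile = percentile, cap = cap),
            class = "truncation_spec")
}

apply_truncation <- function(w, trunc) {
  if (is.null(trunc) || trunc$style == "none") return(w)
  # type-1 (order statistic) quantile guarantees that at most
  # (100 - percentile)% of positive weights lie strictly above the cap
  cap <- if (trunc$style == "absolute") trunc$cap
         else quantile(w[w > 0], trunc$percentile / 100, names = FALSE,
                       type = 1)
  pmin(w, cap)
}

#' Cumulative inverse-probability weights
#'
#' Computes, for each person-interval row, the cumulative product of inverse
#' probabilities of the patient's observed treatment (initiation) and of
#' remaining uncensored, for every modelled censoring cause (per-protocol
#' runs include the artificial-censoring/continuation channel). Truncation
#' applies to the final cumulative weight.
#'
#' Two row/weight conventions are supported, matching the estimator the
#' weights feed. Under `"atrisk"` (product-limit estimators), real
#' censoring acts at the end of the interval: a row censored by
#' disenrollment, death or administrative end remains at risk with `Y = 0`,
#' and the corresponding censoring-survival factors enter the cumulative
#' product with a one-interval lag; artificial (deviation) censoring acts
#' at the interval start, so its factor includes the current interval and
#' deviating rows get weight 0. Under `"strict"` (TMLE fluctuation
#' weights), only fully uncensored rows (`C == "none"`) carry weight and
#' all factors include the current interval.
#'
#' @param long A `person_time` dataset.
#' @param fits List with elements `initiation` (a `nuisance_fit`) and
#'   `censoring` (list of censoring `nuisance_fit`s; fits whose kind
#'   contains `"artificial"` are treated as the deviation channel).
#' @param regime_arm Optional arm label; if `NULL`, weights are computed for
#'   every patient under their own arm.
#' @param truncation A [truncation_spec()] or `NULL`.
#' @param convention `"atrisk"` (default; product-limit) or `"strict"`
#'   (TMLE).
#' @return Numeric weight vector aligned with the rows of `long`.
#' @export
cumulative_weights <- function(long, fits, regime_arm = NULL,
                               truncation = truncation_spec("absolute",
                                                            cap = 20),
                               convention = c("atrisk", "strict")) {
  convention <- match.arg(convention)
  dt <- data.table::as.data.table(long)
  if (is.null(fits$initiation)) stop("missing nuisance fit: initiation")
  gi <- fits$initiation$pred[, list(patient_id, g_init)]
  dt <- merge(dt, gi, by = "patient_id", sort = FALSE, all.x = TRUE)
  if (anyNA(dt$g_init)) stop("initiation fit does not cover all patients")
  dt[, surv_real := 1]
  dt[, surv_dev := 1]
  for (cf in fits$censoring) {
    if (!inherits(cf, "nuisance_fit"))
      stop("censoring fits must be nuisance_fit objects")
    pr <- cf$pred[, list(patient_id, k, pc = p)]
    dt <- merge(dt, pr, by = c("patient_id", "k"), sort = FALSE, all.x = TRUE)
    if (anyNA(dt$pc)) stop("missing fit predictions for ", cf$kind)
    if (grepl("artificial", cf$kind)) dt[, surv_dev := surv_dev * (1 - pc)]
    else dt[, surv_real := surv_real * (1 - pc)]
    dt[, pc := NULL]
  }
  data.table::setorder(dt, patient_id, k)
  if (convention == "strict") {
    dt[, cumsurv := cumprod(surv_real * surv_dev), by = "patient_id"]
    dt[, w := 1 / (g_init * cumsurv)]
    dt[C != "none", w := 0]
  } else {
    dt[, cumsurv := cumprod(data.table::shift(surv_real, fill = 1)) *
         cumprod(surv_dev), by = "patient_id"]
    dt[, w := 1 / (g_init * cumsurv)]
    dt[C == "artificial_pp", w := 0]
  }
  if (!is.null(regime_arm)) dt[arm != regime_arm, w := 0]
  w <- dt$w
  pos <- w > 0
  w[pos] <- apply_truncation(w[pos], truncation)
  # restore the original row order of `long`
  w[match(paste(long$patient_id, long$k), paste(dt$patient_id, dt$k))]
}

#' Oracle nuisance fits from generator ground truth
#'
#' Converts the true per-interval treatment, censoring and deviation
#' probabilities attached by [generate_population()] (attribute `"truth"`)
#' into the same shape as fitted [fit_propensity_series()] output, for use
#' as correctly specified nuisance parameters in validation studies.
#'
#' @param tables A `raw_tables` object generated with `keep_truth = TRUE`.
#' @param long A `person_time` dataset built from those tables.
#' @param mode `"PP"` (include the deviation/continuation channel) or
#'   `"ITT"`.
#' @return List with `initiation` and `censoring` in the shape expected by
#'   [cumulative_weights()] and [tmle_cuminc()].
#' @export
truth_nuisance <- function(tables, long, mode = c("PP", "ITT")) {
  mode <- match.arg(mode)
  tr <- attr(tables, "truth")
  if (is.null(tr)) stop("tables carry no truth attribute; regenerate with ",
                        "keep_truth = TRUE")
  dt <- data.table::as.data.table(long)[, list(patient_id, k)]
  i <- match(dt$patient_id, tr$patient_id)
  if (anyNA(i)) stop("long dataset patients not found in truth tables")
  gmat <- tr$g_init
  colnames(gmat) <- tables$classes
  own <- gmat[cbind(i, match(tr$arm[i], tables$classes))]
  init_pred <- data.table::data.table(
    unique(dt[, list(patient_id)]))
  ii <- match(init_pred$patient_id, tr$patient_id)
  init_pred <- cbind(init_pred, k = 0L, gmat[ii, , drop = FALSE],
                     g_init = gmat[cbind(ii, match(tr$arm[ii],
                                                   tables$classes))])
  data.table::setkey(init_pred, patient_id, k)
  initiation <- structure(list(kind = "initiation", pred = init_pred,
                               arms = tables$classes, detail = list()),
                          class = "nuisance_fit")
  grab <- function(mat, kind) {
    p <- mat[cbind(i, dt$k + 1L)]
    p[is.na(p)] <- 0
    pred <- data.table::data.table(patient_id = dt$patient_id, k = dt$k,
                                   p = p)
    data.table::setkey(pred, patient_id, k)
    structure(list(kind = kind, pred = pred, detail = list()),
              class = "nuisance_fit")
  }
  cens <- list(grab(tr$p_death, "censor_death"),
               grab(tr$p_dis, "censor_disenrollment"))
  if (mode == "PP") cens <- c(cens, list(grab(tr$p_dev,
                                              "censor_artificial_pp")))
  list(initiation = initiation, censoring = cens)
}
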
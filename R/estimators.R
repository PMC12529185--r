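# Counterfactual cumulative incidence estimators: unadjusted and
# inverse-probability-weighted discrete-time product-limit curves, and
# longitudinal TMLE by sequential regression (iterated conditional
# expectation) with logistic targeting, all with influence-curve SEs.

#' Unit weights for the unadjusted estimator
#'
#' Weight 1 for every at-risk person-interval row of the given arm (equal
#' weights for all person-time observations), 0 elsewhere. Rows censored by
#' a real cause remain at risk with `Y = 0` (censoring acts at the interval
#' end); rows at the artificial (deviation) censoring interval do not.
#'
#' @param long A `person_time` dataset.
#' @param regime_arm Arm label, or `NULL` for all arms.
#' @return Numeric weight vector aligned with `long`.
#' @export
unit_weights <- function(long, regime_arm = NULL) {
  w <- as.numeric(long$C != "artificial_pp")
  if (!is.null(regime_arm)) w[long$arm != regime_arm] <- 0
  w
}

#' Weighted discrete-time product-limit cumulative incidence
#'
#' Estimates the per-interval discrete hazard as the weighted event
#' proportion among at-risk rows, and the cumulative incidence as one minus
#' the product of hazard complements. With unit weights and no censoring
#' this reduces exactly to one minus the Kaplan-Meier survival curve.
#' Standard errors come from the influence curve of the weighted
#' product-limit estimator (delta method over interval hazards, weights
#' treated as known).
#'
#' @param long A `person_time` dataset.
#' @param weights Per-row weights (e.g. [cumulative_weights()] or
#'   [unit_weights()]); must be 0 for censored rows.
#' @param regime_arm Arm whose curve is estimated.
#' @param estimator Label stored on the result (`"unadjusted"` or `"ipw"`).
#' @return Object of class `cuminc_curve`: `curve` (`data.table` of `k`,
#'   `F`, `se`, `lcl`, `ucl`), `ic` (n x K influence-curve matrix over the
#'   full cohort), `estimator`, `regime`, `n`, and `truncated_at` (first
#'   interval with zero total weight, if any).
#' @export
product_limit_cuminc <- function(long, weights, regime_arm,
                                 estimator = "ipw") {
  dt <- data.table::as.data.table(long)
  if (length(weights) != nrow(dt)) stop("weights must align with rows")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(weights[dt$C == "artificial_pp"] > 0))
    stop("artificially censored rows must carry zero weight")
  patients <- sort(unique(dt$patient_id))
  n <- length(patients)
  K <- max(dt$k) + 1L
  lam <- rep(NA_real_, K); Sw <- rep(0, K)
  contrib <- matrix(0, n, K)
  sel_arm <- dt$arm == regime_arm
  truncated_at <- NA_integer_
  for (j in seq_len(K) - 1L) {
    at <- which(dt$k == j & sel_arm & weights > 0)
    sw <- sum(weights[at])
    if (sw == 0) {
      later <- any(dt$k > j & sel_arm)
      if (later && is.na(truncated_at)) truncated_at <- j
      lam[j + 1L] <- NA_real_
      next
    }
    Sw[j + 1L] <- sw
    lam[j + 1L] <- sum(weights[at] * dt$Y[at]) / sw
    pi_ <- match(dt$patient_id[at], patients)
    contrib[pi_, j + 1L] <- weights[at] * (dt$Y[at] - lam[j + 1L]) *
      n / sw / max(1 - lam[j + 1L], 1e-12)
  }
  keepK <- if (is.na(truncated_at)) K else truncated_at
  lam_use <- lam[seq_len(keepK)]
  lam_use[is.na(lam_use)] <- 0
  surv <- cumprod(1 - lam_use)
  Fk <- 1 - surv
  cum <- contrib[, seq_len(keepK), drop = FALSE]
  if (keepK > 1L) cum <- t(apply(cum, 1L, cumsum))
  ic <- sweep(cum, 2L, surv, `*`)
  rownames(ic) <- patients
  se <- sqrt(colMeans(ic^2) / n)
  curve <- data.table::data.table(k = seq_len(keepK), F = Fk, se = se,
                                  lcl = pmax(Fk - qnorm(.975) * se, 0),
                                  ucl = pmin(Fk + qnorm(.975) * se, 1))
  structure(list(curve = curve, ic = ic, estimator = estimator,
                 regime = regime_arm, n = n, truncated_at = truncated_at),
            class = "cuminc_curve")
}

#' @export
print.cuminc_curve <- function(x, ...) {
  cat("<cuminc_curve>", x$estimator, "| arm", x$regime, "| n =", x$n, "\n")
  print(x$curve)
  if (!is.na(x$truncated_at))
    cat("  [curve truncated at interval", x$truncated_at,
        "- zero at-risk weight]\n")
  if (isTRUE(x$monotone_projected))
    cat("  [isotonic projection applied across horizons]\n")
  if (isTRUE(x$fluctuation_fallback))
    cat("  [fluctuation did not converge at some horizon;",
        "untargeted plug-in used]\n")
  invisible(x)
}

#' @export
plot.cuminc_curve <- function(x, add = FALSE, col = 1, ...) {
  cv <- x$curve
  if (!add)
    plot(c(0, cv$k), c(0, cv$F), type = "s", xlab = "30-day interval",
         ylab = "Cumulative incidence", col = col, ...)
  else graphics::lines(c(0, cv$k), c(0, cv$F), type = "s", col = col, ...)
  invisible(x)
}

# Q-regression fitter for (possibly fractional) outcomes in [0, 1].
fit_q <- function(X, z, learner = "glm") {
  if (length(z) == 0L) return(function(Xn) rep(0, nrow(Xn)))
  if (var(z) == 0 || ncol(X) == 0L || learner == "intercept") {
    m <- .bound(mean(z))
    return(function(Xn) rep(m, nrow(Xn)))
  }
  if (learner == "lasso" && ncol(X) >= 2L && length(z) >= 40L) {
    keep1 <- z > 0; keep0 <- z < 1
    Xe <- rbind(X[keep1, , drop = FALSE], X[keep0, , drop = FALSE])
    ye <- c(rep(1, sum(keep1)), rep(0, sum(keep0)))
    we <- c(z[keep1], 1 - z[keep0])
    fit <- tryCatch(
      suppressWarnings(glmnet::cv.glmnet(Xe, ye, weights = we,
                                         family = "binomial", nfolds = 5L)),
      error = function(e) NULL)
    if (!is.null(fit))
      return(function(Xn) .bound(drop(predict(fit, newx = Xn,
                                              s = "lambda.min",
                                              type = "response"))))
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(cbind(1, X), z,
                                    family = stats::quasibinomial(),
                                    control = stats::glm.control(
                                      epsilon = 1e-12, maxit = 200))),
    error = function(e) NULL)
  if (is.null(fit)) {
    m <- .bound(mean(z))
    return(function(Xn) rep(m, nrow(Xn)))
  }
  beta <- coef(fit); beta[is.na(beta)] <- 0
  function(Xn) .bound(plogis(drop(cbind(1, Xn) %*% beta)))
}

# Solve the intercept-only weighted logistic fluctuation exactly:
# find eps with sum(h * (z - plogis(off + eps))) = 0. The score is
# monotone decreasing in eps, so bracketing + Newton polish is exact to
# machine precision; degenerate targets are pushed to the +-20 boundary.
solve_fluctuation <- function(off, z, h) {
  f <- function(e) sum(h * (z - plogis(off + e)))
  if (f(20) >= 0) return(list(eps = 20, ok = TRUE))
  if (f(-20) <= 0) return(list(eps = -20, ok = TRUE))
  eps <- tryCatch(stats::uniroot(f, c(-20, 20), tol = 1e-10)$root,
                  error = function(e) NA_real_)
  if (is.na(eps)) return(list(eps = 0, ok = FALSE))
  for (it in 1:20) {
    pr <- plogis(off + eps)
    g <- sum(h * (z - pr)); d <- sum(h * pr * (1 - pr))
    if (d <= 0) break
    step <- g / d
    eps <- eps + step
    if (abs(step) < 1e-14) break
  }
  list(eps = eps, ok = TRUE)
}

# Shared preparation for the sequential-regression pass.
.tmle_prep <- function(long, fits, regime_arm, weight_cap) {
  dt <- data.table::as.data.table(long)
  data.table::setorder(dt, patient_id, k)
  patients <- unique(dt$patient_id)
  n <- length(patients)
  pi_ <- match(dt$patient_id, patients)
  preds <- default_predictors(dt)
  X <- as.matrix(dt[, preds, with = FALSE]); storage.mode(X) <- "double"
  h <- cumulative_weights(dt, fits, regime_arm,
                          truncation_spec("absolute", cap = weight_cap),
                          convention = "strict")
  ke <- rep(Inf, n)
  evr <- which(dt$Y == 1L)
  ke[pi_[evr]] <- dt$k[evr]
  rows_k <- split(seq_len(nrow(dt)), dt$k)
  list(dt = dt, X = X, h = h, pi = pi_, ke = ke, n = n,
       patients = patients, rows_k = rows_k)
}

# One sequential-regression (ICE) pass for horizon m intervals.
# If q_ext is given (a list of prediction functions indexed j+1), the
# outcome regressions are not refit. target=FALSE skips the fluctuation
# (plain ICE g-computation; used to train oracle Q fits).
.tmle_one <- function(prep, m, q_learner, q_ext = NULL, target = TRUE) {
  n <- prep$n
  ic <- numeric(n)
  z <- ifelse(prep$ke < m, 1, 0)    # valid for patients observed through m
  fits_out <- vector("list", m)
  fallback <- FALSE
  for (j in rev(seq_len(m)) - 1L) {
    rows <- prep$rows_k[[as.character(j)]]
    if (is.null(rows)) rows <- integer(0)
    reg <- rows[prep$h[rows] > 0]
    zz <- ifelse(prep$ke[prep$pi[reg]] == j, 1, z[prep$pi[reg]])
    Xr <- prep$X[reg, , drop = FALSE]
    qf <- if (!is.null(q_ext)) q_ext[[j + 1L]]
          else fit_q(Xr, zz, q_learner)
    fits_out[[j + 1L]] <- qf
    q_reg <- .bound(qf(Xr))
    eps <- 0
    if (target && length(reg) && (var(zz) > 0 || var(q_reg) > 0 ||
                                  abs(mean(zz) - mean(q_reg)) > 0)) {
      sol <- solve_fluctuation(qlogis(q_reg), zz, prep$h[reg])
      eps <- sol$eps
      if (!sol$ok) fallback <- TRUE
    }
    q_star_reg <- plogis(qlogis(q_reg) + eps)
    if (target && length(reg))
      ic[prep$pi[reg]] <- ic[prep$pi[reg]] + prep$h[reg] * (zz - q_star_reg)
    # update z for every patient with a row at j (predictions under regime)
    q_all <- plogis(qlogis(.bound(qf(prep$X[rows, , drop = FALSE]))) + eps)
    z_new <- z
    z_new[prep$pi[rows]] <- q_all
    z_new[prep$ke < j] <- 1
    z <- z_new
  }
  Fm <- mean(z)     # every patient has a row at k = 0
  ic <- ic + z - Fm
  list(F = Fm, ic = ic, fits = fits_out, fallback = fallback)
}

#' Longitudinal TMLE for counterfactual cumulative incidence
#'
#' Sequential-regression (iterated conditional expectation) TMLE: for each
#' reporting horizon, the iterated outcome is regressed backwards over
#' intervals on covariate history among at-risk, uncensored rows of the
#' regime arm, and each step is targeted by a weighted intercept-only
#' logistic fluctuation whose weight is the cumulative inverse-probability
#' product (truncated at `weight_cap`). Influence-curve SEs come from the
#' standard sequential-regression efficient influence curve plus plug-in
#' residual. Monotonicity across horizons is enforced by isotonic
#' projection and flagged when applied.
#'
#' @param long A `person_time` dataset.
#' @param fits Nuisance fits (list with `initiation`, `censoring`), fitted
#'   or oracle ([truth_nuisance()]).
#' @param regime_arm Arm whose counterfactual curve is estimated.
#' @param horizons Integer vector of horizons (in intervals) to report;
#'   default all `1..K`.
#' @param q_learner Outcome-regression learner: `"lasso"` (default),
#'   `"glm"`, or `"intercept"`.
#' @param weight_cap Absolute truncation of cumulative weights used in the
#'   fluctuation (default 200).
#' @param q_external Optional externally trained outcome regressions, as
#'   returned by [train_ice_q()]; if supplied, `q_learner` is ignored.
#' @return A `cuminc_curve` (estimator `"tmle"`).
#' @export
tmle_cuminc <- function(long, fits, regime_arm, horizons = NULL,
                        q_learner = c("lasso", "glm", "intercept"),
                        weight_cap = 200, q_external = NULL) {
  q_learner <- match.arg(q_learner)
  prep <- .tmle_prep(long, fits, regime_arm, weight_cap)
  K <- max(prep$dt$k) + 1L
  if (is.null(horizons)) horizons <- seq_len(K)
  if (any(horizons < 1L | horizons > K)) stop("horizons must lie in 1..K")
  Fv <- numeric(length(horizons))
  ic <- matrix(0, prep$n, length(horizons),
               dimnames = list(prep$patients, horizons))
  fallback <- FALSE
  for (s in seq_along(horizons)) {
    m <- horizons[s]
    qe <- if (!is.null(q_external)) q_external[[as.character(m)]] else NULL
    r <- .tmle_one(prep, m, q_learner, q_ext = qe)
    Fv[s] <- r$F; ic[, s] <- r$ic
    fallback <- fallback || r$fallback
  }
  projected <- FALSE
  if (length(Fv) > 1L && any(diff(Fv) < 0)) {
    Fv <- isoreg(horizons, Fv)$yf
    projected <- TRUE
  }
  se <- sqrt(colMeans(ic^2) / prep$n)
  curve <- data.table::data.table(k = horizons, F = Fv, se = se,
                                  lcl = pmax(Fv - qnorm(.975) * se, 0),
                                  ucl = pmin(Fv + qnorm(.975) * se, 1))
  structure(list(curve = curve, ic = ic, estimator = "tmle",
                 regime = regime_arm, n = prep$n, truncated_at = NA_integer_,
                 monotone_projected = projected,
                 fluctuation_fallback = fallback),
            class = "cuminc_curve")
}

#' Train oracle outcome regressions on an independent dataset
#'
#' Runs the untargeted sequential-regression pass on (typically large)
#' external data and returns the per-step outcome regressions, to be passed
#' to [tmle_cuminc()] as `q_external`. Used to supply correctly specified
#' outcome regressions in validation studies.
#'
#' @param long A `person_time` dataset (training data).
#' @param fits Nuisance fits for the training data (used only to identify
#'   at-risk regime rows).
#' @param regime_arm Arm label.
#' @param horizons Horizons to train for.
#' @param q_learner Outcome-regression learner.
#' @return Named list (by horizon) of lists of prediction functions.
#' @export
train_ice_q <- function(long, fits, regime_arm, horizons,
                        q_learner = "glm") {
  prep <- .tmle_prep(long, fits, regime_arm, weight_cap = 200)
  out <- list()
  for (m in horizons) {
    r <- .tmle_one(prep, m, q_learner, target = FALSE)
    out[[as.character(m)]] <- r$fits
  }
  out
}

#' Exact g-computation by enumeration of a finite-support world
#'
#' Computes the exact counterfactual cumulative incidence under a static
#' regime by summing per-interval event probabilities over all covariate
#' histories weighted by their intervened probabilities. Serves as the
#' oracle for saturated-equivalence and double-robustness checks.
#'
#' @param spec List describing the discrete world: `baseline` (a list with
#'   `states` -- a list of covariate states -- and `probs`), `hazard` --
#'   `function(j, arm, hist)` returning the interval-`j` event probability
#'   given the history (list of states so far), and `transition` --
#'   `function(j, arm, hist)` returning `list(states, probs)` for the next
#'   covariate state (may be `NULL` for static worlds).
#' @param regime_arm Arm passed through to `hazard`/`transition`.
#' @param horizon Number of intervals.
#' @param max_support Maximum number of histories (default 1e5).
#' @return Numeric vector `F(1..horizon)` of exact cumulative incidence.
#' @export
gcomp_enumerate <- function(spec, regime_arm, horizon, max_support = 1e5) {
  Fk <- numeric(horizon)
  count <- 0L
  rec <- function(j, hist, mass, surv) {
    if (mass == 0) return()
    h <- spec$hazard(j, regime_arm, hist)
    if (h < 0 || h > 1) stop("hazard outside [0, 1]")
    Fk[(j + 1L):horizon] <<- Fk[(j + 1L):horizon] + mass * surv * h
    if (j + 1L >= horizon) return()
    surv2 <- surv * (1 - h)
    if (is.null(spec$transition)) {
      rec(j + 1L, hist, mass, surv2)
    } else {
      tr <- spec$transition(j, regime_arm, hist)
      for (s in seq_along(tr$states)) {
        count <<- count + 1L
        if (count > max_support) stop("support too large (> ", max_support,
                                      " histories)")
        rec(j + 1L, c(hist, list(tr$states[[s]])), mass * tr$probs[s], surv2)
      }
    }
  }
  for (b in seq_along(spec$baseline$states)) {
    count <- count + 1L
    rec(0L, list(spec$baseline$states[[b]]), spec$baseline$probs[b], 1)
  }
  Fk
}

#' Influence-curve variance, CI and p-value
#'
#' @param ic Influence-curve values (mean approximately zero).
#' @param estimate Point estimate the CI is centred on.
#' @param n Sample size (default `length(ic)`).
#' @return List with `se` (`sqrt(mean(ic^2)/n)` up to centering), `lcl`,
#'   `ucl` (95% normal limits) and `p` (two-sided).
#' @export
ic_variance <- function(ic, estimate = 0, n = length(ic)) {
  if (n < 2L) stop("need at least 2 observations")
  v <- mean((ic - mean(ic))^2)
  se <- sqrt(v / n)
  z <- if (se > 0) estimate / se else if (estimate == 0) 0 else Inf
  list(se = se, lcl = estimate - qnorm(.975) * se,
       ucl = estimate + qnorm(.975) * se,
       p = 2 * pnorm(-abs(z)))
}
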
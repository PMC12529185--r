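test_that("unit-weight product-limit is the empirical cumulative incidence", {
  # 10 patients, no censoring; 2 events in the first interval
  rows <- do.call(rbind, lapply(1:10, function(i) {
    ev <- i <= 2
    data.frame(patient_id = sprintf("p%02d", i), k = if (ev) 0L else 0:2,
               arm = "A", Y = if (ev) 1L else 0L, C = "none")
  }))
  long <- make_long(rows)
  cu <- product_limit_cuminc(long, unit_weights(long, "A"), "A",
                             "unadjusted")
  expect_equal(cu$curve$F[1], 0.2)
  # scale invariance: constant weights c > 0 change nothing
  cu2 <- product_limit_cuminc(long, 7 * unit_weights(long, "A"), "A")
  expect_equal(cu2$curve$F, cu$curve$F)
})

test_that("weighted product-limit matches a hand computation", {
  # 4 patients, 2 intervals, known weights
  long <- make_long(data.frame(
    patient_id = rep(c("a", "b", "c", "d"), times = c(1, 2, 2, 2)),
    k = c(0L, 0:1, 0:1, 0:1),
    arm = "A",
    Y = c(1L, 0L, 1L, 0L, 0L, 0L, 0L),
    C = "none"))
  w <- c(2, 1, 1, 3, 3, 1, 1)
  cu <- product_limit_cuminc(long, w, "A")
  lam0 <- 2 / (2 + 1 + 3 + 1)          # weighted events / at-risk at k=0
  lam1 <- 1 / (1 + 3 + 1)
  expect_equal(cu$curve$F[1], lam0)
  expect_equal(cu$curve$F[2], 1 - (1 - lam0) * (1 - lam1))
})

test_that("unit-weight product-limit equals one minus Kaplan-Meier", {
  skip_if_not_installed("survival")
  tb <- generate_population(scen_randomized(41, n = 800, horizon_days = 300))
  long <- pipeline_long(tb, protocol_spec("ITT", 10,
                                          covariate_kinds = std_kinds))
  dt <- data.table::as.data.table(long)[arm == "su"]
  cu <- product_limit_cuminc(long, unit_weights(long, "su"), "su",
                             "unadjusted")
  # discrete times: event in interval k -> time k + 1 with status 1;
  # censoring acts at the interval end -> censored at time k + 1
  fu <- dt[, list(time = max(k) + 1L, status = as.integer(sum(Y) > 0)),
           by = "patient_id"]
  km <- survival::survfit(survival::Surv(time, status) ~ 1, data = fu)
  F_km <- 1 - summary(km, times = cu$curve$k)$surv
  expect_equal(cu$curve$F, F_km, tolerance = 1e-12)
})

test_that("curves truncate with a flag when an interval loses all weight", {
  long <- make_long(data.frame(patient_id = c("a", "a", "c", "c", "c"),
                               k = c(0L, 1L, 0L, 1L, 2L), arm = "A",
                               Y = 0L, C = "none"))
  w <- c(1, 0, 1, 0, 1)
  cu <- product_limit_cuminc(long, w, "A")
  expect_equal(cu$truncated_at, 1L)
  expect_equal(nrow(cu$curve), 1L)
})

test_that("TMLE matches the empirical incidence under no confounding", {
  cfg <- scen_randomized(42, n = 2000, horizon_days = 180)
  tb <- generate_population(cfg)
  long <- pipeline_long(tb, protocol_spec("PP", 6,
                                          covariate_kinds = std_kinds))
  fits <- fit_all_nuisances(long)
  tm <- tmle_cuminc(long, fits, "su", horizons = 6, q_learner = "glm")
  cu <- product_limit_cuminc(long, unit_weights(long, "su"), "su",
                             "unadjusted")
  se <- sqrt(tm$curve$se[1]^2 + cu$curve$se[6]^2)
  expect_lt(abs(tm$curve$F[1] - cu$curve$F[6]), 3 * se)
  # score equation solved at the reported horizon
  expect_lte(abs(mean(tm$ic[, 1])), 1e-6 * sd(tm$ic[, 1]))
})

test_that("TMLE with no events returns zero risk and zero influence", {
  long <- make_long(data.frame(
    patient_id = rep(sprintf("p%02d", 1:20), each = 3),
    k = rep(0:2, 20), arm = "A", Y = 0L, C = "none",
    L_x = rnorm(60), M_x = 1L))
  fits <- list(initiation = manual_init_fit(long, 1),
               censoring = list(manual_cens_fit(long, 0)))
  tm <- tmle_cuminc(long, fits, "A", horizons = 3, q_learner = "glm")
  expect_equal(tm$curve$F, 0, tolerance = 1e-9)
  expect_lt(max(abs(tm$ic)), 1e-9)
})

test_that("exact enumeration reproduces closed forms and hand computations", {
  # constant hazard, K = 3: F = 1 - (1-p)^3
  spec_const <- list(baseline = list(states = list(c(l = 0)), probs = 1),
                     hazard = function(j, a, hist) 0.1,
                     transition = NULL)
  expect_equal(gcomp_enumerate(spec_const, "A", 3),
               1 - (1 - 0.1)^(1:3))
  # null effect: identical across regimes by symmetry
  spec_null <- list(baseline = list(states = list(c(l = 0), c(l = 1)),
                                    probs = c(0.4, 0.6)),
                    hazard = function(j, a, hist) 0.05 + 0.1 * hist[[1]]["l"],
                    transition = NULL)
  expect_identical(gcomp_enumerate(spec_null, "A", 2),
                   gcomp_enumerate(spec_null, "B", 2))
  # 2-period binary confounder, hand-computed by total probability
  spec2 <- list(
    baseline = list(states = list(c(l0 = 0), c(l0 = 1)), probs = c(0.5, 0.5)),
    hazard = function(j, a, hist) {
      if (j == 0) 0.1 + 0.1 * hist[[1]]["l0"] + 0.05 * (a == "t")
      else 0.05 + 0.2 * hist[[2]]["l1"]
    },
    transition = function(j, a, hist) {
      p1 <- if (hist[[1]]["l0"] == 1) 0.7 else 0.3
      list(states = list(c(l1 = 0), c(l1 = 1)), probs = c(1 - p1, p1))
    })
  # l0 = 0: h0 = .15; P(l1=1) = .3 -> E h1 = .7*.05 + .3*.25
  # l0 = 1: h0 = .25; P(l1=1) = .7 -> E h1 = .3*.05 + .7*.25
  F1 <- unname(0.5 * (0.15 + 0.85 * (0.7 * 0.05 + 0.3 * 0.25)) +
                 0.5 * (0.25 + 0.75 * (0.3 * 0.05 + 0.7 * 0.25)))
  expect_equal(gcomp_enumerate(spec2, "t", 2)[2], F1, tolerance = 1e-12)
  # support guard
  spec_big <- list(baseline = list(states = list(c(l = 0)), probs = 1),
                   hazard = function(j, a, hist) 0.01,
                   transition = function(j, a, hist)
                     list(states = as.list(1:60), probs = rep(1 / 60, 60)))
  expect_error(gcomp_enumerate(spec_big, "A", 4, max_support = 1000),
               "support too large")
})

test_that("influence-curve variance follows its closed form", {
  expect_equal(ic_variance(rep(0, 10))$se, 0)
  ic <- rep(c(1, -1), 50)
  v <- ic_variance(ic, estimate = 0.3)
  expect_equal(v$se, 0.1)
  expect_equal(v$lcl, 0.3 - qnorm(.975) * 0.1)
  expect_error(ic_variance(1), "at least 2")
})

test_that("estimators coincide under randomization within Monte-Carlo error", {
  cfg <- scen_randomized(43, n = 1500, horizon_days = 180)
  tb <- generate_population(cfg)
  long <- pipeline_long(tb, protocol_spec("PP", 6,
                                          covariate_kinds = std_kinds))
  fits <- fit_all_nuisances(long)
  a <- "glp1ra"
  cu <- product_limit_cuminc(long, unit_weights(long, a), a, "unadjusted")
  ci <- product_limit_cuminc(long, cumulative_weights(long, fits, a), a)
  tm <- tmle_cuminc(long, fits, a, horizons = 6, q_learner = "glm")
  se_ui <- sqrt(cu$curve$se[6]^2 + ci$curve$se[6]^2)
  expect_lt(abs(cu$curve$F[6] - ci$curve$F[6]), 3 * se_ui)
  se_ut <- sqrt(cu$curve$se[6]^2 + tm$curve$se[1]^2)
  expect_lt(abs(cu$curve$F[6] - tm$curve$F[1]), 3 * se_ut)
})
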
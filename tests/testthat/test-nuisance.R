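test_that("super learner concentrates weight on the data-generating model", {
  set.seed(31)
  n <- 5000
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 1.2 * x1 - 0.8 * x2))
  d <- data.frame(y = y, x1 = x1, x2 = x2)
  sl <- fit_super_learner(d, "y", c("x1", "x2"),
                          learner_library(c("glm", "intercept"), 10, 1))
  expect_gte(unname(sl$weights["glm"]), 0.9)
  # CV-loss dominance over every single learner
  expect_lte(sl$sl_cv_loss, min(sl$cv_loss) + 1e-8)
})

test_that("degenerate targets yield flagged constant predictors", {
  d <- data.frame(y = rep(0L, 100), x = rnorm(100))
  sl <- fit_super_learner(d, "y", "x", std_lib())
  expect_true(sl$constant)
  expect_lt(max(sl$predict(d)), 1e-5)
})

test_that("a single-learner library is that learner exactly", {
  set.seed(32)
  d <- data.frame(y = rbinom(200, 1, 0.4), x = rnorm(200))
  sl <- fit_super_learner(d, "y", "x",
                          learner_library("glm", cv_folds = 5, seed = 1))
  fit <- glm(y ~ x, binomial, d)
  expect_equal(unname(sl$predict(d)),
               unname(predict(fit, type = "response")), tolerance = 1e-6)
})

test_that("initiation propensities recover the marginal share under randomization", {
  tb <- generate_population(scen_randomized(33, n = 2000, horizon_days = 180))
  long <- pipeline_long(tb, protocol_spec("PP", 6,
                                          covariate_kinds = std_kinds))
  fit <- fit_propensity_series(long, "initiation", std_lib())
  share <- mean(long$arm[long$k == 0] == "su")
  p_su <- fit$pred$su
  se3 <- 3 * sqrt(0.25 / sum(long$k == 0))
  expect_lt(abs(mean(p_su) - share), se3)
  # bounded predictions
  expect_true(all(fit$pred$g_init >= 0.005 & fit$pred$g_init <= 0.995))
})

test_that("absent censoring causes give survival probabilities of one", {
  tb <- generate_population(scenario_config(
    n_patients = 300, horizon_days = 180,
    censoring_model = list(disenrollment = c(intercept = -20),
                           noncv_death = c(intercept = -20)),
    seed = 34))
  long <- pipeline_long(tb, protocol_spec("ITT", 6,
                                          covariate_kinds = std_kinds))
  fit <- fit_propensity_series(long, "censor_disenrollment", std_lib())
  expect_lt(max(fit$pred$p), 1e-5)   # survival 1 - p is 1 up to the floor
})

test_that("censoring predictions respect the probability floor", {
  tb <- generate_population(scen_confounded(35, n = 600))
  long <- pipeline_long(tb, protocol_spec("PP", 6,
                                          covariate_kinds = std_kinds))
  for (kd in c("censor_disenrollment", "censor_artificial_pp")) {
    fit <- fit_propensity_series(long, kd, std_lib())
    expect_true(all(fit$pred$p >= 0 & fit$pred$p <= 1 - 0.005))
  }
  expect_error(fit_propensity_series(long, "censor_bogus", std_lib()),
               "unknown nuisance kind")
})

test_that("cumulative weights invert the supplied propensities", {
  long <- make_long(data.frame(
    patient_id = rep(c("a", "b"), each = 2),
    k = c(0L, 1L, 0L, 1L), arm = "A", Y = 0L, C = "none"))
  fits1 <- list(initiation = manual_init_fit(long, 1),
                censoring = list(manual_cens_fit(long, 0)))
  expect_equal(cumulative_weights(long, fits1, "A", NULL), rep(1, 4))
  # g = 0.5, no censoring: weight 2 at every interval
  fits2 <- list(initiation = manual_init_fit(long, 0.5),
                censoring = list(manual_cens_fit(long, 0)))
  expect_equal(cumulative_weights(long, fits2, "A", NULL), rep(2, 4))
  # absolute cap: raw weight 1/0.02 = 50 truncated to 20
  fits3 <- list(initiation = manual_init_fit(long, 0.02),
                censoring = list(manual_cens_fit(long, 0)))
  w3 <- cumulative_weights(long, fits3, "A",
                           truncation_spec("absolute", cap = 20))
  expect_equal(w3, rep(20, 4))
  expect_equal(cumulative_weights(long, fits3, "A", NULL), rep(50, 4))
})

test_that("real censoring factors lag one interval; strict factors do not", {
  long <- make_long(data.frame(patient_id = "a", k = 0:2, arm = "A",
                               Y = 0L, C = "none"))
  fits <- list(initiation = manual_init_fit(long, 1),
               censoring = list(manual_cens_fit(long, 0.2)))
  # at-risk convention: factors 1, 1/0.8, 1/0.64
  expect_equal(cumulative_weights(long, fits, "A", NULL),
               c(1, 1.25, 1.5625))
  # strict convention: 1/0.8, 1/0.64, 1/0.512
  expect_equal(cumulative_weights(long, fits, "A", NULL,
                                  convention = "strict"),
               c(1.25, 1.5625, 1.953125))
  # the artificial (deviation) channel is unlagged in both
  fits_dev <- list(initiation = manual_init_fit(long, 1),
                   censoring = list(manual_cens_fit(long, 0.2,
                                                    "censor_artificial_pp")))
  expect_equal(cumulative_weights(long, fits_dev, "A", NULL),
               c(1.25, 1.5625, 1.953125))
})

test_that("percentile truncation alters at most the top tail", {
  set.seed(36)
  long <- make_long(data.frame(patient_id = sprintf("p%04d", 1:2000),
                               k = 0L, arm = "A", Y = 0L, C = "none"))
  g <- runif(2000, 0.05, 0.95)
  fits <- list(initiation = manual_init_fit(long, g),
               censoring = list(manual_cens_fit(long, 0)))
  w_raw <- cumulative_weights(long, fits, "A", NULL)
  w_tr <- cumulative_weights(long, fits, "A",
                             truncation_spec("percentile", percentile = 99))
  expect_lte(mean(w_tr != w_raw), 0.01)
  expect_true(all(w_tr <= quantile(w_raw, 0.99, type = 1) + 1e-12))
})

test_that("mean cumulative weight tracks the regime survival in simulation", {
  cfg <- scen_confounded(37, n = 4000)
  tb <- generate_population(cfg)
  long <- pipeline_long(tb, protocol_spec("PP", 6,
                                          covariate_kinds = std_kinds))
  fits <- truth_nuisance(tb, long, "PP")
  w <- cumulative_weights(long, fits, "su", NULL)
  tru <- true_counterfactual_risk(cfg, regime("su"), 100000)
  n <- length(unique(long$patient_id))
  for (kk in 0:5) {
    m <- sum(w[long$k == kk]) / n
    surv <- 1 - c(0, tru$curve$F)[kk + 1L]
    expect_lt(abs(m - surv), 3 * sqrt(var(w[long$k == kk]) * sum(long$k == kk)) / n + 0.02)
  }
})

test_that("truncation specs validate their fields", {
  expect_error(truncation_spec("percentile", percentile = 40), "percentile")
  expect_error(truncation_spec("absolute", cap = 0.5), "cap")
  expect_silent(truncation_spec("none"))
})
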
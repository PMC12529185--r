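# Hand-built micro-EHR: one or two patients, explicit days.
micro <- function(death_day = NA_integer_, death_cause = NA_character_,
                  enrollment_end = 900L, events = NULL, fills = NULL,
                  meas = NULL) {
  pats <- data.frame(patient_id = "p1", enrollment_start = 0L,
                     enrollment_end = enrollment_end,
                     death_day = death_day, death_cause = death_cause)
  if (is.null(fills))
    fills <- data.frame(patient_id = "p1", med_class = "A",
                        dispense_day = 0L, days_supply = 450L)
  if (is.null(events))
    events <- data.frame(patient_id = character(), day = integer(),
                         event_type = character())
  if (is.null(meas))
    meas <- data.frame(patient_id = "p1", day = 0L, covariate = "x",
                       value = 1)
  tiny_tables(pats, fills, meas, events)
}
coh <- data.frame(patient_id = "p1", index_day = 0L, index_class = "A")
spec_pp <- protocol_spec("PP", horizon_intervals = 10,
                         covariate_kinds = c(x = "continuous"))
spec_itt <- protocol_spec("ITT", horizon_intervals = 10,
                          covariate_kinds = c(x = "continuous"))

test_that("an event maps to its 30-day interval and ends the block", {
  tb <- micro(events = data.frame(patient_id = "p1", day = 45L,
                                  event_type = "MI"))
  long <- build_long_dataset(coh, tb$dispensings, tb$measurements,
                             tb$events, tb$patients, spec_pp)
  expect_equal(long$k, c(0L, 1L))
  expect_equal(long$Y, c(0L, 1L))
  expect_true(all(long$C == "none"))
})

test_that("PP adds artificial censoring at the deviation interval; ITT ignores it", {
  fills <- data.frame(patient_id = "p1", med_class = "A",
                      dispense_day = 0L, days_supply = 30L)  # ends day 60
  tb <- micro(fills = fills)
  pp <- build_long_dataset(coh, tb$dispensings, tb$measurements,
                           tb$events, tb$patients, spec_pp)
  expect_equal(pp$k, 0:2)
  expect_equal(pp$C, c("none", "none", "artificial_pp"))
  expect_equal(pp$A, c(1L, 1L, 0L))
  itt <- build_long_dataset(coh, tb$dispensings, tb$measurements,
                            tb$events, tb$patients, spec_itt)
  expect_equal(itt$k, 0:9)
  expect_true(all(itt$C == "none"))
})

test_that("outcome takes precedence over same-interval real censoring", {
  tb <- micro(enrollment_end = 50L,
              events = data.frame(patient_id = "p1", day = 45L,
                                  event_type = "CVA"))
  long <- build_long_dataset(coh, tb$dispensings, tb$measurements,
                             tb$events, tb$patients, spec_pp)
  last <- long[nrow(long)]
  expect_equal(last$Y, 1L)
  expect_equal(last$C, "none")
})

test_that("deaths split into outcome and censoring channels by cause", {
  tb_cv <- micro(death_day = 75L, death_cause = "cardiovascular")
  lcv <- build_long_dataset(coh, tb_cv$dispensings, tb_cv$measurements,
                            tb_cv$events, tb_cv$patients, spec_pp)
  expect_equal(lcv$Y[lcv$k == 2], 1L)
  tb_nc <- micro(death_day = 75L, death_cause = "noncardiovascular")
  lnc <- build_long_dataset(coh, tb_nc$dispensings, tb_nc$measurements,
                            tb_nc$events, tb_nc$patients, spec_pp)
  expect_equal(lnc$C[lnc$k == 2], "noncv_death")
  expect_equal(lnc$Y[lnc$k == 2], 0L)
  tb_uk <- micro(death_day = 5L, death_cause = "unknown")
  luk <- build_long_dataset(coh, tb_uk$dispensings, tb_uk$measurements,
                            tb_uk$events, tb_uk$patients, spec_pp)
  expect_equal(luk$C, "unknown_death")
})

test_that("a deviation preceding a same-interval event censors first under PP", {
  # coverage ends day 60 (deviation at interval 2); MACE on day 70
  fills <- data.frame(patient_id = "p1", med_class = "A",
                      dispense_day = 0L, days_supply = 30L)
  tb <- micro(fills = fills,
              events = data.frame(patient_id = "p1", day = 70L,
                                  event_type = "MI"))
  pp <- build_long_dataset(coh, tb$dispensings, tb$measurements,
                           tb$events, tb$patients, spec_pp)
  expect_equal(pp$C[pp$k == 2], "artificial_pp")
  expect_equal(sum(pp$Y), 0L)
  itt <- build_long_dataset(coh, tb$dispensings, tb$measurements,
                            tb$events, tb$patients, spec_itt)
  expect_equal(itt$Y[itt$k == 2], 1L)
})

test_that("events before the index day are rejected", {
  coh2 <- data.frame(patient_id = "p1", index_day = 60L, index_class = "A")
  fills <- data.frame(patient_id = "p1", med_class = "A",
                      dispense_day = 60L, days_supply = 450L)
  tb <- micro(fills = fills,
              events = data.frame(patient_id = "p1", day = 10L,
                                  event_type = "MI"))
  expect_error(build_long_dataset(coh2, tb$dispensings, tb$measurements,
                                  tb$events, tb$patients, spec_pp),
               "before index")
})

test_that("missingness encoding carries values forward and imputes baselines", {
  co3 <- data.frame(patient_id = c("p1", "p2", "p3"), index_day = 0L)
  meas <- data.frame(
    patient_id = c("p1", "p1", "p2", "p2", "p2"),
    day = c(0L, 90L, 0L, 65L, 80L),
    covariate = "x",
    value = c(5, 7, 12, 100, 9))
  got <- encode_missingness(meas, co3, n_intervals = 5L,
                            covariate_kinds = c(x = "continuous"))
  p1 <- got[got$patient_id == "p1"]
  # LOCF: observed at k=0 and k=3; queried at k=2 -> k=0 value, M=0
  expect_equal(p1$L_x, c(5, 5, 5, 7, 7))
  expect_equal(p1$M_x, c(1L, 0L, 0L, 1L, 0L))
  # two measurements in one interval (days 65, 80 in k=2): later one wins
  p2 <- got[got$patient_id == "p2"]
  expect_equal(p2$L_x[3], 9)
  expect_equal(p2$M_x[3], 1L)
  # p3 never observed: cohort baseline mean of observed baselines (5, 12)
  p3 <- got[got$patient_id == "p3"]
  expect_equal(p3$L_x, rep(8.5, 5))
  expect_equal(p3$M_x, rep(0L, 5))
  # categorical covariates impute the mode
  got2 <- encode_missingness(rbind(meas,
                                   data.frame(patient_id = "p2", day = 0L,
                                              covariate = "b", value = 1),
                                   data.frame(patient_id = "p1", day = 0L,
                                              covariate = "b", value = 1)),
                             co3, 2L, covariate_kinds = c(b = "categorical"))
  expect_equal(got2$L_b[got2$patient_id == "p3"], c(1, 1))
  # no observed baseline anywhere: error
  expect_error(encode_missingness(
    data.frame(patient_id = "p9", day = 0L, covariate = "z", value = 1),
    co3, 2L), "baseline")
})

test_that("PP at-risk rows are a prefix of the ITT rows for every patient", {
  tb <- generate_population(scen_confounded(21, n = 400))
  pp <- pipeline_long(tb, protocol_spec("PP", 6, covariate_kinds = std_kinds))
  itt <- pipeline_long(tb, protocol_spec("ITT", 6,
                                         covariate_kinds = std_kinds))
  ppr <- as.data.frame(pp[pp$C == "none", c("patient_id", "k", "Y")])
  for (p in unique(ppr$patient_id)) {
    a <- ppr[ppr$patient_id == p, ]
    b <- as.data.frame(itt[itt$patient_id == p, c("patient_id", "k", "Y")])
    expect_true(nrow(a) <= nrow(b))
    expect_equal(a$k, b$k[seq_len(nrow(a))])
    expect_equal(a$Y, b$Y[seq_len(nrow(a))])
  }
})

test_that("rows are contiguous with nothing after the first terminal", {
  tb <- generate_population(scen_confounded(22, n = 400))
  long <- pipeline_long(tb, protocol_spec("PP", 8,
                                          covariate_kinds = std_kinds))
  dt <- data.table::as.data.table(long)
  chk <- dt[, list(contig = all(k == seq_len(.N) - 1L),
                   terminals = sum(C != "none") + sum(Y),
                   term_last = all(which(C != "none" | Y == 1L) %in% .N)),
            by = "patient_id"]
  expect_true(all(chk$contig))
  expect_true(all(chk$terminals <= 1L))
  expect_true(all(chk$term_last))
  # row-count conservation against the follow-up summary
  fu <- attr(long, "followup")
  expect_equal(nrow(long), sum(fu$k_end + 1L))
})
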
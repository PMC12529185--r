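# Sensitivity analyses: weight-truncation variants, g-values for
# unmeasured confounding, and alternative outcome definitions.

#' Re-estimate contrasts under alternative weight truncations
#'
#' Recomputes IPW cumulative-incidence contrasts under each truncation
#' specification without refitting any nuisance model, and reports the
#' fraction of positive weights altered by each cap.
#'
#' @param state A `pipeline_state` from [fit_pipeline()].
#' @param specs Named list of [truncation_spec()] objects.
#' @param arms `c(treated, control)`; default: last vs first arm.
#' @return `data.table` with one row per spec: RD estimate, SE, CI, and
#'   the fraction of positive weights altered.
#' @export
truncation_sweep <- function(state, specs, arms = NULL) {
  if (is.null(arms)) arms <- c(state$arms[length(state$arms)],
                               state$arms[1L])
  long <- state$long
  raw1 <- cumulative_weights(long, state$fits, arms[1L], NULL)
  raw0 <- cumulative_weights(long, state$fits, arms[2L], NULL)
  out <- lapply(names(specs), function(nm) {
    tr <- specs[[nm]]
    w1 <- raw1; w0 <- raw0
    w1[w1 > 0] <- apply_truncation(w1[w1 > 0], tr)
    w0[w0 > 0] <- apply_truncation(w0[w0 > 0], tr)
    altered <- (sum(w1[raw1 > 0] != raw1[raw1 > 0]) +
                  sum(w0[raw0 > 0] != raw0[raw0 > 0])) /
      max(sum(raw1 > 0) + sum(raw0 > 0), 1L)
    c1 <- product_limit_cuminc(long, w1, arms[1L], estimator = "ipw")
    c0 <- product_limit_cuminc(long, w0, arms[2L], estimator = "ipw")
    rd <- risk_difference(c1, c0)
    data.table::data.table(spec = nm, style = tr$style,
                           cap = if (tr$style == "percentile")
                             tr$percentile else tr$cap,
                           rd = rd$rd, se = rd$se, lcl = rd$lcl,
                           ucl = rd$ucl, frac_altered = altered)
  })
  data.table::rbindlist(out)
}

#' g-value: bias needed to nullify a conclusion
#'
#' The smallest additive bias (risk-difference scale) from unmeasured
#' confounding or selection that, applied toward the null, makes the 95%
#' CI include 0: `max(0, |estimate| - 1.96 * se)`. Zero when the CI
#' already includes 0.
#'
#' @param estimate Point estimate (e.g. an RD).
#' @param se Influence-curve SE (> 0).
#' @return List with `g_value` and `g_fraction` (relative to `|estimate|`).
#' @export
g_value <- function(estimate, se) {
  if (se <= 0) stop("se must be positive")
  g <- max(0, abs(estimate) - qnorm(.975) * se)
  list(g_value = g,
       g_fraction = if (estimate == 0) 0 else g / abs(estimate))
}

#' Re-run an emulation under an alternative outcome definition
#'
#' Full re-run (cohort to contrasts) with a different composite outcome,
#' e.g. an expanded cardiovascular-death definition; paired with the
#' primary report for side-by-side comparison.
#'
#' @param tables A `raw_tables` object (or [scenario_config()]).
#' @param spec The primary [protocol_spec()].
#' @param outcome_types Alternative event-type set.
#' @param known_types Event/death types that can occur in the data (used to
#'   reject empty predicates); defaults to the standard channels.
#' @param ... Passed to [run_emulation()].
#' @return An `emulation_report` for the alternative outcome.
#' @export
outcome_variant <- function(tables, spec, outcome_types,
                            known_types = c("MI", "CVA", "cv_death",
                                            "noncv_death", "unknown_death"),
                            ...) {
  if (!any(outcome_types %in% known_types))
    stop("alternative outcome matches no known event type")
  spec2 <- spec
  spec2$outcome_types <- outcome_types
  run_emulation(tables, spec = spec2, ...)
}
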
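#' Trough-guided maintenance dose adjustment rule
#'
#' The individualized maintenance strategy measures the trough before the
#' 2nd and before the 3rd maintenance dose and adjusts:
#' \itemize{
#'   \item trough below the low cutoff (100 mg/L at the 2nd-dose check,
#'     50 mg/L at the 3rd-dose check): dose increased by 300 mg, interval
#'     unchanged;
#'   \item trough in the middle band (up to 200 mg/L): no change;
#'   \item trough at or above 200 mg/L: interval extended by 7 days, dose
#'     unchanged.
#' }
#' Thresholds are half-open as printed: the low band is `[0, low)`, the
#' middle band `[low, 200)` and `>= 200` triggers extension. Interval
#' extensions compound across the two checkpoints up to a 28-day cap.
#'
#' @param checkpoint `"before_2nd_dose"` or `"before_3rd_dose"`.
#' @param trough Measured (or model-predicted) trough, mg/L.
#' @param current_dose Current maintenance dose, mg.
#' @param current_interval Current maintenance interval, days.
#' @param low_2nd,low_3rd,high Policy thresholds, mg/L.
#' @param dose_increment Dose step, mg.
#' @param interval_increment Interval step, days.
#' @param interval_cap Maximum interval, days.
#' @return A list with elements `dose` and `interval`.
#' @export
#' @examples
#' tdm_adjust("before_2nd_dose", 80, 1200, 14)   # -> 1500 mg q14d
#' tdm_adjust("before_3rd_dose", 220, 1200, 21)  # -> 1200 mg q28d
tdm_adjust <- function(checkpoint = c("before_2nd_dose", "before_3rd_dose"),
                       trough, current_dose, current_interval,
                       low_2nd = 100, low_3rd = 50, high = 200,
                       dose_increment = 300, interval_increment = 7,
                       interval_cap = 28) {
  checkpoint <- match.arg(checkpoint)
  if (trough < 0) abort("`trough` must be nonnegative")
  low <- if (checkpoint == "before_2nd_dose") low_2nd else low_3rd
  dose <- current_dose
  interval <- current_interval
  if (trough < low) {
    dose <- dose + dose_increment
  } else if (trough >= high) {
    interval <- min(interval + interval_increment, interval_cap)
  }
  list(dose = dose, interval = interval)
}

#' Simulate an individualized (TDM-guided) maintenance course
#'
#' Simulates a maintenance-phase course from a drug-free start: the first
#' maintenance dose (the subject's label-band maintenance dose) at t = 0,
#' then [tdm_adjust()] applied to the trough measured immediately before
#' the 2nd and before the 3rd maintenance dose, re-solving the profile
#' after each change. A dose increase applies from the dose following the
#' measurement; an interval extension lengthens the interval that starts
#' at that dose. After the 3rd maintenance dose the regimen is held fixed
#' for the rest of the horizon. Checkpoint troughs are error-free model
#' predictions by default; with `measure_with_error = TRUE` they are
#' perturbed by the Radboudumc PK residual-error model.
#'
#' @param ind Individual parameters (one-row `ecu_individuals` tibble or
#'   list).
#' @param weight Body weight, kg.
#' @param horizon Days of treatment to schedule (>= 3 maintenance
#'   intervals).
#' @param measure_with_error Perturb checkpoint troughs with assay error?
#' @param pk Population PK parameters (for the residual-error model).
#' @param seed Seed for the measurement error draws.
#' @param rtol,atol Solver tolerances.
#' @return A list of class `ecu_tdm_course`: `doses` (realized dose-event
#'   tibble), `dose_final`, `interval_final`, `troughs` (the two
#'   checkpoint measurements), `dose_history`, `interval_history`,
#'   `third_dose_time`.
#' @export
simulate_tdm_course <- function(ind, weight, horizon = 365.25,
                                measure_with_error = FALSE,
                                pk = pk_parameters(), seed = NULL,
                                rtol = 1e-8, atol = 1e-10) {
  ind <- ind_row(ind)
  b <- band_row(label_band_table, weight)
  dose0 <- b$maint_dose
  int0 <- b$maint_interval
  if (horizon < 3 * int0)
    abort("`horizon` must cover at least 3 maintenance intervals")

  doses <- tibble(time = 0, amount = dose0, duration = 0)
  dose_hist <- dose0
  int_hist <- int0
  troughs <- numeric(2)
  dose_cur <- dose0
  int_cur <- int0
  t_next <- int0 # time of the 2nd maintenance dose

  for (k in 1:2) {
    prof <- solve_profile(ind, doses, times = c(0, t_next), with_cp = FALSE,
                          rtol = rtol, atol = atol)
    tr <- prof$conc[2]
    if (measure_with_error) {
      tr <- apply_residual_error(tr, "pk_radboud", pk = pk,
                                 seed = if (is.null(seed)) NULL else seed + k)
    }
    troughs[k] <- tr
    adj <- tdm_adjust(if (k == 1) "before_2nd_dose" else "before_3rd_dose",
                      tr, dose_cur, int_cur)
    dose_cur <- adj$dose
    int_cur <- adj$interval
    dose_hist <- c(dose_hist, dose_cur)
    int_hist <- c(int_hist, int_cur)
    doses <- bind_rows(doses, tibble(time = t_next, amount = dose_cur, duration = 0))
    t_next <- t_next + int_cur
  }
  third_dose_time <- t_next - int_cur

  # post-3rd-dose regimen held fixed
  if (t_next <= horizon) {
    mt <- seq(t_next, horizon, by = int_cur)
    doses <- bind_rows(doses, tibble(time = mt, amount = rep(dose_cur, length(mt)),
                                     duration = 0))
  }
  structure(list(doses = doses[doses$time <= horizon, ],
                 dose_final = dose_cur, interval_final = int_cur,
                 troughs = troughs,
                 dose_history = dose_hist, interval_history = int_hist,
                 dose_initial = dose0, interval_initial = int0,
                 third_dose_time = third_dose_time,
                 weight = weight),
            class = "ecu_tdm_course")
}

#' @export
print.ecu_tdm_course <- function(x, ...) {
  cat(sprintf("<TDM-guided maintenance course, %g kg>\n", x$weight))
  cat(sprintf("  checkpoint troughs: %.1f, %.1f mg/L\n", x$troughs[1], x$troughs[2]))
  cat(sprintf("  realized regimen: %g mg q%gd (started %g mg q%gd)\n",
              x$dose_final, x$interval_final, x$dose_initial, x$interval_initial))
  invisible(x)
}
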
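# Weight-band dose tables. Bands are half-open [lo, hi) except the top band,
# which is closed above; ">= 40 kg" includes 40.0 exactly. All doses are
# multiples of one 300-mg vial. "week k" maps to t = 7*(k-1) days.

# Label regimen: weekly induction doses, then maintenance at a fixed
# interval from `maint_week` onward.
label_band_table <- tibble::tibble(
  lo = c(5, 10, 20, 30, 40),
  hi = c(10, 20, 30, 40, Inf),
  induction = list(300, 600, c(600, 600), c(600, 600), c(900, 900, 900, 900)),
  maint_week = c(2, 2, 3, 3, 5),
  maint_dose = c(300, 300, 600, 900, 1200),
  maint_interval = c(21, 14, 14, 14, 14)
)

# Weight-based single loading dose (day 1), second dose on day 15, then the
# label maintenance dose and interval of the subject's label band.
loading_band_table <- tibble::tribble(
  ~lo, ~hi, ~load_dose, ~day15_dose,
    5,  10,  300,  300,
   10,  20,  600,  300,
   20,  30,  600,  600,
   30,  40,  900,  900,
   40,  60, 1500, 1200,
   60,  90, 1800, 1200,
   90, 120, 2100, 1200,
  120, Inf, 2400, 1200
)

# Fixed 4-week-interval maintenance doses.
q4w_band_table <- tibble::tribble(
  ~lo, ~hi, ~maint_dose,
    5,  10,  900,
   10,  20, 1200,
   20,  30, 1500,
   30,  40, 1800,
   40,  60, 2100,
   60,  90, 2400,
   90, 120, 2700,
  120, Inf, 3000
)

band_row <- function(table, weight) {
  if (weight < 5)
    abort(sprintf("no dosing band for weight %.1f kg (< 5 kg unsupported)", weight))
  i <- which(weight >= table$lo & weight < table$hi)
  stopifnot(length(i) == 1)
  table[i, ]
}

new_regimen <- function(events, name, weight, maint_dose, maint_interval,
                        first_maint_time) {
  out <- events[order(events$time), ]
  attr(out, "name") <- name
  attr(out, "weight") <- weight
  attr(out, "maintenance_dose") <- maint_dose
  attr(out, "maintenance_interval") <- maint_interval
  attr(out, "first_maint_time") <- first_maint_time
  class(out) <- c("ecu_regimen", class(out))
  out
}

maint_times <- function(start, interval, horizon) {
  if (start > horizon) return(numeric())
  seq(start, horizon, by = interval)
}

#' Label (approved) eculizumab dosing regimen
#'
#' Builds the weight-banded approved schedule: for adults and children
#' >= 40 kg, 900 mg weekly on days 1, 8, 15 and 22, then 1200 mg on day 29
#' and every 14 days; paediatric bands follow the label rows, including the
#' 21-day maintenance interval of the 5-10 kg band. "Day d" maps to
#' `t = d - 1` days, first dose at t = 0.
#'
#' @param weight Body weight, kg (must be >= 5).
#' @param horizon Schedule horizon in days; doses are generated for all
#'   times `t <= horizon`.
#' @return An `ecu_regimen`: a tibble of dose events (`time` days, `amount`
#'   mg, `duration` days) with maintenance dose/interval attributes.
#' @export
#' @examples
#' standard_regimen(70, horizon = 28)
standard_regimen <- function(weight, horizon = 365) {
  b <- band_row(label_band_table, weight)
  ind <- b$induction[[1]]
  ev <- tibble(time = 7 * (seq_along(ind) - 1), amount = ind, duration = 0)
  first_m <- 7 * (b$maint_week - 1)
  mt <- maint_times(first_m, b$maint_interval, horizon)
  ev <- bind_rows(ev[ev$time <= horizon, ],
                  tibble(time = mt, amount = rep(b$maint_dose, length(mt)),
                         duration = 0))
  new_regimen(ev, "standard", weight, b$maint_dose, b$maint_interval, first_m)
}

#' Weight-based single loading dose regimen
#'
#' A single weight-banded loading dose on day 1, a second dose on day 15,
#' then the label maintenance dose at the label interval of the subject's
#' band (adults: 1200 mg every 14 days from day 15).
#'
#' @inheritParams standard_regimen
#' @return An `ecu_regimen`.
#' @export
#' @examples
#' alternative_loading_regimen(75, horizon = 28)
alternative_loading_regimen <- function(weight, horizon = 365) {
  b <- band_row(loading_band_table, weight)
  lb <- band_row(label_band_table, weight)
  mt <- maint_times(14, lb$maint_interval, horizon)
  ev <- tibble(time = c(0, mt),
               amount = c(b$load_dose,
                          if (length(mt)) c(b$day15_dose,
                                            rep(lb$maint_dose, length(mt) - 1))),
               duration = 0)
  ev <- ev[ev$time <= horizon, ]
  new_regimen(ev, "alt_loading", weight, lb$maint_dose, lb$maint_interval, 14)
}

#' Fixed 4-week-interval regimen
#'
#' Maintenance doses per the 4-week weight-band table every 28 days,
#' intended e.g. to allow holidays without therapeutic drug monitoring. By
#' default the schedule starts with the label induction phase and switches
#' to the 4-week maintenance at the band's first maintenance time; with
#' `induction = FALSE` the 4-week maintenance starts at t = 0.
#'
#' @inheritParams standard_regimen
#' @param induction Prepend the label induction phase?
#' @return An `ecu_regimen`.
#' @export
#' @examples
#' q4w_regimen(75, horizon = 100)
q4w_regimen <- function(weight, horizon = 365, induction = TRUE) {
  b <- band_row(q4w_band_table, weight)
  if (induction) {
    lb <- band_row(label_band_table, weight)
    ind <- lb$induction[[1]]
    first_m <- 7 * (lb$maint_week - 1)
    ev <- tibble(time = 7 * (seq_along(ind) - 1), amount = ind, duration = 0)
    ev <- ev[ev$time <= horizon, ]
  } else {
    first_m <- 0
    ev <- tibble(time = numeric(), amount = numeric(), duration = numeric())
  }
  mt <- maint_times(first_m, 28, horizon)
  ev <- bind_rows(ev, tibble(time = mt, amount = rep(b$maint_dose, length(mt)),
                             duration = 0))
  new_regimen(ev, "q4w", weight, b$maint_dose, 28, first_m)
}

#' @export
print.ecu_regimen <- function(x, ...) {
  cat(sprintf("<eculizumab regimen '%s', %g kg: maintenance %g mg q%gd from t = %g d>\n",
              attr(x, "name"), attr(x, "weight"), attr(x, "maintenance_dose"),
              attr(x, "maintenance_interval"), attr(x, "first_maint_time")))
  NextMethod()
}

#' Vial-based drug cost
#'
#' Eculizumab is supplied in 300-mg vials at US$6523 per vial; cost is
#' `ceiling(total_mg / 300) * 6523`. All regimen-generated doses are exact
#' vial multiples, so the ceiling is the identity on them.
#'
#' @param total_mg Total administered amount, mg (vectorised).
#' @param vial_mg,vial_usd Vial size and unit price.
#' @return Cost in USD.
#' @export
#' @examples
#' vial_cost(c(900, 1200))
vial_cost <- function(total_mg, vial_mg = 300, vial_usd = 6523) {
  if (any(total_mg < 0)) abort("`total_mg` must be nonnegative")
  ceiling(total_mg / vial_mg) * vial_usd
}

#' Annualized maintenance drug cost
#'
#' Fractional annualization: `(365.25 / interval) * vial_cost(dose)`,
#' giving smoothly comparable yearly costs across 14-, 21- and 28-day
#' intervals. With `fractional = FALSE` the number of doses per year is
#' rounded down to an integer instead.
#'
#' @param maintenance_dose Maintenance dose, mg.
#' @param interval Dosing interval, days.
#' @param fractional Use fractional dose counts (default) or integer.
#' @return Cost in USD per year.
#' @export
#' @examples
#' annualize_cost(1200, 14)
annualize_cost <- function(maintenance_dose, interval, fractional = TRUE) {
  if (any(interval <= 0)) abort("`interval` must be positive")
  n_doses <- 365.25 / interval
  if (!fractional) n_doses <- floor(n_doses)
  n_doses * vial_cost(maintenance_dose)
}
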
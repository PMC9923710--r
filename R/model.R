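#' Sample individual PK-PD parameters for a cohort
#'
#' Draws the realized per-subject parameters: body-weight-scaled typical
#' values multiplied by independent lognormal interindividual random effects
#' `exp(eta)`, `eta ~ N(0, omega^2)` with `omega` from [cv_to_omega()], for
#' CL and V (PK) and Base and IC50 (PD). Vmax, Km, Imax and the Hill
#' coefficient carry no reported variability and are fixed at their (weight
#' scaled, for Vmax) typical values. One lognormal interoccasion multiplier
#' on clearance is drawn per dosing occasion; a new occasion begins at each
#' administration.
#'
#' Each subject uses a deterministic random substream derived from the
#' master seed and the subject index, so the parameters of subject `i` do
#' not depend on cohort size or order.
#'
#' @param cohort An `ecu_cohort` tibble (or any data frame with
#'   `subject_id` and `weight`).
#' @param pk,pd Population parameter objects.
#' @param n_occasions Number of occasion multipliers to pre-draw per subject
#'   (at least the number of doses that will be administered).
#' @param seed Master integer seed.
#' @return A tibble of class `ecu_individuals` with one row per subject:
#'   identifiers, weight, `cl_i`, `v_i`, `vmax_i`, `km_i`, `base_i`,
#'   `ic50_i`, `gamma_i`, `imax_i` and a list-column `occ_cl` of occasion
#'   multipliers.
#' @export
#' @examples
#' cohort <- generate_cohort(5, seed = 1)
#' sample_individuals(cohort, n_occasions = 4, seed = 2)
sample_individuals <- function(cohort, pk = pk_parameters(), pd = pd_parameters(),
                               n_occasions = 40, seed = 1L) {
  stopifnot(is.data.frame(cohort), n_occasions >= 1)
  typ <- scale_by_weight(pk, cohort$weight)
  om_cl <- cv_to_omega(pk$iiv_cl_cv)
  om_v <- cv_to_omega(pk$iiv_v_cv)
  om_occ <- cv_to_omega(pk$iov_cl_cv)
  om_base <- cv_to_omega(pd$iiv_base_cv)
  om_ic50 <- cv_to_omega(pd$iiv_ic50_cv)
  n <- nrow(cohort)
  eta <- matrix(0, n, 4)
  occ <- vector("list", n)
  for (i in seq_len(n)) {
    with_seed(subject_seed(seed, cohort$subject_id[i]), {
      z <- rnorm(4 + n_occasions)
      eta[i, ] <- z[1:4]
      occ[[i]] <- exp(z[-(1:4)] * om_occ)
    })
  }
  out <- tibble(
    subject_id = cohort$subject_id,
    weight = cohort$weight,
    cl_i = typ$cl * exp(eta[, 1] * om_cl),
    v_i = typ$v * exp(eta[, 2] * om_v),
    vmax_i = typ$vmax,
    km_i = typ$km,
    base_i = pd$base * exp(eta[, 3] * om_base),
    ic50_i = pd$ic50 * exp(eta[, 4] * om_ic50),
    gamma_i = pd$gamma,
    imax_i = pd$imax,
    occ_cl = occ)
  class(out) <- c("ecu_individuals", class(out))
  out
}

as_dose_tbl <- function(doses) {
  if (is.null(doses) || (is.data.frame(doses) && nrow(doses) == 0))
    return(tibble(time = numeric(), amount = numeric(), duration = numeric()))
  stopifnot(is.data.frame(doses), all(c("time", "amount") %in% names(doses)))
  if (!("duration" %in% names(doses))) doses$duration <- 0
  if (any(doses$time < 0)) abort("dose times must be nonnegative")
  if (any(doses$amount < 0)) abort("dose amounts must be nonnegative")
  if (is.unsorted(doses$time)) abort("doses must be sorted by time")
  tibble(time = as.double(doses$time), amount = as.double(doses$amount),
         duration = as.double(doses$duration))
}

ind_row <- function(ind) {
  if (is.data.frame(ind)) {
    stopifnot(nrow(ind) == 1)
    ind <- as.list(ind)
    if (is.list(ind$occ_cl)) ind$occ_cl <- ind$occ_cl[[1]]
  }
  ind
}

#' Solve an individual concentration (and CP activity) profile
#'
#' Numerically integrates the one-compartment model
#' `dA/dt = input(t) - (CL_occ/V) A - Vmax (A/V)/(Km + A/V)` over a dosing
#' schedule with an adaptive embedded Runge-Kutta 5(4) method (relative
#' tolerance 1e-8). Bolus doses are instantaneous amount additions; doses
#' with `duration > 0` enter as zero-order infusions. The occasion-specific
#' clearance multiplier applies from each dose onward. At grid times that
#' coincide with a dose the reported value is the pre-dose left limit, i.e.
#' the trough.
#'
#' @param ind A one-row `ecu_individuals` tibble (or a list with fields
#'   `cl_i`, `v_i`, `vmax_i`, `km_i`, optionally `occ_cl` and the PD fields
#'   `base_i`, `ic50_i`, `gamma_i`, `imax_i`).
#' @param doses Data frame of dose events: `time` (days), `amount` (mg),
#'   optional `duration` (days, 0 = bolus).
#' @param times Strictly increasing nonnegative output grid, days.
#' @param with_cp If `TRUE` (default when PD fields are present) the CP
#'   activity is added via [predict_cp_activity()].
#' @param rtol,atol Solver tolerances.
#' @return A tibble (`time`, `conc`, and `cp` when requested).
#' @export
#' @examples
#' ind <- list(cl_i = 0.163, v_i = 6.42, vmax_i = 29.6, km_i = 37.9)
#' doses <- tibble::tibble(time = 0, amount = 1200)
#' solve_profile(ind, doses, times = seq(0, 14, 0.5), with_cp = FALSE)
solve_profile <- function(ind, doses, times, with_cp = NULL,
                          rtol = 1e-8, atol = 1e-10) {
  ind <- ind_row(ind)
  doses <- as_dose_tbl(doses)
  if (any(!is.finite(times)) || any(times < 0))
    abort("`times` must be finite and nonnegative")
  nd <- nrow(doses)
  occ <- ind$occ_cl %||% rep(1, nd)
  if (nd > length(occ))
    abort(sprintf("schedule has %d doses but only %d occasion multipliers", nd, length(occ)))
  cl_occ <- ind$cl_i * occ[seq_len(nd)]
  conc <- .solve_pk_cpp(as.double(times), doses$time, doses$amount,
                        doses$duration, as.double(cl_occ),
                        ind$v_i, ind$vmax_i, ind$km_i, rtol, atol)
  if (any(conc < -1e-9)) abort("solver returned negative concentrations")
  conc <- pmax(conc, 0)
  out <- tibble(time = as.double(times), conc = conc)
  has_pd <- !is.null(ind$base_i)
  if (isTRUE(with_cp) && !has_pd) abort("individual has no PD parameters")
  if (isTRUE(with_cp) || (is.null(with_cp) && has_pd))
    out$cp <- predict_cp_activity(ind, conc)
  out
}

#' Predict classical pathway activity from free drug concentration
#'
#' Inhibitory sigmoid Emax model:
#' `E = Base_i * (1 - Imax * C^gamma / (IC50_i^gamma + C^gamma))`.
#'
#' @param ind Individual parameters (one-row tibble or list with `base_i`,
#'   `ic50_i`, `gamma_i`, `imax_i`).
#' @param conc Free eculizumab concentration(s), mg/L, nonnegative
#'   (`Inf` allowed and maps to the maximal-inhibition asymptote).
#' @return CP activity in %, same length as `conc`.
#' @export
#' @examples
#' typ <- list(base_i = 100.7, ic50_i = 22, gamma_i = 5.42, imax_i = 0.96)
#' predict_cp_activity(typ, c(0, 22, Inf))
predict_cp_activity <- function(ind, conc) {
  ind <- ind_row(ind)
  if (any(is.na(conc)) || any(conc < 0)) abort("`conc` must be nonnegative")
  frac <- ifelse(is.infinite(conc), 1,
                 conc^ind$gamma_i / (ind$ic50_i^ind$gamma_i + conc^ind$gamma_i))
  ind$base_i * (1 - ind$imax_i * frac)
}

#' Concentration at which CP activity crosses a threshold
#'
#' Inverts the sigmoid Emax model: the concentration at which the predicted
#' CP activity equals `threshold` percent. Returns `Inf` when the asymptote
#' `Base (1 - Imax)` lies above the threshold (the target is unattainable)
#' and 0 when even the drug-free baseline is below it.
#'
#' @inheritParams predict_cp_activity
#' @param threshold CP activity threshold, % (default 10, the complete
#'   complement blockade target).
#' @return Concentration in mg/L.
#' @export
cp_threshold_conc <- function(ind, threshold = 10) {
  ind <- ind_row(ind)
  if (threshold <= 0) abort("`threshold` must be positive")
  if (threshold >= ind$base_i) return(0)
  f <- (1 - threshold / ind$base_i) / ind$imax_i
  if (f >= 1) return(Inf)
  ind$ic50_i * (f / (1 - f))^(1 / ind$gamma_i)
}

#' Trough concentration immediately before a dose
#'
#' Returns the profile value at the latest grid point at or before
#' `dose_time`; grid values at dose times are stored as pre-dose left
#' limits, so this is the trough.
#'
#' @param profile A tibble from [solve_profile()].
#' @param dose_time Time of the dose, days.
#' @return Concentration in mg/L.
#' @export
trough_before <- function(profile, dose_time) {
  stopifnot(is.data.frame(profile), all(c("time", "conc") %in% names(profile)))
  if (dose_time > max(profile$time))
    abort("`dose_time` outside the profile time range")
  if (dose_time <= profile$time[1])
    abort("no grid point precedes `dose_time`")
  # a grid value stored exactly at a dose time is the pre-dose left limit
  profile$conc[max(which(profile$time <= dose_time))]
}
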
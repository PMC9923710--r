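#' Specify a virtual dosing trial
#'
#' Bundles a cohort, a dosing strategy and the evaluation settings for
#' [run_trial()]. Strategies `standard` and `alt_loading` default to the
#' loading-phase study (first 28 days of treatment); `standard`, `tdm` and
#' `q4w` can be run as maintenance-phase studies, in which each subject's
#' maintenance course is simulated standalone from a drug-free start
#' (first maintenance dose at t = 0) and followed over one year.
#'
#' @param cohort An `ecu_cohort` tibble (see [generate_cohort()],
#'   [load_cohort()]).
#' @param strategy One of `"standard"`, `"alt_loading"`, `"tdm"`, `"q4w"`.
#' @param phase `"loading"` or `"maintenance"`; defaults to `"loading"` for
#'   the two loading strategies and `"maintenance"` for `tdm` and `q4w`.
#' @param threshold Efficacy target: CP activity below this percentage
#'   counts as complete complement blockade (default 10%).
#' @param grid_dt Evaluation grid step, days.
#' @param eval_days Length of the maintenance evaluation window, days.
#' @param seed Master seed; drives parameter sampling and any measurement
#'   noise.
#' @param pk,pd Population parameter objects.
#' @param measure_with_error Measure TDM checkpoint troughs with assay
#'   residual error instead of noise-free model predictions?
#' @param n_occasions Occasion multipliers pre-drawn per subject.
#' @param continue_on_error Log-and-skip subjects whose solve fails instead
#'   of aborting.
#' @return A list of class `ecu_trial_spec`.
#' @export
trial_spec <- function(cohort,
                       strategy = c("standard", "alt_loading", "tdm", "q4w"),
                       phase = NULL, threshold = 10, grid_dt = 0.1,
                       eval_days = 365.25, seed = 1L,
                       pk = pk_parameters(), pd = pd_parameters(),
                       measure_with_error = FALSE, n_occasions = 80,
                       continue_on_error = FALSE) {
  strategy <- match.arg(strategy)
  if (is.null(phase))
    phase <- if (strategy %in% c("standard", "alt_loading")) "loading" else "maintenance"
  phase <- match.arg(phase, c("loading", "maintenance"))
  if (strategy %in% c("tdm", "q4w") && phase == "loading")
    abort(sprintf("strategy '%s' is a maintenance-phase strategy", strategy))
  if (threshold <= 0 || threshold >= 100) abort("`threshold` must be in (0, 100)")
  structure(list(cohort = cohort, strategy = strategy, phase = phase,
                 threshold = threshold, grid_dt = grid_dt,
                 eval_days = eval_days,
                 seed = seed, pk = pk, pd = pd,
                 measure_with_error = measure_with_error,
                 n_occasions = n_occasions,
                 continue_on_error = continue_on_error),
            class = "ecu_trial_spec")
}

loading_schedule <- function(strategy, weight, horizon) {
  switch(strategy,
         standard = standard_regimen(weight, horizon),
         alt_loading = alternative_loading_regimen(weight, horizon),
         abort("unknown loading strategy"))
}

#' Run a Monte Carlo virtual dosing trial
#'
#' For every cohort subject: sample individual PK-PD parameters, build the
#' strategy's dose schedule (the TDM strategy interacts with the trough
#' policy and re-solves after each adjustment), integrate the concentration
#' profile, map it to CP activity with the sigmoid Emax model, and compute
#' the endpoints. Attainment classification uses noise-free individual CP
#' predictions. Fully reproducible under the spec seed.
#'
#' Loading studies are evaluated on the absolute grid t = 0..28 days of
#' treatment; maintenance studies over one year of maintenance dosing
#' (t = 0..`eval_days` from the first maintenance dose).
#'
#' @param spec An [trial_spec()] object.
#' @return An object of class `ecu_trial`: a list with `attainment`
#'   (tibble: `time`, `fraction`), `subjects` (per-subject endpoint
#'   tibble), `troughs` (pooled maintenance troughs), `q4w_marks`
#'   (attainment 14/21/28 days post-dose, 4-week strategy only), `n_failed`
#'   and the spec metadata.
#' @export
run_trial <- function(spec) {
  stopifnot(inherits(spec, "ecu_trial_spec"))
  cohort <- spec$cohort
  n <- nrow(cohort)
  inds <- sample_individuals(cohort, spec$pk, spec$pd,
                             n_occasions = spec$n_occasions, seed = spec$seed)
  dt <- spec$grid_dt
  loading <- spec$phase == "loading"
  rel_grid <- if (loading) seq(0, 28, by = dt) else seq(0, spec$eval_days, by = dt)
  below_counts <- numeric(length(rel_grid))
  subj_rows <- vector("list", n)
  trough_rows <- vector("list", n)
  q4w_marks <- if (spec$strategy == "q4w") matrix(NA_real_, n, 3) else NULL
  n_failed <- 0L

  for (i in seq_len(n)) {
    ind <- as.list(inds[i, ])
    ind$occ_cl <- ind$occ_cl[[1]]
    w <- cohort$weight[i]
    res <- tryCatch({
      if (loading) {
        reg <- loading_schedule(spec$strategy, w, horizon = 28)
        prof <- solve_profile(ind, reg, times = rel_grid)
        below <- prof$cp < spec$threshold
        cost <- vial_cost(sum(reg$amount[reg$time <= 28]))
        list(below = below, cost = cost, dose_final = NA_real_,
             interval_final = NA_real_, troughs = NULL)
      } else {
        # maintenance-phase study: a standalone maintenance course from a
        # drug-free start (first maintenance dose at t = 0), followed over
        # one year
        t_end <- spec$eval_days
        if (spec$strategy == "tdm") {
          course <- simulate_tdm_course(
            ind, w, horizon = t_end,
            measure_with_error = spec$measure_with_error, pk = spec$pk,
            seed = if (spec$measure_with_error)
              subject_seed(spec$seed + 1L, cohort$subject_id[i]) else NULL)
          interval <- course$interval_final
          dose <- course$dose_final
          doses <- course$doses
          cost <- sum(vial_cost(doses$amount)) # realized-schedule cost
        } else {
          b <- band_row(if (spec$strategy == "q4w") q4w_band_table
                        else label_band_table, w)
          interval <- if (spec$strategy == "q4w") 28 else b$maint_interval
          dose <- b$maint_dose
          mt <- seq(0, t_end, by = interval)
          doses <- tibble(time = mt, amount = rep(dose, length(mt)),
                          duration = 0)
          cost <- annualize_cost(dose, interval)
        }
        prof <- solve_profile(ind, doses, times = rel_grid)
        below <- prof$cp < spec$threshold
        dose_times <- doses$time[doses$time > 0] # pre-dose troughs
        tr <- prof$conc[match(round(dose_times, 6), round(rel_grid, 6))]
        tr <- tr[!is.na(tr)]
        if (spec$strategy == "q4w") {
          # the last complete inter-dose interval of the year
          ld <- max(doses$time[doses$time + interval <= t_end])
          marks <- match(round(ld + c(14, 21, 28), 6), round(rel_grid, 6))
          q4w_marks[i, ] <- prof$cp[marks] < spec$threshold
        }
        list(below = below, cost = cost, dose_final = dose,
             interval_final = interval,
             troughs = tibble(subject_id = cohort$subject_id[i], trough = tr))
      }
    }, error = function(e) {
      if (!spec$continue_on_error)
        abort(sprintf("subject %s failed: %s", cohort$subject_id[i],
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    below_counts <- below_counts + res$below
    subj_rows[[i]] <- tibble(subject_id = cohort$subject_id[i], weight = w,
                             frac_time_below = mean(res$below),
                             cost = res$cost, dose_final = res$dose_final,
                             interval_final = res$interval_final)
    trough_rows[[i]] <- res$troughs
  }

  n_ok <- n - n_failed
  structure(list(
    strategy = spec$strategy, phase = spec$phase, threshold = spec$threshold,
    n = n_ok, n_failed = n_failed, seed = spec$seed,
    attainment = tibble(time = rel_grid, fraction = below_counts / n_ok),
    subjects = list_rbind(subj_rows[!vapply(subj_rows, is.null, TRUE)]),
    troughs = list_rbind(trough_rows[!vapply(trough_rows, is.null, TRUE)]),
    q4w_marks = if (!is.null(q4w_marks))
      setNames(colMeans(q4w_marks, na.rm = TRUE), c("wk2", "wk3", "wk4"))),
    class = "ecu_trial")
}

#' @export
print.ecu_trial <- function(x, ...) {
  cat(sprintf("<virtual eculizumab trial: strategy '%s' (%s phase), n = %d%s>\n",
              x$strategy, x$phase, x$n,
              if (x$n_failed) sprintf(", %d failed", x$n_failed) else ""))
  cat(sprintf("  mean fraction of time with CP < %g%%: %.3f\n", x$threshold,
              mean(x$subjects$frac_time_below)))
  cat(sprintf("  mean cost (%s): $%s\n",
              if (x$phase == "loading") "first 28 days" else "per maintenance year",
              format(round(mean(x$subjects$cost)), big.mark = " ")))
  invisible(x)
}

#' Attainment fraction at a grid time
#'
#' Fraction of subjects whose model-predicted CP activity is below the
#' efficacy threshold at the given evaluation-grid time (absolute days for
#' loading studies; days into the steady-state evaluation window for
#' maintenance studies). Off-grid times are refused rather than
#' interpolated.
#'
#' @param result An `ecu_trial` object.
#' @param time Time in days, on the evaluation grid.
#' @return Fraction in \[0, 1\].
#' @export
attainment_at <- function(result, time) {
  stopifnot(inherits(result, "ecu_trial"))
  i <- match(round(time, 9), round(result$attainment$time, 9))
  if (is.na(i)) abort(sprintf("time %g is not on the evaluation grid", time))
  result$attainment$fraction[i]
}

#' Realized dosing-interval fractions under the TDM policy
#'
#' Tally of each subject's final realized maintenance interval after the
#' two trough checkpoints (14, 21 or 28 days).
#'
#' @param result An `ecu_trial` from the `tdm` strategy.
#' @return A tibble `interval`, `n`, `fraction`; fractions sum to 1.
#' @export
extension_fractions <- function(result) {
  stopifnot(inherits(result, "ecu_trial"))
  if (result$strategy != "tdm")
    abort("interval-extension fractions are defined for the tdm strategy")
  tab <- table(factor(result$subjects$interval_final, levels = c(14, 21, 28)))
  tibble(interval = as.numeric(names(tab)), n = as.integer(tab),
         fraction = as.integer(tab) / sum(tab))
}

#' Fraction of maintenance troughs in a concentration band
#'
#' Pooled over all maintenance troughs observed in the steady-state
#' evaluation window; band is half-open, `[lo, hi)`.
#'
#' @param result A maintenance-phase `ecu_trial`.
#' @param lo,hi Band limits, mg/L.
#' @return Fraction in \[0, 1\].
#' @export
trough_band_fraction <- function(result, lo, hi) {
  stopifnot(inherits(result, "ecu_trial"))
  if (lo >= hi) abort("`lo` must be below `hi`")
  if (is.null(result$troughs) || nrow(result$troughs) == 0)
    abort("trial carries no maintenance troughs (loading-phase study?)")
  mean(result$troughs$trough >= lo & result$troughs$trough < hi)
}

#' Cohort-mean drug cost
#'
#' For loading studies, the mean vial cost of the doses administered in the
#' first 28 days of treatment (t in \[0, 28\]); for maintenance studies, the
#' mean annualized maintenance cost (fixed strategies: the band's
#' maintenance dose at its interval; TDM: the realized post-checkpoint dose
#' and interval).
#'
#' @param result An `ecu_trial`.
#' @param window `"first28d"` or `"per_year_maintenance"`; must match the
#'   trial phase.
#' @return Mean cost in USD.
#' @export
mean_cost <- function(result, window = c("first28d", "per_year_maintenance")) {
  stopifnot(inherits(result, "ecu_trial"))
  window <- match.arg(window)
  needed <- if (window == "first28d") "loading" else "maintenance"
  if (result$phase != needed)
    abort(sprintf("window '%s' requires a %s-phase trial", window, needed))
  mean(result$subjects$cost)
}

#' @exportS3Method generics::tidy
tidy.ecu_trial <- function(x, ...) x$attainment

#' @exportS3Method generics::glance
glance.ecu_trial <- function(x, ...) {
  tibble(strategy = x$strategy, phase = x$phase, n = x$n,
         n_failed = x$n_failed, threshold = x$threshold,
         mean_frac_time_below = mean(x$subjects$frac_time_below),
         mean_cost = mean(x$subjects$cost))
}

#' Plot the attainment curve of a virtual trial
#'
#' Percentage of subjects with CP activity below the efficacy threshold
#' over time, the headline display of the dosing-strategy comparison.
#'
#' @param object An `ecu_trial` (or a list of them for overlays).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecu_trial
#' @export
autoplot.ecu_trial <- function(object, ...) {
  plot_attainment(setNames(list(object), object$strategy))
}

#' @rdname autoplot.ecu_trial
#' @param trials Named list of `ecu_trial` objects to overlay.
#' @export
plot_attainment <- function(trials) {
  if (inherits(trials, "ecu_trial")) trials <- list(trial = trials)
  df <- list_rbind(purrr::imap(trials, function(tr, nm) {
    out <- tr$attainment
    out$strategy <- if (nzchar(nm)) nm else tr$strategy
    out
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = 100 * .data$fraction,
                                   colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "subjects with CP activity < 10% (%)",
                  colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
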
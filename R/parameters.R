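#' Population pharmacokinetic parameters of eculizumab
#'
#' Constructs the population PK parameter set of the one-compartment
#' eculizumab model with parallel first-order and Michaelis-Menten
#' (target-mediated) elimination. Defaults are the published population
#' estimates for a typical 70-kg person: clearance 0.163 L/day, volume of
#' distribution 6.42 L, maximal saturable elimination rate 29.6 mg/day and
#' Michaelis constant 37.9 mg/L, with lognormal interindividual variability
#' (IIV) on clearance (43.4% CV) and volume (37.1% CV), interoccasion
#' variability (IOV) on clearance (34.4% CV), and a combined
#' additive (4.33 mg/L) + proportional residual error with an
#' assay-specific proportional term for each of the two bioanalytical
#' methods (Radboudumc and Sanquin ELISAs).
#'
#' @param cl_typ Typical linear clearance, L/day.
#' @param v_typ Typical volume of distribution, L.
#' @param vmax_typ Typical maximal Michaelis-Menten elimination rate, mg/day.
#' @param km Michaelis constant (concentration at half-maximal saturable
#'   elimination rate), mg/L.
#' @param iiv_cl_cv,iiv_v_cv Interindividual variability on CL and V, CV%.
#' @param iov_cl_cv Interoccasion variability on CL, CV%. A new occasion
#'   starts at each dose administration.
#' @param add_err Additive residual error SD, mg/L.
#' @param prop_err_radboud,prop_err_sanquin Proportional residual error term
#'   for each assay. Interpreted as a variance (sigma^2) by default; see
#'   `prop_err_is_variance`.
#' @param prop_err_is_variance If `TRUE` (default) the proportional error
#'   terms are variances, the usual convention for mixed-effects model
#'   reports; if `FALSE` they are standard deviations.
#' @param ref_weight Reference body weight of the typical subject, kg.
#' @param allo_cl,allo_v Allometric exponents used to scale clearance-like
#'   (CL, Vmax) and volume parameters by body weight.
#'
#' @return An object of class `ecu_pk_params` (a named list).
#' @export
#' @examples
#' pk_parameters()
#' pk_parameters(iiv_cl_cv = 0, iiv_v_cv = 0, iov_cl_cv = 0) # typical subject only
pk_parameters <- function(cl_typ = 0.163, v_typ = 6.42, vmax_typ = 29.6,
                          km = 37.9,
                          iiv_cl_cv = 43.4, iiv_v_cv = 37.1, iov_cl_cv = 34.4,
                          add_err = 4.33,
                          prop_err_radboud = 0.0247, prop_err_sanquin = 0.248,
                          prop_err_is_variance = TRUE,
                          ref_weight = 70, allo_cl = 0.75, allo_v = 1.0) {
  p <- list(cl_typ = cl_typ, v_typ = v_typ, vmax_typ = vmax_typ, km = km,
            iiv_cl_cv = iiv_cl_cv, iiv_v_cv = iiv_v_cv, iov_cl_cv = iov_cl_cv,
            add_err = add_err, prop_err_radboud = prop_err_radboud,
            prop_err_sanquin = prop_err_sanquin,
            prop_err_is_variance = isTRUE(prop_err_is_variance),
            ref_weight = ref_weight, allo_cl = allo_cl, allo_v = allo_v)
  structural <- c("cl_typ", "v_typ", "vmax_typ", "km", "ref_weight")
  for (nm in structural)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0)
      abort(sprintf("`%s` must be a single positive number", nm))
  for (nm in c("iiv_cl_cv", "iiv_v_cv", "iov_cl_cv"))
    if (p[[nm]] < 0 || p[[nm]] >= 200)
      abort(sprintf("`%s` must be a CV%% in [0, 200)", nm))
  if (p$add_err < 0 || p$prop_err_radboud < 0 || p$prop_err_sanquin < 0)
    abort("residual error terms must be nonnegative")
  structure(p, class = "ecu_pk_params")
}

#' Population pharmacodynamic parameters (inhibitory sigmoid Emax model)
#'
#' Constructs the parameter set of the sequential PD model linking free
#' eculizumab concentration C to classical complement pathway (CP) activity:
#' \deqn{E = Base (1 - Imax C^\gamma / (IC50^\gamma + C^\gamma))}
#' Defaults are the published estimates: baseline CP activity 100.7%,
#' maximal inhibition 0.96, IC50 22.0 mg/L, Hill coefficient 5.42, with
#' lognormal IIV on the baseline (23% CV) and IC50 (38.5% CV) and a
#' proportional residual error.
#'
#' @param base Baseline CP activity without drug, % of control sera.
#' @param imax Maximal inhibition fraction, in (0, 1].
#' @param ic50 Concentration for half-maximal CP inhibition, mg/L.
#' @param gamma Hill coefficient (sigmoidicity).
#' @param iiv_base_cv,iiv_ic50_cv Interindividual variability, CV%.
#' @param prop_err Proportional residual error term (variance by default).
#' @param prop_err_is_variance Interpretation flag as in [pk_parameters()].
#'
#' @return An object of class `ecu_pd_params` (a named list).
#' @export
pd_parameters <- function(base = 100.7, imax = 0.96, ic50 = 22.0,
                          gamma = 5.42, iiv_base_cv = 23, iiv_ic50_cv = 38.5,
                          prop_err = 0.089, prop_err_is_variance = TRUE) {
  if (imax <= 0 || imax > 1) abort("`imax` must be in (0, 1]")
  if (ic50 <= 0) abort("`ic50` must be positive")
  if (gamma <= 0) abort("`gamma` must be positive")
  if (base <= 0 || base > 200) abort("`base` must be in (0, 200]")
  if (iiv_base_cv < 0 || iiv_ic50_cv < 0) abort("CV% terms must be nonnegative")
  if (prop_err < 0) abort("`prop_err` must be nonnegative")
  structure(list(base = base, imax = imax, ic50 = ic50, gamma = gamma,
                 iiv_base_cv = iiv_base_cv, iiv_ic50_cv = iiv_ic50_cv,
                 prop_err = prop_err,
                 prop_err_is_variance = isTRUE(prop_err_is_variance)),
            class = "ecu_pd_params")
}

#' @export
print.ecu_pk_params <- function(x, ...) {
  cat("<eculizumab population PK parameters>\n")
  cat(sprintf("  CL %.3g L/day, V %.3g L, Vmax %.3g mg/day, Km %.3g mg/L (ref %g kg)\n",
              x$cl_typ, x$v_typ, x$vmax_typ, x$km, x$ref_weight))
  cat(sprintf("  IIV: CL %.3g%%, V %.3g%%; IOV: CL %.3g%% (CV)\n",
              x$iiv_cl_cv, x$iiv_v_cv, x$iov_cl_cv))
  cat(sprintf("  residual: additive %.3g mg/L; proportional %s %.4g (Radboud) / %.4g (Sanquin)\n",
              x$add_err, if (x$prop_err_is_variance) "variance" else "SD",
              x$prop_err_radboud, x$prop_err_sanquin))
  invisible(x)
}

#' @export
print.ecu_pd_params <- function(x, ...) {
  cat("<eculizumab population PD parameters (inhibitory sigmoid Emax)>\n")
  cat(sprintf("  Base %.4g%%, Imax %.3g, IC50 %.3g mg/L, gamma %.3g\n",
              x$base, x$imax, x$ic50, x$gamma))
  cat(sprintf("  IIV: Base %.3g%%, IC50 %.3g%%; proportional residual %s %.3g\n",
              x$iiv_base_cv, x$iiv_ic50_cv,
              if (x$prop_err_is_variance) "variance" else "SD", x$prop_err))
  invisible(x)
}

#' Convert a coefficient of variation to a lognormal standard deviation
#'
#' For a lognormal random effect `exp(eta)` with `eta ~ N(0, omega^2)`, a
#' coefficient of variation of `cv` percent corresponds to
#' `omega = sqrt(log(1 + (cv/100)^2))`.
#'
#' @param cv_percent Coefficient of variation in percent (vectorised).
#' @return Lognormal SD(s) on the log scale.
#' @export
#' @examples
#' cv_to_omega(43.4) # approx 0.4154
cv_to_omega <- function(cv_percent) {
  if (any(!is.finite(cv_percent)) || any(cv_percent < 0))
    abort("`cv_percent` must be finite and nonnegative")
  sqrt(log(1 + (cv_percent / 100)^2))
}

#' Weight-scaled typical PK parameters
#'
#' Applies fixed allometric scaling referenced to the typical body weight:
#' clearance-like parameters (CL, Vmax) scale with `(weight/ref)^0.75`,
#' the volume of distribution with `(weight/ref)^1`, and the Michaelis
#' constant Km (a concentration) is weight-independent.
#'
#' @param pop An [pk_parameters()] object.
#' @param weight Body weight in kg (vectorised).
#' @return A tibble with one row per weight: `weight`, `cl`, `v`, `vmax`, `km`.
#' @export
#' @examples
#' scale_by_weight(pk_parameters(), c(35, 70))
scale_by_weight <- function(pop, weight) {
  stopifnot(inherits(pop, "ecu_pk_params"))
  if (any(!is.finite(weight)) || any(weight <= 0))
    abort("`weight` must be positive")
  f_cl <- (weight / pop$ref_weight)^pop$allo_cl
  f_v <- (weight / pop$ref_weight)^pop$allo_v
  tibble(weight = weight,
         cl = pop$cl_typ * f_cl,
         v = pop$v_typ * f_v,
         vmax = pop$vmax_typ * f_cl,
         km = rep(pop$km, length(weight)))
}

prop_sd <- function(term, is_variance) if (is_variance) sqrt(term) else term

#' Apply the residual (observation) error model
#'
#' PK observations carry a combined proportional + additive error,
#' `obs = true * (1 + eps_p) + eps_a`, with an assay-specific proportional
#' term (Radboudumc or Sanquin ELISA); PD (CP activity) observations carry a
#' proportional error only. Negative perturbed values are truncated at 0.
#'
#' @param true_value Model-predicted value(s), nonnegative.
#' @param error_model One of `"pk_radboud"`, `"pk_sanquin"`, `"pd"`.
#' @param pk,pd Population parameter objects supplying the error magnitudes.
#' @param seed Optional integer seed for reproducible draws.
#' @return Observed value(s), same length as `true_value`.
#' @export
apply_residual_error <- function(true_value,
                                 error_model = c("pk_radboud", "pk_sanquin", "pd"),
                                 pk = pk_parameters(), pd = pd_parameters(),
                                 seed = NULL) {
  error_model <- match.arg(error_model)
  if (any(true_value < 0)) abort("`true_value` must be nonnegative")
  n <- length(true_value)
  draw <- function() {
    switch(error_model,
      pk_radboud = ,
      pk_sanquin = {
        sp <- prop_sd(if (error_model == "pk_radboud") pk$prop_err_radboud
                      else pk$prop_err_sanquin, pk$prop_err_is_variance)
        true_value * (1 + rnorm(n, 0, sp)) + rnorm(n, 0, pk$add_err)
      },
      pd = {
        sp <- prop_sd(pd$prop_err, pd$prop_err_is_variance)
        true_value * (1 + rnorm(n, 0, sp))
      })
  }
  obs <- if (is.null(seed)) draw() else with_seed(seed, draw())
  pmax(obs, 0)
}
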
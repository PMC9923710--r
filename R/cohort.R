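# Growth-curve anchor medians used by the cohort emulator. Values are
# standard reference medians (kg, cm) at the anchor ages; between anchors the
# weight median is interpolated log-linearly in age, heights linearly.
growth_anchor_ages <- c(1, 2, 5, 10, 15, 18, 30, 60)

growth_weight_median <- list(
  female = c(9.5, 12.0, 18.0, 32.5, 53.0, 62.0, 68.0, 68.0),
  male   = c(10.2, 12.7, 18.5, 32.0, 56.5, 68.0, 80.0, 80.0)
)

growth_height_median <- list(
  female = c(74, 86, 109, 138, 162, 163, 162, 160),
  male   = c(76, 88, 110, 138, 170, 176, 176, 174)
)

growth_median <- function(age, sex, what = c("weight", "height")) {
  what <- match.arg(what)
  tab <- if (what == "weight") growth_weight_median else growth_height_median
  out <- numeric(length(age))
  for (s in c("female", "male")) {
    idx <- sex == s
    if (!any(idx)) next
    y <- tab[[s]]
    if (what == "weight") {
      out[idx] <- exp(approx(growth_anchor_ages, log(y), xout = pmin(pmax(age[idx], 1), 60),
                             rule = 2)$y)
    } else {
      out[idx] <- approx(growth_anchor_ages, y, xout = pmin(pmax(age[idx], 1), 60),
                         rule = 2)$y
    }
  }
  out
}

#' Generate a virtual aHUS-like simulation cohort
#'
#' Emulates the NHANES-derived virtual population used for the dosing
#' simulations: 2000 subjects ages 1-79 years, 48% female, median weight
#' 61.6 kg (range 8.3-155.6) and median height 159 cm. Only these printed
#' summary statistics are available, so the cohort is generated
#' parametrically: age is a mixture of a paediatric stratum (uniform on
#' 1-18 years, weight 0.40) and an adult stratum (18-79 years, front-
#' weighted Beta(1, 1.5) as in survey age pyramids) calibrated so the
#' median age is about 24.8 years; weight is lognormal around a
#' sex- and age-conditional growth-curve median (CV 20% in adults, 15% in
#' children), truncated to the printed range; height is lognormal (CV 4%)
#' around the growth-curve median.
#'
#' @param n Number of subjects.
#' @param age_range Two-element numeric, years; default `c(1, 79)`.
#' @param seed Integer seed; the cohort is fully reproducible.
#' @param prop_female Probability a subject is female.
#' @param child_fraction Mixture weight of the paediatric age stratum.
#' @param weight_cv_adult,weight_cv_child Lognormal spread (CV, fraction) of
#'   weight about the growth-curve median. Setting a CV to 0 pins weight to
#'   the growth-curve median exactly.
#' @param weight_range Truncation range for weight, kg.
#' @param height_cv Lognormal spread of height about the growth-curve median.
#' @return A tibble of class `ecu_cohort` with columns `subject_id`, `age`,
#'   `sex`, `weight`, `height`.
#' @export
#' @examples
#' cohort <- generate_cohort(200, seed = 1)
#' summary(cohort$weight)
generate_cohort <- function(n, age_range = c(1, 79), seed = 1L,
                            prop_female = 0.48, child_fraction = 0.40,
                            weight_cv_adult = 0.20, weight_cv_child = 0.15,
                            weight_range = c(8.3, 155.6), height_cv = 0.04) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) abort("`n` must be >= 1")
  if (length(age_range) != 2 || diff(age_range) < 0)
    abort("`age_range` must be a nondecreasing pair of ages")
  lo <- age_range[1]; hi <- age_range[2]
  child_hi <- min(18, hi)
  with_seed(seed, {
    is_child <- if (lo < child_hi) runif(n) < child_fraction else rep(FALSE, n)
    adult_lo <- max(lo, child_hi)
    age <- ifelse(is_child,
                  runif(n, lo, child_hi),
                  adult_lo + (hi - adult_lo) * stats::rbeta(n, 1, 1.5))
    sex <- ifelse(runif(n) < prop_female, "female", "male")
    cv_w <- ifelse(age < 18, weight_cv_child, weight_cv_adult)
    om_w <- sqrt(log(1 + cv_w^2))
    med_w <- growth_median(age, sex, "weight")
    weight <- med_w * exp(rnorm(n, 0, 1) * om_w)
    weight <- pmin(pmax(weight, weight_range[1]), weight_range[2])
    om_h <- sqrt(log(1 + height_cv^2))
    height <- growth_median(age, sex, "height") * exp(rnorm(n, 0, 1) * om_h)
    height <- pmin(pmax(height, 60), 210)
    out <- tibble(subject_id = seq_len(n), age = age, sex = sex,
                  weight = weight, height = height)
    class(out) <- c("ecu_cohort", class(out))
    out
  })
}

#' Growth-curve median weight or height
#'
#' The sex- and age-conditional median used by [generate_cohort()]:
#' reference medians at anchor ages 1, 2, 5, 10, 15, 18, 30 and 60 years,
#' interpolated log-linearly (weight) or linearly (height) in between and
#' held constant outside the anchors.
#'
#' @param age Age(s) in years.
#' @param sex `"female"` or `"male"`, recycled to the length of `age`.
#' @param what `"weight"` (kg) or `"height"` (cm).
#' @return Numeric vector of medians.
#' @export
growth_curve_median <- function(age, sex, what = c("weight", "height")) {
  sex <- rep_len(sex, length(age))
  if (!all(sex %in% c("female", "male"))) abort("`sex` must be female/male")
  growth_median(age, sex, match.arg(what))
}

#' Load and validate a cohort from CSV
#'
#' Reads a cohort table with columns `subject_id`, `age`, `sex`, `weight`,
#' `height`. Rows violating the plausibility invariants (age in 1-79 years,
#' weight in 5-160 kg, height in 60-210 cm, sex female/male) are rejected
#' with row-level diagnostics.
#'
#' @param path Path to a CSV file.
#' @return A validated `ecu_cohort` tibble.
#' @export
load_cohort <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  required <- c("subject_id", "age", "sex", "weight", "height")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    abort(sprintf("cohort file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0) {
    warn("cohort file contains a header only; returning an empty cohort")
    out <- df[required]
    class(out) <- c("ecu_cohort", class(out))
    return(out)
  }
  for (col in c("age", "weight", "height")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      abort(sprintf("non-numeric `%s` in row(s): %s", col,
                    paste(head(bad, 5), collapse = ", ")))
    df[[col]] <- v
  }
  ok_age <- df$age >= 1 & df$age <= 79
  ok_weight <- df$weight >= 5 & df$weight <= 160
  ok_height <- df$height >= 60 & df$height <= 210
  ok_sex <- df$sex %in% c("female", "male")
  ok <- ok_age & ok_weight & ok_height & ok_sex & !is.na(df$age) &
    !is.na(df$weight) & !is.na(df$height)
  if (any(!ok)) {
    bad <- which(!ok)
    abort(sprintf(
      "cohort row(s) violate subject invariants (age 1-79, weight 5-160 kg, height 60-210 cm, sex female/male): row %s",
      paste(head(bad, 10), collapse = ", ")))
  }
  out <- df[required]
  class(out) <- c("ecu_cohort", class(out))
  out
}
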
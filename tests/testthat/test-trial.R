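small_cohort <- function(n = 25, seed = 31) generate_cohort(n, seed = seed)

test_that("a zero-variability adult attains the target as a step function", {
  co <- tibble::tibble(subject_id = 1, age = 40, sex = "male", weight = 70,
                       height = 176)
  class(co) <- c("ecu_cohort", class(co))
  spec <- trial_spec(co, "standard", pk = zero_iiv_pk(), pd = zero_iiv_pd(),
                     seed = 1)
  tr <- run_trial(spec)
  att <- tr$attainment
  # pre-dose zero at t = 0, then attained for the whole 28 days: the
  # typical subject stays above the ~36.3 mg/L threshold concentration
  expect_equal(att$fraction[att$time == 0], 0)
  expect_true(all(att$fraction[att$time >= 1] == 1))
  expect_equal(attainment_at(tr, 6), 1)
  expect_error(attainment_at(tr, 6.05), "grid")
})

test_that("a vacuous threshold yields full attainment", {
  co <- small_cohort(10)
  tr <- run_trial(trial_spec(co, "standard", threshold = 99.9, seed = 2))
  expect_true(all(tr$attainment$fraction[tr$attainment$time > 0.5] == 1))
})

test_that("trials are deterministic under the seed", {
  co <- small_cohort(15)
  t1 <- run_trial(trial_spec(co, "tdm", seed = 4))
  t2 <- run_trial(trial_spec(co, "tdm", seed = 4))
  expect_identical(t1$attainment, t2$attainment)
  expect_identical(t1$subjects, t2$subjects)
  expect_identical(t1$troughs, t2$troughs)
})

test_that("doubling every dose never lowers attainment", {
  co <- small_cohort(20, seed = 33)
  inds <- sample_individuals(co, seed = 33)
  for (i in c(1, 7, 13)) {
    ind <- as.list(inds[i, ]); ind$occ_cl <- ind$occ_cl[[1]]
    reg <- standard_regimen(co$weight[i], horizon = 28)
    reg2 <- reg; reg2$amount <- reg2$amount * 2
    times <- seq(0.5, 28, 0.5)
    below1 <- solve_profile(ind, reg, times)$cp < 10
    below2 <- solve_profile(ind, reg2, times)$cp < 10
    expect_true(all(below2 >= below1))
  }
})

test_that("single-adult 28-day costs match the printed vial counts", {
  co <- tibble::tibble(subject_id = 1, age = 40, sex = "female", weight = 70,
                       height = 165)
  class(co) <- c("ecu_cohort", class(co))
  std <- run_trial(trial_spec(co, "standard", seed = 1))
  alt <- run_trial(trial_spec(co, "alt_loading", seed = 1))
  # 4 x 900 + 1200 = 16 vials vs 1800 + 2 x 1200 = 14 vials
  expect_identical(mean_cost(std, "first28d"), 16 * 6523)
  expect_identical(mean_cost(alt, "first28d"), 14 * 6523)
  # the 12.5% saving quoted for the adult case
  expect_equal(1 - mean_cost(alt, "first28d") / mean_cost(std, "first28d"),
               0.125, tolerance = 1e-12)
})

test_that("trial cost accounting is exact vial arithmetic", {
  co <- small_cohort(12, seed = 35)
  tr <- run_trial(trial_spec(co, "standard", seed = 35))
  expect_true(all(tr$subjects$cost %% 6523 == 0))
  tdm <- run_trial(trial_spec(co, "tdm", seed = 35))
  expect_true(all(tdm$subjects$cost %% 6523 == 0))
})

test_that("extension fractions partition the tdm cohort", {
  co <- small_cohort(30, seed = 36)
  tr <- run_trial(trial_spec(co, "tdm", seed = 36))
  ef <- extension_fractions(tr)
  expect_equal(sum(ef$fraction), 1, tolerance = 1e-12)
  expect_equal(ef$interval, c(14, 21, 28))
  std <- run_trial(trial_spec(co, "standard", seed = 36))
  expect_error(extension_fractions(std), "tdm")
})

test_that("a zero-IIV cohort keeps the label interval under TDM", {
  co <- tibble::tibble(subject_id = 1:3, age = c(30, 40, 50),
                       sex = "female", weight = c(70, 80, 90),
                       height = 165)
  class(co) <- c("ecu_cohort", class(co))
  tr <- run_trial(trial_spec(co, "tdm", pk = zero_iiv_pk(),
                             pd = zero_iiv_pd(), seed = 1))
  ef <- extension_fractions(tr)
  expect_equal(ef$fraction[ef$interval == 14], 1)
})

test_that("trough band fractions behave like probabilities", {
  co <- small_cohort(15, seed = 37)
  tr <- run_trial(trial_spec(co, "standard", phase = "maintenance", seed = 37))
  expect_equal(trough_band_fraction(tr, 0, Inf), 1)
  f1 <- trough_band_fraction(tr, 50, 100)
  f2 <- trough_band_fraction(tr, 50, 200)
  expect_true(f1 >= 0 && f1 <= 1 && f2 >= f1)
  expect_error(trough_band_fraction(tr, 100, 50), "below")
  loading <- run_trial(trial_spec(co, "standard", seed = 37))
  expect_error(trough_band_fraction(loading, 50, 100), "troughs")
  expect_error(mean_cost(loading, "per_year_maintenance"), "maintenance")
})

test_that("tidy, glance and autoplot summarise a trial", {
  co <- small_cohort(8, seed = 38)
  tr <- run_trial(trial_spec(co, "q4w", seed = 38))
  td <- generics::tidy(tr)
  expect_true(all(c("time", "fraction") %in% names(td)))
  gl <- generics::glance(tr)
  expect_equal(gl$n, 8)
  expect_true(gl$mean_frac_time_below <= 1)
  p <- ggplot2::autoplot(tr)
  expect_s3_class(p, "ggplot")
})
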
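test_that("trough rules follow the adjustment table", {
  # 2nd-dose checkpoint: low cutoff 100 mg/L
  expect_equal(tdm_adjust("before_2nd_dose", 80, 1200, 14),
               list(dose = 1500, interval = 14))
  expect_equal(tdm_adjust("before_2nd_dose", 150, 1200, 14),
               list(dose = 1200, interval = 14))
  expect_equal(tdm_adjust("before_2nd_dose", 220, 1200, 14),
               list(dose = 1200, interval = 21))
  # 3rd-dose checkpoint: low cutoff 50 mg/L, extensions compound to 28 d
  expect_equal(tdm_adjust("before_3rd_dose", 49.9, 600, 14),
               list(dose = 900, interval = 14))
  expect_equal(tdm_adjust("before_3rd_dose", 60, 1200, 14),
               list(dose = 1200, interval = 14))
  expect_equal(tdm_adjust("before_3rd_dose", 220, 1200, 21),
               list(dose = 1200, interval = 28))
  # boundaries are half-open as printed
  expect_equal(tdm_adjust("before_2nd_dose", 100, 1200, 14)$dose, 1200)
  expect_equal(tdm_adjust("before_2nd_dose", 200, 1200, 14)$interval, 21)
  # cap at 28 days
  expect_equal(tdm_adjust("before_3rd_dose", 300, 1200, 28)$interval, 28)
  expect_error(tdm_adjust("before_2nd_dose", -1, 1200, 14), "nonnegative")
})

test_that("mid-band troughs leave the standard course untouched", {
  # a slow-clearing adult whose checkpoint troughs fall in [100, 200) and
  # [50, 200): the realized course must equal the standard maintenance
  # schedule exactly
  ind <- list(cl_i = 0.163 * 0.5, v_i = 6.42, vmax_i = 29.6, km_i = 37.9)
  cc <- simulate_tdm_course(ind, 70, horizon = 365.25)
  expect_true(cc$troughs[1] >= 100 && cc$troughs[1] < 200)
  expect_true(cc$troughs[2] >= 50 && cc$troughs[2] < 200)
  expect_equal(cc$dose_final, 1200)
  expect_equal(cc$interval_final, 14)
  std <- seq(0, 365.25, by = 14)
  expect_equal(cc$doses$time, std)
  expect_equal(cc$doses$amount, rep(1200, length(std)))
})

test_that("fast clearance raises the dose, slow clearance extends the interval", {
  fast <- list(cl_i = 0.163 * 3, v_i = 6.42, vmax_i = 29.6, km_i = 37.9)
  cc <- simulate_tdm_course(fast, 70, horizon = 365.25)
  expect_lt(cc$troughs[1], 100)
  expect_equal(cc$dose_final, 1500)
  expect_equal(cc$interval_final, 14)

  slow <- list(cl_i = 0.163 * 0.3, v_i = 6.42, vmax_i = 29.6, km_i = 37.9)
  cs <- simulate_tdm_course(slow, 70, horizon = 365.25)
  expect_gte(cs$troughs[2], 200)
  expect_equal(cs$interval_final, 21)

  # very slow clearance in a small volume: both checkpoints >= 200,
  # extensions compound to the 28-day cap
  vslow <- list(cl_i = 0.163 * 0.2, v_i = 3.5, vmax_i = 29.6, km_i = 37.9)
  cv <- simulate_tdm_course(vslow, 70, horizon = 365.25)
  expect_true(all(cv$troughs >= 200))
  expect_equal(cv$interval_final, 28)
  expect_equal(cv$dose_final, 1200)
  # the realized schedule reflects both extensions: doses at 0, 14, 35, then q28
  expect_equal(head(cv$doses$time, 4), c(0, 14, 35, 63))
})

test_that("policy outcomes are monotone in clearance", {
  mults <- c(0.2, 0.3, 0.5, 0.8, 1, 1.5, 3)
  res <- lapply(mults, function(m) {
    ind <- list(cl_i = 0.163 * m, v_i = 6.42, vmax_i = 29.6, km_i = 37.9)
    simulate_tdm_course(ind, 70, horizon = 365.25)
  })
  intervals <- vapply(res, function(x) x$interval_final, 0)
  doses <- vapply(res, function(x) x$dose_final, 0)
  # decreasing clearance never decreases the realized interval
  expect_true(all(diff(intervals) <= 0))
  # increasing clearance never decreases the realized dose
  expect_true(all(diff(doses) >= 0))
})

test_that("realized regimens stay within the policy's reachable set", {
  co <- generate_cohort(60, seed = 21)
  inds <- sample_individuals(co, seed = 21)
  for (i in seq_len(nrow(co))) {
    ind <- as.list(inds[i, ]); ind$occ_cl <- ind$occ_cl[[1]]
    cc <- simulate_tdm_course(ind, co$weight[i], horizon = 365.25)
    expect_true(cc$interval_final %in% c(cc$interval_initial,
                                         cc$interval_initial + 7,
                                         min(cc$interval_initial + 14, 28)))
    expect_true(cc$dose_final %in% (cc$dose_initial + c(0, 300, 600)))
    # interval never below and dose never below the starting regimen
    expect_gte(cc$interval_final, cc$interval_initial)
    expect_gte(cc$dose_final, cc$dose_initial)
  }
})

test_that("measurement error perturbs the checkpoints reproducibly", {
  ind <- list(cl_i = 0.163, v_i = 6.42, vmax_i = 29.6, km_i = 37.9)
  c1 <- simulate_tdm_course(ind, 70, horizon = 365.25,
                            measure_with_error = TRUE, seed = 5)
  c2 <- simulate_tdm_course(ind, 70, horizon = 365.25,
                            measure_with_error = TRUE, seed = 5)
  c0 <- simulate_tdm_course(ind, 70, horizon = 365.25)
  expect_identical(c1$troughs, c2$troughs)
  expect_false(identical(c1$troughs, c0$troughs))
})
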
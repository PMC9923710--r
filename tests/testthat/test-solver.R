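test_that("no doses give an identically zero profile", {
  prof <- solve_profile(typical_pk(), NULL, times = seq(0, 10, 1),
                        with_cp = FALSE)
  expect_true(all(prof$conc == 0))
})

test_that("solver matches the linear-elimination closed form", {
  # Vmax = 0, single 1200-mg bolus: C(t) = (1200/6.42) exp(-CL/V t)
  ind <- typical_pk(vmax = 0)
  times <- c(0.5, 1, 2, 5, 7, 14, 21, 28)
  prof <- solve_profile(ind, data.frame(time = 0, amount = 1200), times,
                        with_cp = FALSE)
  expected <- 1200 / 6.42 * exp(-0.163 / 6.42 * times)
  expect_equal(prof$conc, expected, tolerance = 1e-6)
  expect_equal(prof$conc[times == 14], 130.96, tolerance = 1e-3)

  # superposition over an arbitrary bolus schedule
  doses <- data.frame(time = c(0, 3, 7.5, 14), amount = c(900, 300, 600, 1200))
  t2 <- seq(0.25, 30, by = 0.25)
  prof2 <- solve_profile(ind, doses, t2, with_cp = FALSE)
  # strict inequality: grid values at dose times are pre-dose left limits
  sup <- rowSums(sapply(seq_len(nrow(doses)), function(i)
    ifelse(t2 > doses$time[i],
           doses$amount[i] / 6.42 * exp(-0.163 / 6.42 * (t2 - doses$time[i])), 0)))
  expect_equal(prof2$conc, sup, tolerance = 1e-6)
})

test_that("grid values at dose times are pre-dose left limits", {
  ind <- typical_pk(vmax = 0)
  prof <- solve_profile(ind, data.frame(time = c(0, 14), amount = 1200),
                        times = c(0, 7, 14), with_cp = FALSE)
  expect_equal(prof$conc[1], 0) # before the first bolus
  expect_equal(prof$conc[3], 1200 / 6.42 * exp(-0.163 / 6.42 * 14),
               tolerance = 1e-6)
})

test_that("adaptive solver agrees with an explicit-Euler oracle", {
  ind <- typical_ind()
  doses <- data.frame(time = c(0, 14), amount = c(900, 1200))
  out_t <- c(1, 5, 13.5, 15, 21, 28)
  ref <- euler_profile(ind, doses, t_end = 28, dt = 1e-4, out_times = out_t)
  prof <- solve_profile(ind, doses, out_t, with_cp = FALSE)
  expect_equal(prof$conc, ref, tolerance = 1e-3)
})

test_that("saturable elimination only ever lowers concentrations", {
  doses <- data.frame(time = c(0, 7, 14, 21), amount = c(900, 900, 900, 900))
  times <- seq(0.5, 28, by = 0.5)
  lin <- solve_profile(typical_pk(vmax = 0), doses, times, with_cp = FALSE)
  mm <- solve_profile(typical_pk(vmax = 29.6), doses, times, with_cp = FALSE)
  expect_true(all(mm$conc <= lin$conc + 1e-9))
})

test_that("mass balance holds in the linear case", {
  # total eliminated = CL * integral(C) must equal the administered dose
  ind <- typical_pk(vmax = 0)
  times <- seq(0.01, 1500, by = 0.05)
  prof <- solve_profile(ind, data.frame(time = 0, amount = 1200), times,
                        with_cp = FALSE)
  auc <- sum(diff(times) * (head(prof$conc, -1) + tail(prof$conc, -1)) / 2)
  # close the [0, 0.01] sliver with the known post-dose concentration
  auc <- auc + (1200 / 6.42 + prof$conc[1]) / 2 * 0.01
  expect_equal(0.163 * auc, 1200, tolerance = 1e-4)
})

test_that("concentrations stay nonnegative over random dosing schedules", {
  set.seed(42)
  for (rep in 1:8) {
    nd <- sample(1:6, 1)
    doses <- data.frame(time = sort(runif(nd, 0, 40)),
                        amount = 300 * sample(1:8, nd, replace = TRUE))
    ind <- list(cl_i = runif(1, 0.05, 0.6), v_i = runif(1, 1, 10),
                vmax_i = runif(1, 0, 60), km_i = runif(1, 5, 80))
    prof <- solve_profile(ind, doses, seq(0, 60, 0.25), with_cp = FALSE)
    expect_true(all(prof$conc >= 0))
    expect_true(all(is.finite(prof$conc)))
  }
})

test_that("solver agrees with deSolve on the nonlinear model", {
  skip_if_not_installed("deSolve")
  ind <- typical_ind()
  doses <- data.frame(time = c(0, 14, 28), amount = c(900, 1200, 1200))
  times <- seq(0, 42, by = 0.5)
  rhs <- function(t, y, p) {
    C <- y[1] / p$v
    list(-p$cl / p$v * y[1] - p$vmax * C / (p$km + C))
  }
  ev <- data.frame(var = "A", time = doses$time, value = doses$amount,
                   method = "add")
  ref <- deSolve::lsoda(c(A = 0), times = sort(unique(c(times, doses$time))),
                        func = rhs,
                        parms = list(cl = ind$cl_i, v = ind$v_i,
                                     vmax = ind$vmax_i, km = ind$km_i),
                        events = list(data = ev),
                        rtol = 1e-10, atol = 1e-10)
  prof <- solve_profile(ind, doses, times[-1], with_cp = FALSE)
  # compare away from dose times (deSolve reports post-event values there)
  keep <- !(times[-1] %in% doses$time)
  ref_c <- ref[match(times[-1], ref[, "time"]), "A"] / ind$v_i
  expect_equal(prof$conc[keep], unname(ref_c[keep]), tolerance = 1e-6)
})

test_that("infusions administer the full amount at a finite rate", {
  ind <- typical_pk(vmax = 0)
  bolus <- solve_profile(ind, data.frame(time = 0, amount = 1200),
                         times = seq(1, 14, 0.5), with_cp = FALSE)
  inf <- solve_profile(ind, data.frame(time = 0, amount = 1200,
                                       duration = 0.04), # ~1 h
                       times = seq(1, 14, 0.5), with_cp = FALSE)
  expect_equal(inf$conc, bolus$conc, tolerance = 2e-3)
  # the infusion lags the bolus, so after it ends its concentrations sit
  # slightly above the bolus curve (less decay time)
  expect_true(all(inf$conc >= bolus$conc - 1e-9))
})

test_that("trough_before returns the pre-dose left limit", {
  flat <- tibble::tibble(time = seq(0, 28, 1), conc = 120)
  expect_equal(trough_before(flat, 14), 120)
  ind <- typical_pk(vmax = 0)
  prof <- solve_profile(ind, data.frame(time = c(0, 14), amount = 1200),
                        times = seq(0, 28, 0.5), with_cp = FALSE)
  expect_equal(trough_before(prof, 14), 130.96, tolerance = 1e-3)
  expect_error(trough_before(prof, 0), "precedes")
  expect_error(trough_before(prof, 99), "range")
})
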
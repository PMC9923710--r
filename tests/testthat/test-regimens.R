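test_that("label regimen reproduces the approved schedule", {
  r <- standard_regimen(70, horizon = 29)
  expect_equal(r$time, c(0, 7, 14, 21, 28))
  expect_equal(r$amount, c(900, 900, 900, 900, 1200))
  expect_equal(attr(r, "maintenance_interval"), 14)

  r25 <- standard_regimen(25, horizon = 14)
  expect_equal(r25$amount[1:2], c(600, 600))

  r8 <- standard_regimen(8, horizon = 100)
  expect_equal(attr(r8, "maintenance_dose"), 300)
  expect_equal(attr(r8, "maintenance_interval"), 21)
  m <- r8$time[r8$amount == 300 & r8$time >= 7]
  expect_equal(diff(m), rep(21, length(m) - 1))

  expect_error(standard_regimen(4), "band")
})

test_that("weight-based loading regimen follows its band table", {
  r75 <- alternative_loading_regimen(75, horizon = 28)
  expect_equal(r75$time, c(0, 14, 28))
  expect_equal(r75$amount, c(1800, 1200, 1200))
  expect_equal(alternative_loading_regimen(125, 14)$amount[1], 2400)
  r15 <- alternative_loading_regimen(15, horizon = 14)
  expect_equal(r15$amount, c(600, 300))
  expect_error(alternative_loading_regimen(3), "band")
})

test_that("4-week regimen uses the 4-week band doses every 28 days", {
  r <- q4w_regimen(75, horizon = 200, induction = FALSE)
  expect_equal(unique(r$amount), 2400)
  expect_equal(unique(diff(r$time)), 28)
  expect_equal(q4w_regimen(50, 100)$amount |> tail(1), 2100)
  expect_equal(attr(q4w_regimen(8, 100), "maintenance_dose"), 900)
})

test_that("every weight maps to exactly one band in each table", {
  for (w in c(5, 5.01, 9.99, 10, 19.9, 20, 29.5, 30, 39.99, 40, 59.9, 60,
              89.9, 90, 119.9, 120, 155.6)) {
    expect_s3_class(standard_regimen(w, 30), "ecu_regimen")
    expect_s3_class(alternative_loading_regimen(w, 30), "ecu_regimen")
    expect_s3_class(q4w_regimen(w, 30), "ecu_regimen")
  }
  # boundaries are half-open: 40.0 falls in the adult band
  expect_equal(standard_regimen(40, 7)$amount[1], 900)
  expect_equal(standard_regimen(39.999, 7)$amount[1], 600)
})

test_that("all generated doses are whole vials", {
  for (w in c(6, 12, 25, 35, 55, 70, 100, 130)) {
    for (reg in list(standard_regimen(w, 365), alternative_loading_regimen(w, 365),
                     q4w_regimen(w, 365))) {
      expect_true(all(reg$amount %% 300 == 0))
    }
  }
})

test_that("in-code band tables match the transcribed dose tables", {
  # label regimen: generated weekly schedule vs the transcription
  lab <- read.csv(system.file("extdata", "label_regimen_table.csv",
                              package = "ecudose"))
  for (i in seq_len(nrow(lab))) {
    w <- lab$lo_kg[i] + 1
    r <- standard_regimen(w, horizon = 28)
    weeks <- as.numeric(lab[i, paste0("week", 1:5, "_mg")])
    sched <- rep(NA_real_, 5)
    sched[r$time / 7 + 1] <- r$amount
    expect_equal(sched, weeks, info = sprintf("label band from %g kg", lab$lo_kg[i]))
    expect_equal(attr(r, "maintenance_interval"),
                 lab$maintenance_interval_days[i])
  }
  # loading-dose strategy table
  load_tab <- read.csv(system.file("extdata", "loading_strategy_table.csv",
                                   package = "ecudose"))
  for (i in seq_len(nrow(load_tab))) {
    r <- alternative_loading_regimen(load_tab$lo_kg[i] + 1, horizon = 14)
    expect_equal(r$amount[1], load_tab$day1_mg[i])
    expect_equal(r$amount[2], load_tab$day15_mg[i])
  }
  # 4-week interval table
  q4_tab <- read.csv(system.file("extdata", "q4w_table.csv", package = "ecudose"))
  for (i in seq_len(nrow(q4_tab))) {
    r <- q4w_regimen(q4_tab$lo_kg[i] + 1, horizon = 56, induction = FALSE)
    expect_equal(unique(r$amount), q4_tab$dose_mg[i])
  }
})

test_that("vial costs are exact integer arithmetic", {
  expect_identical(vial_cost(0), 0)
  expect_identical(vial_cost(1200), 4 * 6523)
  expect_identical(vial_cost(900), 19569)
  expect_identical(vial_cost(301), 2 * 6523) # partial vials are whole vials
  expect_error(vial_cost(-300), "nonnegative")
})

test_that("annualized cost uses fractional dose counts", {
  expect_equal(annualize_cost(1200, 14), 365.25 / 14 * 26092)
  expect_equal(annualize_cost(1200, 14), 680700, tolerance = 1e-4)
  expect_equal(annualize_cost(300, 21), 365.25 / 21 * 6523)
  expect_equal(annualize_cost(300, 21), 113450, tolerance = 1e-4)
  # same total mg/year -> same cost
  expect_equal(annualize_cost(2400, 28), annualize_cost(1200, 14))
  expect_equal(annualize_cost(1200, 14, fractional = FALSE), 26 * 26092)
  expect_error(annualize_cost(1200, 0), "positive")
})
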
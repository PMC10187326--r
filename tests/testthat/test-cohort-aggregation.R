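test_that("QC rules fire exactly at the published boundaries", {
  all_day <- rep(TRUE, 24)
  r <- qc_screen(71.9, all_day)
  expect_false(r$include)
  expect_identical(r$flags, "wear<72h")
  expect_true(qc_screen(72, all_day)$include)
  r <- qc_screen(100, all_day, mean_acceleration_mg = 101)
  expect_false(r$include)
  expect_identical(r$flags, "mean_acceleration>100mg")
  expect_true(qc_screen(100, all_day, mean_acceleration_mg = 100)$include)
  # 7 full days, all hours covered, 28 mg mean -> included
  expect_true(qc_screen(7 * 24, all_day, TRUE, 28)$include)
  r <- qc_screen(100, 0:22)  # hour 23 never covered
  expect_false(r$include)
  expect_identical(r$flags, "incomplete_diurnal_coverage")
  expect_false(qc_screen(100, all_day, calibration_ok = FALSE)$include)
})

test_that("QC screening is monotone in wear time", {
  covered <- rep(TRUE, 24)
  for (h in seq(72, 170, by = 7)) expect_true(qc_screen(h, covered)$include)
})

test_that("non-wear minutes are imputed from the same minute on other days", {
  grid <- matrix(0, 4, 1440)
  grid[, 511] <- c(10, 5, 20, 30)  # minute 08:30 (zero-based 510)
  miss <- matrix(FALSE, 4, 1440)
  miss[2, 511] <- TRUE
  imp <- impute_nonwear(grid, miss)
  expect_equal(imp$steps[2, 511], mean(c(10, 20, 30)))
  expect_true(imp$imputed[2, 511])
  expect_equal(sum(imp$imputed), 1L)
})

test_that("a complete grid passes through imputation untouched", {
  set.seed(5)
  grid <- matrix(rpois(3 * 1440, 2), 3, 1440)
  miss <- matrix(FALSE, 3, 1440)
  imp <- impute_nonwear(grid, miss)
  expect_equal(imp$steps, grid)
  expect_identical(daily_steps(imp$steps)$per_day, daily_steps(grid)$per_day)
})

test_that("minutes missing on every day become zero and are flagged", {
  grid <- matrix(3, 3, 1440)
  miss <- matrix(FALSE, 3, 1440)
  miss[, 100] <- TRUE
  imp <- impute_nonwear(grid, miss)
  expect_equal(imp$steps[, 100], c(0, 0, 0))
  expect_true(imp$all_missing[100])
  expect_equal(sum(imp$all_missing), 1L)
})

test_that("imputed values stay within the observed range for that minute", {
  set.seed(6)
  grid <- matrix(rpois(5 * 1440, 4), 5, 1440)
  miss <- matrix(runif(5 * 1440) < 0.1, 5, 1440)
  imp <- impute_nonwear(grid, miss)
  for (m in which(colSums(miss) > 0 & !imp$all_missing)) {
    obs <- grid[!miss[, m], m]
    filled <- imp$steps[miss[, m], m]
    expect_true(all(filled >= min(obs) - 1e-9 & filled <= max(obs) + 1e-9))
  }
})

test_that("daily totals and medians follow the stated conventions", {
  grid <- matrix(9000 / 1440, 7, 1440)
  expect_equal(daily_steps(grid)$median_daily, 9000)
  totals <- c(8, 9, 10, 11, 12, 13, 14) * 1000
  grid2 <- matrix(0, 7, 1440); grid2[, 1] <- totals
  expect_equal(daily_steps(grid2)$median_daily, 11000)
  # even count: mean of the middle two
  grid3 <- matrix(0, 6, 1440); grid3[, 1] <- c(1, 2, 3, 4, 5, 6) * 1000
  expect_equal(daily_steps(grid3)$median_daily, 3500)
  expect_true(is.na(daily_steps(grid3, valid_days = rep(FALSE, 6))$median_daily))
})

test_that("peak one-minute cadence is the median of the day maxima", {
  grid <- matrix(0, 3, 1440)
  grid[1, 600] <- 117; grid[2, 30] <- 117; grid[3, 1200] <- 117
  expect_equal(peak_1min_cadence(grid)$peak_cadence, 117)
  grid2 <- matrix(0, 3, 1440)
  grid2[1, 5] <- 110; grid2[2, 5] <- 115; grid2[3, 5] <- 120
  expect_equal(peak_1min_cadence(grid2)$peak_cadence, 115)
  # a uniform 60 steps/min 10-minute bout each day gives exactly 60
  grid3 <- matrix(0, 3, 1440); grid3[, 200:209] <- 60
  expect_equal(peak_1min_cadence(grid3)$peak_cadence, 60)
})

test_that("the daily summary ties the pieces together", {
  grid <- matrix(5, 4, 1440)
  miss <- matrix(FALSE, 4, 1440); miss[1, 1:10] <- TRUE
  s <- daily_summary(grid, miss, wear_hours = 96,
                     hours_covered = rep(TRUE, 24),
                     mean_acceleration_mg = 28)
  expect_true(s$include)
  expect_equal(s$median_daily, 5 * 1440)
  expect_equal(s$imputed_minutes, 10L)
  s2 <- daily_summary(grid, miss, wear_hours = 20,
                      hours_covered = rep(TRUE, 24))
  expect_false(s2$include)
  expect_gte(length(s2$qc_flags), 1L)
})
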
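test_that("monthly anomaly subtracts the calendar-month climatology", {
  # two baseline Januaries with values 1 and 3: new January value 4 -> 2
  x <- c(1, 3, 4)
  mo <- c(1, 1, 1)
  yr <- c(2000, 2001, 2002)
  a <- monthly_anomaly(x, mo, yr, 2000:2001)
  expect_equal(a[3], 2)
  # a constant series is its own climatology regardless of baseline
  xc <- rep(5, 36)
  mo36 <- rep(1:12, 3)
  yr36 <- rep(2000:2002, each = 12)
  expect_equal(monthly_anomaly(xc, mo36, yr36, 2000:2002), rep(0, 36))
  expect_equal(monthly_anomaly(xc, mo36, yr36, 2000:2000), rep(0, 36))
  expect_error(monthly_anomaly(1:3, c(1, 2, 3), c(2000, 2000, 2001), 2001),
               "month 1")
})

test_that("anomalies average to zero over the baseline, per calendar month", {
  set.seed(3)
  yr <- rep(1980:2009, each = 12)
  mo <- rep(1:12, 30)
  x <- 10 + 3 * sin(2 * pi * mo / 12) + rnorm(360)
  a <- monthly_anomaly(x, mo, yr, 1980:2009)
  for (m in 1:12) expect_equal(mean(a[mo == m]), 0, tolerance = 1e-12)
})

test_that("trailing rolling mean averages the current and previous months", {
  expect_equal(rolling_mean(c(4, 8, 15), window = 1), c(4, 8, 15))
  expect_equal(rolling_mean(c(0, 3, 6), window = 3)[3], 3)
  expect_equal(rolling_mean(rep(2.5, 10), window = 3), rep(2.5, 10))
  # partial head: averages over the months available so far
  expect_equal(rolling_mean(c(2, 4, 6, 8), window = 3),
               c(2, 3, 4, 6))
  expect_equal(rolling_mean(c(2, 4, 6), window = 3, partial = FALSE),
               c(NA, NA, 4))
  expect_error(rolling_mean(1:3, window = 0), "window")
})

test_that("drought length counts runs of positive anomalies", {
  expect_identical(drought_length(c(0.2, 0.3, -0.1, 0.5)), c(1L, 2L, 0L, 1L))
  expect_identical(drought_length(rep(-1, 5)), rep(0L, 5))
  expect_identical(drought_length(rep(1, 4)), 1:4)
  expect_identical(drought_length(numeric(0)), integer(0))
  expect_identical(drought_length(c(0, 0.1)), c(0L, 1L))  # zero is not positive
})

test_that("drought length is a valid run-length counter on random series", {
  set.seed(11)
  for (k in 1:50) {
    ta <- rnorm(60)
    dl <- drought_length(ta)
    pos <- which(dl > 0)
    starts <- pos[dl[pos] == 1]
    increments <- pos[dl[pos] > 1]
    expect_true(all(dl[increments] == dl[increments - 1] + 1))
    expect_true(all(dl[starts] == 1))
    expect_true(all(dl[ta <= 0] == 0))
  }
})

test_that("climate forcing: median-ratio and mean-deviation forms", {
  # two regions whose values at one period sit exactly at their medians
  TA <- rep(0, 10)
  p <- make_toy_panel(2, 5, conflict = rep(1L, 10),
                      TA = TA, DL = rep(0L, 10),
                      PA = c(1, 2, 2, 2, 9, 3, 4, 4, 4, 11))
  # medians: region 1 -> 2, region 2 -> 4
  fc <- climate_forcing(p, "PA", "median_ratio")
  expect_equal(fc$C[2], 2)  # both ratios are 1
  expect_equal(unname(fc$denominators), c(2, 4))
  # a value at twice the region median contributes 2
  p1 <- make_toy_panel(1, 5, PA = c(3, 3, 6, 3, 3), TA = rep(0, 5),
                       DL = rep(0L, 5), conflict = rep(1L, 5))
  fc1 <- climate_forcing(p1, "PA", "median_ratio")
  expect_equal(fc1$C[3], 2)
  # mean-deviation mode centres each region at zero
  fm <- climate_forcing(p, "PA", "mean_deviation")
  expect_equal(sum(fm$C), 0, tolerance = 1e-12)
  # near-zero median raises the guard with actionable advice
  pz <- make_toy_panel(1, 5, PA = c(-1, -2, 0, 2, 1), TA = rep(0, 5),
                       DL = rep(0L, 5), conflict = rep(1L, 5))
  expect_error(climate_forcing(pz, "PA", "median_ratio"), "mean_deviation")
  expect_error(climate_forcing(p, "nope"), "unknown panel column")
})

test_that("group means are constant within groups and mass-conserving", {
  p <- make_toy_panel(4, 6, seed = 5)
  gm <- group_means(p)
  # weighted grand mean of region means equals the raw column mean
  expect_equal(mean(gm$region_means$TA), mean(p$TA), tolerance = 1e-12)
  expect_equal(mean(gm$period_means$TA), mean(p$TA), tolerance = 1e-12)
  p2 <- add_group_means(p)
  expect_true(all(tapply(p2$TA_bar_i, p2$region,
                         function(x) diff(range(x)) == 0)))
  expect_true(all(tapply(p2$DL_bar_t, p2$period,
                         function(x) diff(range(x)) == 0)))
  # two regions with TA 1 and 3 at a period average to 2
  q <- make_toy_panel(2, 1, TA = c(1, 3), DL = c(0L, 0L), PA = c(0, 0),
                      conflict = c(0L, 0L))
  expect_equal(group_means(q)$period_means$TA, 2)
})
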
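hourly_panel <- function(values_by_monitor, date = "2010-06-01") {
  do.call(rbind, lapply(names(values_by_monitor), function(m) {
    v <- values_by_monitor[[m]]
    data.frame(date = date, hour = which(!is.na(v)) - 1L,
               monitor_id = m, value = v[!is.na(v)])
  }))
}

test_that("daily mean averages monitors within hours, then hours, with completeness", {
  p <- hourly_panel(list(a = rep(10, 24), b = rep(20, 24)))
  expect_equal(daily_mean_across_monitors(p)$value, 15)

  p2 <- hourly_panel(list(a = 1:24))
  expect_equal(daily_mean_across_monitors(p2)$value, 12.5)

  v <- rep(NA_real_, 24); v[1:10] <- 5
  p3 <- hourly_panel(list(a = v))
  expect_true(is.na(daily_mean_across_monitors(p3, completeness = 0.75)$value))
  expect_equal(daily_mean_across_monitors(p3, completeness = 10 / 24)$value, 5)

  # monitor-first averaging: monitor b reports only in hours where it reads 0
  v1 <- rep(10, 24); v2 <- rep(NA_real_, 24); v2[1:12] <- 0
  p4 <- hourly_panel(list(a = v1, b = v2))
  expect_equal(daily_mean_across_monitors(p4)$value, mean(c(rep(5, 12), rep(10, 12))))

  expect_error(daily_mean_across_monitors(p[0, ]), "empty")
})

test_that("daily maximum 8-h mean scans same-day windows with a validity minimum", {
  h <- data.frame(date = "2010-06-01", hour = 0:23, value = 30)
  expect_equal(daily_max_8h(h)$value, 30)

  h2 <- data.frame(date = "2010-06-01", hour = 0:23, value = 1:24)
  expect_equal(daily_max_8h(h2)$value, mean(17:24))  # 20.5, window 16-23

  h3 <- data.frame(date = "2010-06-01", hour = 0:5, value = 50)
  expect_equal(daily_max_8h(h3)$value, 50)            # one 6-hour valid window
  expect_true(is.na(daily_max_8h(h3, min_hours_in_window = 7)$value))

  h4 <- data.frame(date = "2010-06-01", hour = 0:23, value = NA_real_)
  h4 <- rbind(h4, data.frame(date = "2010-06-02", hour = 0:23, value = 1))
  expect_equal(daily_max_8h(h4)$value, c(NA, 1))
})

test_that("AQHI formula reproduces frozen values and its zero point exactly", {
  expect_identical(compute_aqhi(0, 0, 0), 0)
  expect_equal(compute_aqhi(16.1, 31.5, 6.0), 3.2795706984, tolerance = 1e-9)
  expect_equal(compute_aqhi(62.3, 85.9, 44.8), 12.0219856991, tolerance = 1e-9)
  expect_true(is.na(compute_aqhi(NA, 10, 10)))
  expect_error(compute_aqhi(-1, 0, 0), "non-negative")
})

test_that("AQHI is strictly increasing in each argument and 0 only at the origin", {
  set.seed(5)
  base <- matrix(runif(90, 0, 80), ncol = 3)
  for (j in 1:3) {
    lo <- base; hi <- base; hi[, j] <- hi[, j] + runif(30, 0.1, 5)
    expect_true(all(compute_aqhi(hi[, 1], hi[, 2], hi[, 3]) >
                      compute_aqhi(lo[, 1], lo[, 2], lo[, 3])))
  }
  expect_true(all(compute_aqhi(base[, 1], base[, 2], base[, 3]) > 0))
})

test_that("lag_series shifts by k days with missing lead-in", {
  x <- c(1, 2, 3)
  expect_identical(lag_series(x, 0), x)
  expect_equal(lag_series(x, 1), c(NA, 1, 2))
  expect_true(all(is.na(lag_series(x, 5))))
  expect_error(lag_series(x, -1), "non-negative")
})

test_that("lags compose: lag a then b equals lag a + b on the overlap", {
  set.seed(6)
  x <- rnorm(50)
  for (ab in list(c(0, 3), c(1, 2), c(4, 5))) {
    a <- ab[1]; b <- ab[2]
    two <- lag_series(lag_series(x, a), b)
    one <- lag_series(x, a + b)
    expect_equal(two[-(seq_len(a + b))], one[-(seq_len(a + b))])
  }
})

test_that("IQR scaling uses type-7 quantiles and behaves affinely", {
  expect_equal(iqr_spec(rep(7, 10))$iqr, 0)
  # five-point series whose quartiles are the printed ozone Q1/Q3
  o3 <- c(3.3, 24.0, 31.5, 40.0, 85.9)
  expect_equal(iqr_spec(o3, "o3")$iqr, 16.0)
  pm <- c(0.1, 3.8, 6.0, 9.8, 44.8)
  expect_equal(iqr_spec(pm)$iqr, 6.0)

  set.seed(7)
  x <- rnorm(101)
  expect_equal(iqr_spec(x + 5)$iqr, iqr_spec(x)$iqr)
  expect_equal(iqr_spec(3 * x)$iqr, 3 * iqr_spec(x)$iqr)
  expect_error(iqr_spec(c(1, NA)), "at least 2")
})

test_that("add_lags appends pollutant and matching temperature columns", {
  e <- data.frame(date = as.Date("2010-01-01") + 0:9,
                  no2 = 1:10, o3 = 11:20, pm25 = 21:30, temp = 0:9)
  out <- add_lags(e, lags = 0:2)
  expect_true(all(c("no2_lag2", "temp_lag2", "pm25_lag0") %in% names(out)))
  expect_equal(out$no2_lag2, c(NA, NA, 1:8))
  expect_equal(out$temp_lag1, c(NA, 0:8))
})
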
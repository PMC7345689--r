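# small synthetic world shared by the grid tests
grid_world <- function(n_days = 3 * 365, rr = 1, lag = 1, seed = 18,
                       series = NULL) {
  set.seed(seed)
  truth <- simulation_truth(effect_pollutant = "pm25", effect_lag = lag,
                            series = series)
  expo <- simulate_exposures(n_days, truth)
  truth$beta <- log(rr) / iqr_spec(expo$pm25)$iqr
  counts <- simulate_counts(expo, truth, subgroups = TRUE)
  list(expo = expo, counts = counts, truth = truth)
}

test_that("the grid has exactly one row per subgroup x pollutant x lag cell", {
  w <- grid_world(400)
  sub <- data.frame(sex = "all", age_group = "all", category = "all")
  g <- run_grid(w$counts, w$expo, subgroups = sub, pollutants = "pm25", lags = 0:5)
  expect_s3_class(g, "cc_grid")
  expect_identical(nrow(g), 6L)
  expect_identical(g$lag, 0:5)
  expect_true(all(!is.na(g$rr)))
  expect_true(all(g$rr_low <= g$rr & g$rr <= g$rr_high))

  g2 <- run_grid(w$counts, w$expo, subgroups = sub, pollutants = "pm25", lags = 0:5)
  expect_identical(g, g2)  # deterministic re-run
})

test_that("a simulated lag-1 effect is localised to lag 1 in most replicates", {
  # weak exposure autocorrelation so distant lags are nearly independent of
  # the causal one; with strong AR(1) a lag-1 effect genuinely leaks into
  # neighbouring lags through the exposure series itself
  set.seed(101)
  sub <- data.frame(sex = "all", age_group = "all", category = "all")
  hits <- replicate(20, {
    truth <- simulation_truth(effect_pollutant = "pm25", effect_lag = 1,
                              series = list(pm25 = list(ar = 0.2)))
    expo <- simulate_exposures(4 * 365, truth)
    truth$beta <- log(1.15) / iqr_spec(expo$pm25)$iqr
    counts <- simulate_counts(expo, truth)
    g <- run_grid(counts, expo, subgroups = sub, pollutants = "pm25",
                  lags = c(1, 4, 5))
    sig <- g$rr_low > 1
    sig[g$lag == 1] && !sig[g$lag == 4] && !sig[g$lag == 5]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("empty subgroups fail gracefully with a reason, not an error", {
  w <- grid_world(400)
  counts <- w$counts[w$counts$sex == "M", ]
  sub <- data.frame(sex = c("M", "F"), age_group = "all", category = "all")
  g <- run_grid(counts, w$expo, subgroups = sub, pollutants = "no2", lags = 0)
  expect_identical(nrow(g), 2L)
  expect_false(is.na(g$rr[g$sex == "M"]))
  expect_true(is.na(g$rr[g$sex == "F"]))
  expect_match(g$note[g$sex == "F"], "zero counts")
})

test_that("significance map is 1 exactly when the lower limit exceeds 1", {
  fake <- data.frame(
    subgroup = rep(c("A", "M"), each = 3), pollutant = "no2",
    lag = rep(0:2, 2),
    rr_low = c(1.01, 0.99, 1.0, NA, 1.2, 0.5),
    rr = 1.1, rr_high = 2
  )
  class(fake) <- c("cc_grid", "data.frame")
  m <- significance_map(fake)
  expect_identical(as.integer(m["A.no2", ]), c(1L, 0L, 0L))  # boundary 1.0 -> 0
  expect_identical(as.integer(m["M.no2", ]), c(0L, 1L, 0L))  # NA -> 0
})

test_that("period split rebuilds strata within each half and pairs the cells", {
  w <- grid_world(2 * 365)
  cut <- as.Date(w$expo$date[365])
  sub <- data.frame(sex = "all", age_group = "all", category = "all")
  sp <- sensitivity_split(w$counts, w$expo, cutpoint = cut, subgroups = sub,
                          pollutants = "no2", lags = 0:1)
  expect_s3_class(sp, "cc_split")
  expect_identical(nrow(sp$comparison), 2L)
  # each half used only its own days
  expect_lte(max(sp$first$n_days), 365L)
  expect_lte(max(sp$second$n_days), 365L)
  expect_error(sensitivity_split(w$counts, w$expo, cutpoint = "2050-01-01"),
               "inside the study period")
})

test_that("AQHI sensitivity computes the index when absent and scales by its IQR", {
  w <- grid_world(400)
  expo2 <- w$expo[setdiff(names(w$expo), "aqhi")]
  sub <- data.frame(sex = "all", age_group = "all", category = "all")
  g <- aqhi_sensitivity(w$counts, expo2, subgroups = sub, lags = 0:1)
  expect_identical(unique(g$pollutant), "aqhi")
  expect_equal(unname(attr(g, "iqr")["aqhi"]),
               iqr_spec(compute_aqhi(expo2$no2, expo2$o3, expo2$pm25))$iqr)
  expect_true(all(!is.na(g$rr)))
})

test_that("result files follow the conventional report layout", {
  w <- grid_world(400)
  sub <- rbind(
    data.frame(sex = c("all", "M", "F"), age_group = "all", category = "all"),
    data.frame(sex = "M", age_group = "13-18", category = "all"),
    data.frame(sex = "all", age_group = "all", category = "mood")
  )
  g <- run_grid(w$counts, w$expo, subgroups = sub, pollutants = "pm25", lags = 0:1)
  dir <- withr::local_tempdir()
  files <- write_result_files(g, dir)
  expect_setequal(basename(files),
                  c("ResAll.csv", "ResAgeGSex.csv", "ResTypeAMF.csv", "SigMap.csv"))
  res_all <- read.csv(file.path(dir, "ResAll.csv"))
  expect_identical(nrow(res_all), 6L)   # 3 sexes x 2 lags
  expect_identical(nrow(read.csv(file.path(dir, "ResAgeGSex.csv"))), 2L)
  expect_identical(nrow(read.csv(file.path(dir, "ResTypeAMF.csv"))), 2L)
})
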
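test_that("growing-season detection follows the 5 degC all-cold-day rule", {
  # foothill-like: an all-cold day in April (and in every other off-season
  # month) leaves May-September as the longest qualifying run
  fh <- make_env(cold_months = c(1:4, 10:12))
  gs <- detect_growing_season(fh)
  expect_equal(format(gs$start_date), "2023-05-01")
  expect_equal(format(gs$end_date), "2023-09-30")
  expect_equal(gs$hours, 3672L)
  # alpine-like: one all-cold day in May shortens the season to June-September
  ate <- make_env(cold_months = c(1:5, 10:12))
  gs2 <- detect_growing_season(ate)
  expect_equal(format(gs2$start_date), "2023-06-01")
  expect_equal(gs2$hours, 2928L)
  # constant 10 degC all year: every month qualifies
  gs3 <- detect_growing_season(make_env())
  expect_equal(format(gs3$start_date), "2023-01-01")
  expect_equal(format(gs3$end_date), "2023-12-31")
})

test_that("season ties break toward the run holding the warmest month", {
  env <- make_env(cold_months = c(1, 2, 6, 10, 11, 12), warm_months = 7)
  gs <- detect_growing_season(env) # Mar-May vs Jul-Sep, July warmest
  expect_equal(format(gs$start_date), "2023-07-01")
  expect_equal(format(gs$end_date), "2023-09-30")
})

test_that("incomplete month coverage is a detection error", {
  env <- make_env()
  expect_error(detect_growing_season(env[-1, ]), "coverage")
  expect_error(detect_growing_season(env[1:100, ]), "coverage")
})

test_that("cumulative exposure reproduces the 150 ppm seasonal-sum example", {
  gs <- growing_season("2023-06-01", "2023-09-30") # 30+31+31+30 days
  env <- make_env(o3 = 52)
  expect_equal(cumulative_exposure(env, gs, round_to = 10), 150)
  expect_equal(cumulative_exposure(env, gs), 52 * gs$hours / 1000)
  expect_equal(cumulative_exposure(make_env(o3 = 0), gs), 0)
  # unit check: constant 1 ppb contributes hours/1000 ppm
  expect_equal(cumulative_exposure(make_env(o3 = 1), gs), gs$hours / 1000)
})

test_that("exposure sums are additive and enforce the coverage floor", {
  env <- make_env(o3 = 37)
  june <- growing_season("2023-06-01", "2023-06-30")
  july <- growing_season("2023-07-01", "2023-07-31")
  both <- growing_season("2023-06-01", "2023-07-31")
  expect_equal(cumulative_exposure(env, june) + cumulative_exposure(env, july),
               cumulative_exposure(env, both))
  # 15 % missing ozone -> coverage error; 5 % missing -> excluded with message
  env2 <- env
  idx <- which(as.Date(env2$timestamp) >= june$start_date &
                 as.Date(env2$timestamp) <= june$end_date)
  env2$o3_ppb[idx[seq_len(0.15 * length(idx))]] <- NA
  expect_error(cumulative_exposure(env2, june), "data-coverage")
  env3 <- env
  env3$o3_ppb[idx[seq_len(0.05 * length(idx))]] <- NA
  expect_message(v <- cumulative_exposure(env3, june), "excluding")
  expect_equal(v, 37 * (length(idx) - 36) / 1000)
})

test_that("sumO3 and avgO3 conversions are exact inverses at the study seasons", {
  ate <- growing_season("2023-06-01", "2023-09-30")
  fh <- growing_season("2023-05-01", "2023-09-30")
  expect_equal(round(sum_to_avg(464.0, ate), 1), 158.5)
  expect_equal(round(sum_to_avg(426.0, fh), 1), 116.0)
  expect_equal(sum_to_avg(0, ate), 0)
  for (x in c(0.1, 52.7, 158.5, 400)) {
    expect_equal(sum_to_avg(avg_to_sum(x, ate), ate), x, tolerance = 1e-14)
  }
  expect_error(sum_to_avg(100, 0), "positive")
})

test_that("AOT40 accumulates daylight excess over 40 ppb", {
  gs <- growing_season("2023-06-01", "2023-09-30")
  expect_equal(aot40(make_env(o3 = 40), gs), 0)
  env50 <- make_env(o3 = 50)
  n_day <- sum(as.Date(env50$timestamp) >= gs$start_date &
                 as.Date(env50$timestamp) <= gs$end_date &
                 env50$glob_rad_wm2 >= 50)
  expect_equal(aot40(env50, gs), n_day * 10 / 1000)
  # brute-force hour-by-hour oracle on a diurnal profile
  env <- make_env()
  hr <- as.integer(format(env$timestamp, "%H"))
  env$o3_ppb <- pmax(0, 45 + 20 * sin(2 * pi * (hr - 15) / 24))
  sub <- env[as.Date(env$timestamp) >= gs$start_date &
               as.Date(env$timestamp) <= gs$end_date, ]
  manual <- 0
  for (i in seq_len(nrow(sub))) {
    if (sub$glob_rad_wm2[i] >= 50 && sub$o3_ppb[i] > 40) {
      manual <- manual + (sub$o3_ppb[i] - 40)
    }
  }
  expect_equal(aot40(env, gs), manual / 1000)
  # monotone in o3 pointwise
  env_hi <- env; env_hi$o3_ppb <- env$o3_ppb + 5
  expect_gte(aot40(env_hi, gs), aot40(env, gs))
  expect_error(aot40(env[, setdiff(names(env), "glob_rad_wm2")], gs),
               "glob_rad")
})
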
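test_that("generators are bit-identical under a fixed seed and leave no RNG trace", {
  cfg <- synthetic_config(seed = 21)
  set.seed(999); before <- runif(3)
  set.seed(999)
  e1 <- generate_env_series(cfg)
  d1 <- generate_ozonation_series(cfg)
  x1 <- generate_conductivity_experiment(cfg)
  p1 <- generate_peak_table(cfg)
  after <- runif(3)
  expect_identical(before, after) # global RNG stream untouched
  expect_identical(e1, generate_env_series(cfg))
  expect_identical(d1, generate_ozonation_series(cfg))
  expect_identical(x1, generate_conductivity_experiment(cfg))
  expect_identical(p1, generate_peak_table(cfg))
  cfg2 <- synthetic_config(seed = 22)
  expect_false(identical(d1, generate_ozonation_series(cfg2)))
})

test_that("ozone profiles match their zone: flat at the treeline, diurnal below", {
  ate <- generate_env_series(synthetic_config(seed = 4, "alpine-flat"))
  day <- as.Date(ate$timestamp)
  daily_means <- tapply(ate$o3_ppb, day, mean)
  expect_true(all(abs(daily_means - 52.7) <= 0.1))
  fh <- generate_env_series(synthetic_config(seed = 4, "foothill-diurnal"))
  hr <- as.integer(format(fh$timestamp, "%H"))
  daytime <- hr >= 10 & hr <= 18
  expect_gt(mean(fh$o3_ppb[daytime]), mean(fh$o3_ppb[!daytime]))
  expect_true(all(fh$o3_ppb >= 0))
  expect_error(synthetic_config(zone_profile = "alpine-flat",
                                o3_diurnal_amplitude = 10), "zero diurnal")
})

test_that("generated temperature fields reproduce the study growing seasons", {
  ate <- generate_env_series(synthetic_config(seed = 31, "alpine-flat"))
  gs <- detect_growing_season(ate)
  expect_equal(format(gs$start_date), "2023-06-01")
  expect_equal(format(gs$end_date), "2023-09-30")
  fh <- generate_env_series(synthetic_config(seed = 31, "foothill-diurnal"))
  gs2 <- detect_growing_season(fh)
  expect_equal(format(gs2$start_date), "2023-05-01")
  expect_equal(format(gs2$end_date), "2023-09-30")
})

test_that("ozonation series add the chamber dose to the ambient seasonal sum", {
  cfg <- synthetic_config(seed = 5, o3_mean = 154000 / 2928, chamber_sd = 0)
  expect_equal(generate_ozonation_series(cfg),
               c(154, 304, 604, 904, 1204, 1654), tolerance = 1e-12)
  cfg0 <- synthetic_config(seed = 5, chamber_concentration = 0, chamber_sd = 0)
  expect_equal(generate_ozonation_series(cfg0),
               rep(52.7 * 2928 / 1000, 6), tolerance = 1e-12)
  # default jitter keeps doses in the magnitudes of the reference experiment
  d <- generate_ozonation_series(synthetic_config(seed = 6))
  expect_true(all(diff(d) > 0))
  expect_gt(d[1], 100); expect_lt(d[1], 200)
  expect_gt(d[6], 1200); expect_lt(d[6], 2300)
})

test_that("noise-free conductivity experiments invert exactly through the pipeline", {
  cfg <- synthetic_config(seed = 8, noise_sd = 0, chamber_sd = 0)
  exp0 <- generate_conductivity_experiment(cfg)
  ii <- injury_indices(exp0$measurements)
  expect_equal(ii$inx, 10 * exp(8e-4 * exp0$doses), tolerance = 1e-12)
  fit <- suppressWarnings(fit_exponential_baseline(exp0$doses, ii$inx))
  expect_equal(fit$a, 10, tolerance = 1e-9)
  expect_equal(fit$b, 8e-4, tolerance = 1e-9)
})

test_that("peak tables carry the configured monoterpene decline", {
  pt <- generate_peak_table(synthetic_config(seed = 13,
                                             composition_effect = 0.4))
  prof <- aggregate_classes(normalise_peak_areas(pt))
  expect_equal(as.numeric(tapply(prof$pct, prof$sample_id, sum)),
               rep(100, 18), tolerance = 1e-9)
  mono <- prof[prof$class == "monoterpene", ]
  m <- tapply(mono$pct, mono$ozonation_category, mean)
  expect_true(m[["A"]] > m[["B"]] && m[["B"]] > m[["C"]])
  sesq <- prof[prof$class == "sesquiterpene", ]
  s <- tapply(sesq$pct, sesq$ozonation_category, mean)
  expect_lt(max(s) - min(s), 10) # sesquiterpene share stays stable
})
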
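test_that("conductance response functions hit their analytic anchors", {
  p <- flux_params(t_min = 0, t_opt = 20, t_max = 35, light_a = 0.006,
                   vpd_min = 0.5, vpd_max = 3.0, fmin = 0.1)
  expect_equal(f_temp(20, p), 1)
  expect_equal(f_temp(0, p), 0)
  expect_equal(f_temp(35, p), 0)
  expect_equal(f_temp(-5, p), 0)
  expect_equal(f_temp(10, p), 0.5 * (25 / 15)^0.75, tolerance = 1e-12)
  expect_equal(f_light(0, p), 0)
  expect_equal(f_light(1e9, p), 1)
  expect_equal(f_light(500, p), 1 - exp(-3), tolerance = 1e-12)
  expect_error(f_light(-1, p), ">= 0")
  expect_equal(f_vpd(0.5, p), 1)
  expect_equal(f_vpd(0.2, p), 1)
  expect_equal(f_vpd(3.0, p), 0.1)
  expect_equal(f_vpd(5.0, p), 0.1)
  expect_equal(f_vpd(1.75, p), (1 + 0.1) / 2)
  # bounded in [0, 1] over wide sweeps
  tt <- seq(-20, 50, by = 0.5)
  expect_true(all(f_temp(tt, p) >= 0 & f_temp(tt, p) <= 1))
  vv <- seq(0, 8, by = 0.1)
  expect_true(all(f_vpd(vv, p) >= 0.1 & f_vpd(vv, p) <= 1))
})

test_that("phenology ramps linearly at the season edges", {
  p <- flux_params(phen_ramp_days = 10)
  gs <- growing_season("2023-06-01", "2023-09-30")
  expect_equal(f_phen(as.Date("2023-07-15"), gs, p), 1)
  expect_equal(f_phen(as.Date("2023-05-31"), gs, p), 0)
  expect_equal(f_phen(as.Date("2023-10-01"), gs, p), 0)
  expect_equal(f_phen(as.Date("2023-06-06"), gs, p), 0.5) # mid-ramp
  expect_equal(f_phen(as.Date("2023-09-25"), gs, p), 0.5)
})

test_that("multiplicative conductance obeys the floor rule and bounds", {
  p <- flux_params()
  # all factors at 1 (saturating light, optimal T, low VPD) -> gmax
  expect_equal(stomatal_conductance(p$t_opt, 1e9, 0.1, p), p$gmax)
  expect_equal(stomatal_conductance(p$t_opt, 0, 0.1, p), 0) # night
  # f_temp * f_vpd below fmin with the others at 1 -> gmax * fmin
  expect_equal(stomatal_conductance(p$t_min + 0.1, 1e9, p$vpd_max, p),
               p$gmax * p$fmin)
  set.seed(1)
  g <- stomatal_conductance(runif(200, -10, 45), runif(200, 0, 2000),
                            runif(200, 0, 6), p)
  expect_true(all(g >= 0 & g <= p$gmax))
})

test_that("stomatal flux matches the hand-evaluated resistance chain", {
  p <- flux_params()
  gsto <- stomatal_conductance(18, 800, 1.2, p)
  expect_equal(gsto, oracle$flux_record$gsto, tolerance = 1e-9)
  fst <- stomatal_o3_flux(50, 18, gsto, p, wind_speed = 2)
  expect_equal(fst, oracle$flux_record$fst, tolerance = 1e-9)
  # closed stomata and no external conductance -> zero flux
  p0 <- flux_params(gext = 0)
  expect_equal(stomatal_o3_flux(50, 18, 0, p0), 0)
  # vanishing boundary layer -> deposition velocity equals gsto in m/s
  pnb <- flux_params(leaf_dimension = 1e-14, gext = 0)
  gsto_ms <- 77.8071679286 * 1e-3 * 8.31446261815324 * 291.15 / 101325
  expect_equal(stomatal_o3_flux(50, 18, 77.8071679286, pnb),
               o3_concentration(50, 18) * gsto_ms, tolerance = 1e-6)
  expect_error(stomatal_o3_flux(50, 18, 10, p, wind_speed = 0), "wind")
  expect_error(stomatal_o3_flux(-1, 18, 10, p), ">= 0")
})

test_that("POD accumulation converts flux hours and is monotone in Y", {
  # constant 1 nmol m-2 s-1 over 1000 daylight hours -> 3.6 mmol m-2
  fst <- rep(1, 1200); rad <- c(rep(500, 1000), rep(0, 200))
  expect_equal(accumulate_pod(fst, rad, y = 0), 3.6)
  expect_equal(accumulate_pod(fst, rad, y = 2), 0) # y above max flux
  set.seed(2)
  f <- runif(500, 0, 8); r <- runif(500, 0, 800)
  pods <- vapply(c(0, 0.5, 1, 2, 4), function(y) accumulate_pod(f, r, y),
                 numeric(1))
  expect_true(all(diff(pods) <= 0))
})

test_that("flat-profile critical-level projection is linear in concentration", {
  cfg <- synthetic_config(seed = 11, zone_profile = "alpine-flat")
  env <- generate_env_series(cfg)
  gs <- growing_season("2023-06-01", "2023-09-30")
  p <- flux_params(species = "pinus_mugo")
  expect_equal(project_cl_oxs(0, env, p, gs), 0)
  pod1 <- project_cl_oxs(52.7, env, p, gs)
  pod2 <- project_cl_oxs(105.4, env, p, gs)
  expect_equal(pod2 / pod1, 2, tolerance = 1e-12)
  expect_equal(project_cl_oxs(158.5, env, p, gs) / pod1, 158.5 / 52.7,
               tolerance = 1e-12)
  expect_gt(pod1, 0)
})

test_that("a daytime ozone peak raises POD0 over the flat profile at equal mean", {
  cfg <- synthetic_config(seed = 12, zone_profile = "foothill-diurnal")
  env <- generate_env_series(cfg)
  gs <- growing_season("2023-05-01", "2023-09-30")
  p <- flux_params(species = "pinus_mugo")
  flat_mean <- mean(env$o3_ppb)
  pod_diurnal <- compute_pod(env, p, gs)
  pod_flat <- project_cl_oxs(flat_mean, env, p, gs)
  expect_gte(pod_diurnal, pod_flat)
})

test_that("species presets borrow parameter sets as documented", {
  expect_equal(unclass(flux_params(species = "pinus_sylvestris")),
               unclass(flux_params(species = "pinus_cembra")))
  expect_equal(unclass(flux_params(species = "abies_alba")),
               unclass(flux_params(species = "picea_abies")))
  # explicit arguments beat the preset
  expect_equal(flux_params(species = "pinus_mugo", gmax = 99)$gmax, 99)
  expect_error(flux_params(species = "quercus_robur"), "unknown species")
  expect_error(flux_params(t_min = 20, t_opt = 10), "t_min")
  expect_error(flux_params(fmin = 1.2))
})

test_that("tolerance utilisation is the ambient share of the critical level", {
  expect_equal(round(tolerance_utilisation(8.2, 32.2), 1), 25.5)
  expect_equal(tolerance_utilisation(5, 5), 100)
  expect_error(tolerance_utilisation(1, 0), "> 0")
})
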
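test_that("mesocosm generator is deterministic and respects null configs", {
  cfg <- quick_site()
  expect_identical(gen_mesocosm_study(cfg, seed = 7),
                   gen_mesocosm_study(cfg, seed = 7))
  expect_false(identical(gen_mesocosm_study(cfg, seed = 7),
                         gen_mesocosm_study(cfg, seed = 8)))
  # no noise, no effect: every export Si:N equals the baseline exactly
  null <- gen_mesocosm_study(quick_site(noise_cv = 0, oa_export_multiplier = 1),
                             seed = 1)
  expect_equal(unique(null$si / null$n), 1.0, tolerance = 1e-12)
})

test_that("generated export Si:N is centred on its configured value", {
  # moment fidelity: sample mean within 3 noise standard errors of centre
  cfg <- mesocosm_site_config(baseline_si_n = 1.8, n_days = 30)
  study <- gen_mesocosm_study(cfg, seed = 42)
  amb <- study[study$compartment == "export" & study$pco2_uatm < 500, ]
  n <- nrow(amb)
  se <- 1.8 * cfg$noise_cv * sqrt(2) / sqrt(n)  # ratio of two noisy variates
  expect_lt(abs(mean(amb$si / amb$n) - 1.8), 3 * se)
  # OA group centred on baseline x multiplier
  oa <- study[study$compartment == "export" & study$pco2_uatm >= 700, ]
  expect_lt(abs(mean(oa$si / oa$n) - 1.8 * 1.17), 3 * 1.17 * se)
})

test_that("salinity attenuation suppresses the export effect at brackish sites", {
  cfg <- quick_site(salinity = 6, salinity_attenuation = TRUE, noise_cv = 0)
  study <- gen_mesocosm_study(cfg, seed = 1)
  oa <- study[study$compartment == "export" & study$pco2_uatm >= 700, ]
  expect_equal(unique(oa$si / oa$n), 1.0, tolerance = 1e-12)
  # same salinity without the flag keeps the effect
  cfg2 <- quick_site(salinity = 6, noise_cv = 0)
  study2 <- gen_mesocosm_study(cfg2, seed = 1)
  oa2 <- study2[study2$compartment == "export" & study2$pco2_uatm >= 700, ]
  expect_equal(unique(oa2$si / oa2$n), 1.17, tolerance = 1e-12)
})

test_that("mesocosm config guards reject impossible settings", {
  expect_error(mesocosm_site_config(baseline_si_n = 0),
               class = "silicatepump_invalid_config")
  expect_error(mesocosm_site_config(n_ambient = 0),
               class = "silicatepump_invalid_config")
  expect_error(mesocosm_site_config(pco2_oa = 650),
               class = "silicatepump_invalid_config")
  expect_error(mesocosm_site_config(pco2_ambient = 900, pco2_oa = 850),
               class = "silicatepump_invalid_config")
})

test_that("null-effect datasets yield effects indistinguishable from zero", {
  # null embedding across seeds: lnRR coverage behaves like its nominal level
  cfg <- quick_site(oa_export_multiplier = 1, n_days = 5)
  hits <- vapply(1:20, function(s) {
    study <- gen_mesocosm_study(cfg, seed = s)
    pooled <- suppressMessages(pool_treatments(study))
    eff <- site_effect_sizes(pooled)
    eff$significant
  }, logical(1))
  expect_lt(mean(hits), 0.3)  # ~5 % nominal; bound loose at 20 seeds
  z <- vapply(1:20, function(s) {
    study <- gen_mesocosm_study(cfg, seed = s)
    eff <- site_effect_sizes(suppressMessages(pool_treatments(study)))
    eff$lnrr / sqrt(eff$variance)
  }, numeric(1))
  expect_lt(abs(mean(z)), 2 / sqrt(20) * 3)  # mean z-score near 0
})

test_that("trap generator: determinism, eligibility and noiseless recovery", {
  cfg <- trap_compilation_config(n_profiles = 25)
  expect_identical(gen_trap_compilation(cfg, seed = 3),
                   gen_trap_compilation(cfg, seed = 3))
  expect_error(trap_compilation_config(min_levels = 2),
               class = "silicatepump_invalid_config")
  # noiseless statistical mode: regression recovers the coefficient exactly
  cfg0 <- trap_compilation_config(n_profiles = 30, noise_sd = 0,
                                  sin_jitter_sd = 0)
  comp <- gen_trap_compilation(cfg0, seed = 2)
  sl <- suppressWarnings(profile_slopes(filter_profiles(comp)))
  fit <- ph_regression(dplyr::left_join(sl, comp$stations, by = "station_id"))
  expect_equal(fit$slope, -0.0214, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("mechanistic trap mode reflects the kinetics it is driven by", {
  kp_eq <- kinetics_params(k_si0 = 0.08, k_n0 = 0.08, s_ph = 0)
  cfg <- trap_compilation_config(mode = "mechanistic", n_profiles = 6,
                                 flux_noise_cv = 0)
  comp <- gen_trap_compilation(cfg, seed = 1, params = kp_eq)
  sl <- suppressWarnings(profile_slopes(filter_profiles(comp), keep_all = TRUE))
  expect_equal(sl$delta_sin_per_m, rep(0, 6), tolerance = 1e-12)
  expect_error(gen_trap_compilation(cfg, seed = 1),
               class = "silicatepump_invalid_config")  # params required
})

test_that("climatology has realistic vertical gradients and is reproducible", {
  cl <- gen_climatology(seed = 5)
  expect_identical(cl, gen_climatology(seed = 5))
  wide <- tidyr::pivot_wider(cl[cl$depth_m %in% c(0, 3000), ],
                             names_from = "depth_m",
                             values_from = c("ph", "temp_c"))
  dph <- wide$ph_0 - wide$ph_3000
  expect_true(all(dph >= 0.3 & dph <= 0.35))
  dtc <- mean(wide$temp_c_0 - wide$temp_c_3000)
  expect_gt(dtc, 15)
  expect_lt(dtc, 20)
})

test_that("RCP forcings honour their scenario structure", {
  f85 <- gen_rcp_forcing("RCP8.5")
  f60 <- gen_rcp_forcing("RCP6.0")
  expect_error(gen_rcp_forcing("RCP4.5"),
               class = "silicatepump_unknown_scenario")
  # preindustrial reference
  expect_true(all(f85$ph_anomaly[f85$year == 1750] == 0))
  expect_true(all(f85$temp_anomaly[f85$year == 1750] == 0))
  # surface pH anomaly monotonically non-increasing after 1850
  srf <- f85[f85$box == "srf_low" & f85$year >= 1850, ]
  expect_true(all(diff(srf$ph_anomaly) <= 0))
  # projected end-of-century surface pH decline of 0.2-0.4
  expect_gt(srf$ph_anomaly[srf$year == 2100], -0.4 - 1e-9)
  expect_lt(srf$ph_anomaly[srf$year == 2100], -0.2)
  # scenario ordering in magnitude, all years, all boxes
  expect_true(all(abs(f85$ph_anomaly) >= abs(f60$ph_anomaly)))
  # deep boxes lag and are damped relative to the surface
  deep <- f85[f85$box == "abyss_s", ]
  srf_all <- f85[f85$box == "srf_low", ]
  expect_true(all(abs(deep$ph_anomaly) <= abs(srf_all$ph_anomaly)))
  expect_equal(deep$ph_anomaly[deep$year == 2100],
               0.4 * srf_all$ph_anomaly[srf_all$year == 2050])
})

test_that("csv readers round-trip generated data and validate schemas", {
  study <- gen_mesocosm_study(quick_site(), seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(study, f)
  back <- read_mesocosm_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(study))
  comp <- gen_trap_compilation(trap_compilation_config(n_profiles = 4))
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(comp$profiles, f2)
  expect_equal(nrow(read_trap_csv(f2)), nrow(comp$profiles))
  expect_error(read_trap_csv(f), class = "silicatepump_schema_error")
  expect_equal(mass_to_molar(60.08, "si"), 1)
})
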
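test_that("profile filter enforces paired levels and keeps an exact ledger", {
  prof <- toy_profiles()
  filt <- filter_profiles(prof)
  expect_setequal(unique(filt$station_id), c("A", "C"))
  excl <- trap_exclusions(filt)
  expect_equal(excl$station_id, "B")
  expect_equal(excl$reason, "insufficient depth levels")
  # eligible + excluded account for every input station
  expect_equal(length(unique(filt$station_id)) + nrow(excl),
               attr(filt, "n_input"))
  # a level with missing N is dropped; profile kept iff >= 3 paired remain
  prof4 <- tibble::tibble(station_id = "D", lat = 0, lon = 0,
                          depth_m = c(500, 1000, 1500, 2000),
                          si_flux = 1, n_flux = c(1, NA, 1, 1))
  expect_equal(nrow(filter_profiles(prof4)), 3)
  prof3 <- dplyr::mutate(prof4, n_flux = c(1, NA, NA, 1))
  expect_equal(nrow(filter_profiles(prof3)), 0)
  expect_error(filter_profiles(prof[0, ]),
               class = "silicatepump_empty_compilation")
})

test_that("per-profile slope matches hand OLS and rejects flat profiles", {
  prof <- toy_profiles()
  a <- suppressWarnings(profile_slope(prof[prof$station_id == "A", ]))
  # (1000,1.0) (2000,1.2) (3000,1.4): exact line with slope 2e-4 per m
  expect_equal(a$delta_sin_per_m, 2e-4, tolerance = 1e-12)
  expect_equal(a$r2, 1, tolerance = 1e-9)
  flat <- suppressWarnings(profile_slope(prof[prof$station_id == "C", ]))
  expect_equal(flat$delta_sin_per_m, 0)
  expect_false(flat$retained)
  expect_error(profile_slope(tibble::tibble(depth_m = c(5, 5, 5),
                                            si_flux = 1:3, n_flux = 1)),
               class = "silicatepump_degenerate_profile")
  # slope equivariance: scaling Si fluxes scales the slope
  sc <- prof[prof$station_id == "A", ]
  sc$si_flux <- sc$si_flux * 7
  expect_equal(suppressWarnings(profile_slope(sc))$delta_sin_per_m,
               7 * a$delta_sin_per_m)
})

test_that("significance filter rejects null profiles at its nominal rate", {
  set.seed(31)
  depths <- seq(500, 3000, length.out = 5)
  retained <- vapply(1:400, function(i) {
    p <- tibble::tibble(station_id = "x", depth_m = depths,
                        si_flux = 1 + rnorm(5, 0, 0.1), n_flux = 1)
    profile_slope(p)$retained
  }, logical(1))
  expect_equal(mean(retained), 0.05, tolerance = 0.5)  # binomial SE ~ 0.011
  expect_lt(mean(retained), 0.09)
})

test_that("climatology attachment averages over the profile depth range", {
  # uniform column: the mean is the constant, whatever the range
  uni <- tidyr::expand_grid(depth_m = seq(0, 4000, 500), lat = c(-10, 10)) |>
    dplyr::mutate(ph = 8.0, temp_c = 4)
  sl <- tibble::tibble(station_id = "A", lat = 3, delta_sin_per_m = 1e-4,
                       depth_min = 1000, depth_max = 3000)
  out <- attach_environment(sl, uni)
  expect_equal(out$mean_ph, 8.0)
  expect_equal(out$mean_temp, 4)
  # linear pH 8.1 at 0 m to 7.7 at 4000 m: mean over 1000-3000 m is 7.9
  lin <- tidyr::expand_grid(depth_m = seq(0, 4000, 500), lat = 0) |>
    dplyr::mutate(ph = 8.1 - 0.4 * depth_m / 4000, temp_c = 10)
  out2 <- attach_environment(dplyr::mutate(sl, lat = 0), lin)
  expect_equal(out2$mean_ph, 7.9, tolerance = 1e-12)
  # stations outside the grid or deeper than coverage error out
  expect_error(attach_environment(dplyr::mutate(sl, lat = 89), uni),
               class = "silicatepump_climatology_gap")
  expect_error(attach_environment(dplyr::mutate(sl, depth_max = 9000), uni),
               class = "silicatepump_climatology_gap")
})

test_that("pH regression recovers structure and rejects degenerate input", {
  comp <- gen_trap_compilation(trap_compilation_config(n_profiles = 60),
                               seed = 8)
  sl <- profile_slopes(filter_profiles(comp)) |>
    dplyr::left_join(comp$stations, by = "station_id")
  fit <- ph_regression(sl)
  expect_lt(fit$slope, 0)  # lower pH, stronger Si preservation
  expect_equal(fit$n, nrow(sl))
  expect_equal(glance(fit)$r2, fit$r2)
  expect_equal(nrow(tidy(fit)), 1)
  expect_error(ph_regression(sl[1:2, ]),
               class = "silicatepump_insufficient_data")
  expect_error(ph_regression(dplyr::mutate(sl, mean_ph = 8)),
               class = "silicatepump_degenerate_predictor")
  # permutation null: p-values approximately uniform
  set.seed(12)
  pvals <- vapply(1:60, function(i) {
    perm <- dplyr::mutate(sl, mean_ph = sample(mean_ph))
    ph_regression(perm)$p_value
  }, numeric(1))
  expect_gt(mean(pvals), 0.3)
  expect_lt(mean(pvals), 0.7)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("pH+temperature regression separates and standardizes both effects", {
  # orthogonal noiseless predictors: exact recovery
  d <- tidyr::expand_grid(mean_ph = seq(7.7, 8.1, 0.1),
                          mean_temp = seq(1, 4, 1)) |>
    dplyr::mutate(delta_sin_per_m = 0.2 - 0.02 * mean_ph + 0.003 * mean_temp)
  fit <- suppressWarnings(ph_temperature_regression(d))
  expect_equal(unname(fit$slope), c(-0.02, 0.003), tolerance = 1e-10)
  # collinearity guard
  coll <- dplyr::mutate(d, mean_temp = 10 * mean_ph)
  expect_error(ph_temperature_regression(coll),
               class = "silicatepump_collinearity")
  # zero temperature effect in the generator: pH coefficient agrees with the
  # single-predictor fit (nested-model consistency)
  comp <- gen_trap_compilation(trap_compilation_config(n_profiles = 120),
                               seed = 9)
  sl <- profile_slopes(filter_profiles(comp)) |>
    dplyr::left_join(comp$stations, by = "station_id")
  f1 <- ph_regression(sl)
  f2 <- ph_temperature_regression(sl)
  se1 <- (f1$ci[1, 2] - f1$ci[1, 1]) / (2 * qnorm(0.975))
  expect_lt(abs(f2$slope[1] - f1$slope[1]), 2 * se1)
  # equal standardized effects are recovered as comparable
  set.seed(13)
  n <- 150
  ph <- runif(n, 7.7, 8.15); tc <- runif(n, 0.5, 4)
  bph <- -0.01; btc <- bph * sd(ph) / sd(tc)  # equal standardized size
  dd <- tibble::tibble(mean_ph = ph, mean_temp = tc,
                       delta_sin_per_m = 0.1 + bph * ph + btc * tc +
                         rnorm(n, 0, 0.0005))
  f3 <- ph_temperature_regression(dd)
  expect_lt(abs(abs(f3$std_estimate[1] / f3$std_estimate[2]) - 1), 0.2)
})

test_that("two-stage recovery: mechanistic pipeline finds pH only when present", {
  cl_template <- trap_compilation_config(mode = "mechanistic", n_profiles = 40,
                                         flux_noise_cv = 0.03)
  kp_ph <- kinetics_params(s_ph = 0.567)
  comp <- gen_trap_compilation(cl_template, seed = 14, params = kp_ph)
  sl <- profile_slopes(filter_profiles(comp)) |>
    dplyr::left_join(comp$stations, by = "station_id")
  expect_lt(ph_regression(sl)$slope, 0)
  kp_null <- kinetics_params(s_ph = 0)
  comp0 <- gen_trap_compilation(cl_template, seed = 14, params = kp_null)
  sl0 <- profile_slopes(filter_profiles(comp0), keep_all = TRUE) |>
    dplyr::left_join(comp0$stations, by = "station_id")
  expect_gt(ph_regression(sl0)$p_value, 0.05)
})
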
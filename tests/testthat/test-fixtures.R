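test_that("packaged tables have the published shape and spot values", {
  sites <- load_site_terrain()
  expect_equal(nrow(sites), 7)
  expect_equal(sites$water_accumulation[sites$site == "Nandiala"], 0.76)
  expect_equal(sites$inundation_score[sites$site == "Sissene"], 0.74)
  # printed exponent strings parse to the numeric columns
  expect_equal(as.numeric(sites$longitudinal_printed),
               sites$longitudinal_convexity)
  # clip-rule invariant holds in the published data too
  expect_true(all(sites$inundation_score[sites$longitudinal_convexity >= 0] == 0))
  expect_true(all(sites$inundation_score >= 0))

  groups <- load_site_terrain_groups()
  expect_equal(groups$inundation_score, c(0.18, 0.73))

  tr <- load_field_trials()
  expect_equal(nrow(tr), 7)
  expect_equal(tr$submergence_days[tr$site == "Poa"], 40)
  expect_equal(tr$cumulative_water_depth[tr$site == "Villy"], 380)
  expect_equal(tr$yield_nktsp[tr$site == "Sissene"], 6.33)
  expect_equal(nrow(load_field_trials_groups()), 3)

  h <- load_soil_horizons()
  expect_equal(nrow(h), 38)
  expect_equal(sum(!is.na(h$sand)), 37)
  expect_equal(nrow(load_soil_horizons(complete_only = TRUE)), 34)
  expect_equal(h$clay[h$site == "Villy" & h$horizon == "Bwg3"], 71.6)
  expect_equal(h$bray2_p[h$site == "Ramongo" & h$horizon == "Apg1"], 9.8)
  tex <- h[!is.na(h$sand), ]
  expect_true(all(abs(tex$sand + tex$silt + tex$clay - 100) <= 1))
})

test_that("packaged tables round-trip through CSV", {
  tr <- load_field_trials()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tr, path, row.names = FALSE)
  expect_equal(read.csv(path), tr)
})

test_that("simulated trials follow the configured linear model exactly at zero noise", {
  cfg <- trial_sim_config(
    n_sites = 3, scores = c(0, 0.5, 1),
    slopes = c(CT = 1.7, NK = 1.7, "NK+PR" = 1.7, "NK+TSP" = 1.7),
    intercepts = c(CT = 0.6, NK = 0.6, "NK+PR" = 0.6, "NK+TSP" = 0.6),
    noise_sd = c(CT = 0, NK = 0, "NK+PR" = 0, "NK+TSP" = 0),
    n_years = 1, seed = 2)
  sim <- simulate_trial(cfg)
  ct <- sim$trials[sim$trials$treatment == "CT", ]
  expect_equal(ct$yield[order(ct$score)], c(0.6, 1.45, 2.3))
  # zero noise makes the downstream regression exact
  f <- suppressWarnings(ols_fit(ct$score, ct$yield))
  expect_equal(f$r2, 1, tolerance = 1e-12)
})

test_that("simulators are deterministic in the seed and leave the RNG alone", {
  a <- simulate_trial(trial_sim_config(seed = 7))
  b <- simulate_trial(trial_sim_config(seed = 7))
  expect_identical(a, b)
  expect_false(identical(a, simulate_trial(trial_sim_config(seed = 8))))

  d1 <- simulate_dem(dem_sim_config(seed = 7))
  d2 <- simulate_dem(dem_sim_config(seed = 7))
  expect_identical(d1$values, d2$values)
  expect_false(identical(d1$values, simulate_dem(dem_sim_config(seed = 8))$values))

  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_dem(dem_sim_config(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("the synthetic channel has the analytic cross-sectional curvature", {
  cfg <- dem_sim_config(rows = 30, cols = 31, cell_size = 5,
                        base_slope = 0.01, profile_curvature = 0,
                        channel_depth = 1, channel_width = 20, noise_sd = 0)
  dem <- simulate_dem(cfg)
  cv <- convexity(dem)
  want <- -8 * 1 / (20^2 * 5^2)   # -8 d / (w^2 L^2)
  expect_equal(cv$cross_sectional$values[2:29, 16], rep(want, 28),
               tolerance = 1e-10)
  # default-config tilted plane without channel has zero curvature inside
  flat <- simulate_dem(dem_sim_config(rows = 30, cols = 31,
                                      profile_curvature = 0,
                                      channel_depth = 0, noise_sd = 0))
  cvf <- convexity(flat)
  expect_equal(max(abs(cvf$longitudinal$values[2:29, 2:30])), 0,
               tolerance = 1e-12)
})

test_that("simulator configs validate their arguments", {
  expect_error(trial_sim_config(n_sites = 2), ">= 3")
  expect_error(trial_sim_config(noise_sd = c(CT = -1, NK = 1, "NK+PR" = 1,
                                             "NK+TSP" = 1)), "non-negative")
  expect_error(trial_sim_config(scores = c(1, 2)), "length")
  expect_error(dem_sim_config(rows = 10), ">= 30")
  expect_error(dem_sim_config(channel_depth = -1), "non-negative")
})

test_that("topsoil texture is the thickness-weighted 0-20 cm average", {
  h <- load_soil_horizons()
  tex <- topsoil_texture(h)
  nass <- tex[tex$site == "Nassoulou", ]
  expect_equal(nass$sand, (77.0 * 6 + 50.8 * 14) / 20, tolerance = 1e-12)
  expect_equal(nass$clay, (11.9 * 6 + 34.9 * 14) / 20, tolerance = 1e-12)
  expect_equal(nrow(tex), 7)
})
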
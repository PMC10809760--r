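test_that("depth-age conversion matches the worked doubling example", {
  expect_equal(round(depth_to_age(1.4, 0.76)), 18)
  expect_equal(round(depth_to_age(1.4, 0.29)), 48)
  expect_equal(depth_to_age(1.4, 0.76), 14 / 0.76, tolerance = 1e-12)
  expect_equal(depth_to_age(0, 0.5), 0)
  expect_error(depth_to_age(1, 0), "omega")
  expect_equal(round(doubling_from_distance(1.4, 0.76)), 18)
  expect_equal(round(doubling_from_distance(1.4, 0.29)), 48)
  expect_equal(doubling_from_distance(2.8, 0.5),
               2 * doubling_from_distance(1.4, 0.5))
  expect_error(doubling_from_distance(0, 0.5), "distance")
})

test_that("noise-free exponential series are recovered exactly", {
  t <- seq(0, 900, by = 100)
  a <- 0.8 * 2^(-t / 250)
  fit <- fit_exponential(t, a, "decay")
  expect_equal(fit$rate_constant, log(2) / 250, tolerance = 1e-9)
  expect_equal(fit$half_life, 250, tolerance = 1e-9)
  expect_equal(fit$half_life, log(2) / fit$rate_constant, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_true(fit$converged)
  # growth branch
  g <- 0.01 * 2^(t / 40)
  fitg <- fit_exponential(t, g, "growth")
  expect_equal(fitg$half_life, 40, tolerance = 1e-9)
  # OLS and NLS agree on noise-free input
  fit_nls <- fit_exponential(t, a, "decay", method = "nls")
  expect_equal(fit_nls$rate_constant, fit$rate_constant, tolerance = 1e-6)
})

test_that("the two-point decline between 6 and 20 cm gives a ~144-year half-life", {
  omega <- 0.76
  ages <- depth_to_age(c(6, 13, 20), omega)
  # closed-form two-point solution from the endpoints
  lam <- log(0.75 / 0.31) / (ages[3] - ages[1])
  expect_equal(log(2) / lam, 144.5, tolerance = 0.01)
  # a midpoint on the same log-line leaves the OLS fit at the two-point answer
  ab <- 0.75 * exp(-lam * (ages - ages[1]))
  fit <- fit_exponential(ages, ab, "decay")
  expect_equal(fit$half_life, log(2) / lam, tolerance = 1e-9)
  expect_lt(abs(fit$half_life - 144.5), 0.1)
})

test_that("OLS on noised series matches a grid-search oracle for lambda", {
  withr::local_seed(20)
  t <- seq(0, 450, by = 50)
  a <- 0.5 * exp(-0.004 * t) * rlnorm(length(t), 0, 0.2)
  fit <- fit_exponential(t, a, "decay")
  lam_oracle <- -oracle_grid_lambda(t, a, lo = -0.1, hi = 0.1)
  expect_equal(fit$rate_constant, lam_oracle, tolerance = 1e-6)
})

test_that("fits are scale invariant and sign mismatches are flagged, not raised", {
  t <- seq(0, 500, by = 100)
  a <- 0.3 * exp(-0.002 * t)
  f1 <- fit_exponential(t, a, "decay")
  f2 <- fit_exponential(t, 17 * a, "decay")
  expect_equal(f1$rate_constant, f2$rate_constant, tolerance = 1e-12)
  expect_equal(f2$intercept, f1$intercept + log(17), tolerance = 1e-9)

  wrong <- fit_exponential(t, a, "growth")
  expect_false(wrong$converged)
  expect_true(is.na(wrong$half_life))
})

test_that("zero abundances are dropped, excess zeros refuse the fit", {
  t <- c(0, 100, 200, 300, 400)
  a <- c(0.4, 0.2, 0, 0.05, 0.025)
  fit <- fit_exponential(t, a, "decay")
  expect_equal(fit$n_zero_dropped, 1L)
  expect_equal(fit$n_points, 4L)
  expect_error(fit_exponential(t, c(0.4, 0, 0, 0, 0.1), "decay"),
               class = "hadalguilds_insufficient_data")
  expect_error(fit_exponential(t[1:3], c(0.4, 0, 0.2), "decay"),
               class = "hadalguilds_insufficient_data")
})

test_that("fitting against depth then converting by omega equals fitting against age", {
  withr::local_seed(4)
  z <- seq(8, 28, by = 2)
  omega <- 0.45
  ages <- depth_to_age(z, omega)
  a <- 0.6 * exp(-0.003 * ages) * rlnorm(length(z), 0, 0.1)
  lam_age <- fit_exponential(ages, a, "decay")$rate_constant
  slope_z <- fit_exponential(z, a, "decay")$rate_constant  # per cm
  expect_equal(slope_z * omega / 10, lam_age, tolerance = 1e-12)
})

test_that("per-site guild kinetics recover planted half-lives exactly at sigma=0", {
  cfg <- sim_config(sigma = 0, half_life_yr = seq(150, 400, length.out = 6))
  sim <- simulate_community(cfg, seed = 3)
  asn <- suppressWarnings(classify_guilds(sim$catalog, sim$gene_table,
                                          sim$metal_flags))
  ga <- aggregate_groups(relative_abundance(sim$coverage),
                         guild_mapping(asn))
  dec <- fit_guild_kinetics(ga, sim$metadata,
                            groups = c("aerobic", "nitrogen"),
                            direction = "decay")
  for (g in c("aerobic", "nitrogen")) {
    f <- dec$fits[dec$fits$group == g, ]
    f <- f[order(f$site_id), ]
    expect_equal(f$half_life, sim$kinetics_truth$half_life_yr,
                 tolerance = 1e-9)
  }
  rng <- dec$range[dec$range$group == "aerobic", ]
  expect_equal(c(rng$half_life_min, rng$half_life_max), c(150, 400),
               tolerance = 1e-9)

  gro <- fit_guild_kinetics(ga, sim$metadata, groups = "fermenter",
                            direction = "growth")
  f <- gro$fits[order(gro$fits$site_id), ]
  expect_equal(f$half_life, sim$kinetics_truth$doubling_time_yr,
               tolerance = 1e-9)
  # doubling every 1.4 cm at the printed rate extremes spans ~18-48 years
  expect_equal(round(min(f$half_life), 1), 18.4)
  expect_equal(round(max(f$half_life), 1), 48.3)
})

test_that("sites without enough horizons in the window are skipped with a warning", {
  cfg <- tiny_sim_config(sigma = 0)
  sim <- simulate_community(cfg, seed = 5)
  asn <- suppressWarnings(classify_guilds(sim$catalog, sim$gene_table,
                                          sim$metal_flags))
  ga <- aggregate_groups(relative_abundance(sim$coverage), guild_mapping(asn))
  meta <- sim$metadata
  # push one site's ferruginous top so deep that <3 horizons remain below it
  meta$no3_penetration_cm[meta$site_id == "H1"] <- 27
  expect_warning(
    res <- fit_guild_kinetics(ga, meta, groups = "aerobic",
                              direction = "decay"),
    "skipped")
  expect_false("H1" %in% res$fits$site_id)
  expect_equal(sort(unique(res$fits$site_id)), sprintf("H%d", 2:6))
})
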
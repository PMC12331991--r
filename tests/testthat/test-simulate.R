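# Synthetic-data generators: determinism, exact noise-free inversion,
# configured-moment recovery, and the cohort forward simulation.

test_that("incubation generator is bit-identical under a fixed seed", {
  a <- simulate_incubations(incubation_sim_config(seed = 5))
  b <- simulate_incubations(incubation_sim_config(seed = 5))
  expect_identical(a, b)
  c <- simulate_incubations(incubation_sim_config(seed = 6))
  expect_false(identical(a$incubations, c$incubations))
})

test_that("noise-free generator inverts exactly through the rates module", {
  sim <- simulate_incubations(noise_free_cfg())
  r <- derive_rates(sim$incubations)
  expect_equal(r$npp, sim$truth$npp_true, tolerance = 1e-10)
  expect_equal(r$doc_ex, sim$truth$doc_ex_true, tolerance = 1e-10)
  # dark mature DOC_ex equals the configured intercept exactly
  # (NPP < 0 in the dark, so the slope term vanishes)
  dark_mat <- r$light_class == "dark" & r$maturity == "mature"
  expect_equal(unique(round(r$doc_ex[dark_mat], 12)), 0.96)
  # forced NPP = 100 through the mature law: doc = 0.015*100 + 0.96
  cfg <- noise_free_cfg()
  expect_equal(cfg$mature_slope * 100 + cfg$mature_intercept, 2.46)
})

test_that("senescent draws match configured moments and ignore light", {
  # ~1000 senescent draws: 14 ages > 50, enough blades to get there
  cfg <- incubation_sim_config(
    n_blades_per_age = 56L, ages_days = c(58, 68, 78), seasons = "summer",
    par_levels = c(0, 150, 1000), seed = 31)
  sim <- simulate_incubations(cfg)
  sen <- sim$truth$maturity_true == "senescent"
  d <- sim$truth$doc_ex_true[sen]
  n <- length(d)
  expect_gte(n, 500)
  se <- cfg$senescent_sd / sqrt(n)
  # within 3 SE of the configured mean (severity weighting preserves it);
  # the SD exceeds the plain lognormal's because severity varies across ages
  expect_lt(abs(mean(d) - cfg$senescent_mean), 3 * se * 2)
  expect_lt(abs(cor(d, sim$truth$par[sen])), 0.1)
  # right-skew: median well below mean
  expect_lt(median(d), mean(d))
})

test_that("mature law and Pmax decline are recovered from the default world", {
  sim <- simulate_incubations(incubation_sim_config(seed = 17))
  r <- derive_rates(sim$incubations)
  m <- r$maturity == "mature"
  # OLS on doc_ex ~ max(npp, 0) recovers the generative slope within 2 SE
  x <- pmax(r$npp[m], 0)
  fit <- lm(r$doc_ex[m] ~ x)
  co <- summary(fit)$coefficients
  expect_lt(abs(co[2, 1] - 0.015), 2 * co[2, 2])
  expect_lt(abs(co[1, 1] - 0.96), 2 * co[1, 2])
  # per-season Pmax-age OLS slope near the configured decline
  pm <- pmax_by_age(r)
  expect_lt(abs(pm$fits$spring$slope - (-1.6)), 0.5)
  expect_lt(abs(pm$fits$summer$slope - (-2.8)), 0.5)
})

test_that("generator rejects invalid configurations", {
  expect_error(incubation_sim_config(n_blades_per_age = 0), ">= 1")
  expect_error(incubation_sim_config(par_levels = c(-5, 100)), ">= 0")
  expect_error(incubation_sim_config(senescent_mean = -1), "positive")
  expect_error(incubation_sim_config(noise_sd = list(dic = -1, doc = 0, doc_bio = 0, pmax = 0)),
               ">= 0")
})

test_that("forward cohort simulation matches hand bookkeeping", {
  # constant growth 1 kg/day for 120 days
  mass <- kelpDOC:::forward_cohorts(rep(1, 120), 120L)
  expect_equal(sum(mass[120, ]), 120)
  expect_equal(as.numeric(mass[120, ]), rep(1, 120))
  # senescent fraction at day 120: ages 51..120 hold 70 of 120 kg
  expect_equal(sum(mass[120, 51:120]) / sum(mass[120, ]), 70 / 120)
  # death at lifespan: day 121 of the same world loses the oldest kg
  mass2 <- kelpDOC:::forward_cohorts(rep(1, 121), 120L)
  expect_equal(sum(mass2[121, ]), 120)
  # mass conservation: total = births in the trailing lifespan window
  births <- c(5, 0, 0, 2, 0, 1)
  m3 <- kelpDOC:::forward_cohorts(births, 4L)
  expect_equal(rowSums(m3), c(5, 5, 5, 7, 2, 3))
})

test_that("canopy generator: determinism, zero growth, truth consistency", {
  a <- simulate_canopy(small_canopy_cfg())
  b <- simulate_canopy(small_canopy_cfg())
  expect_identical(a, b)

  z <- simulate_canopy(small_canopy_cfg(peak_biomass_kg = 0))
  expect_true(all(z$observations$wet_kg == 0))
  expect_true(all(z$truth_region$total_kg == 0))

  # ledger mass conservation in the truth: total = sum of cohort masses
  led <- simulate_canopy(small_canopy_cfg(n_pixels = 1L), keep_ledger = TRUE)
  expect_equal(rowSums(led$ledgers[[1]]), led$truth_daily$total_kg)
  # senescent fraction consistent with the ledger split
  old <- seq_len(120) > 50
  expect_equal(rowSums(led$ledgers[[1]][, old]), led$truth_daily$senescent_kg)

  # observations are a subsample of the truth (noise-free config)
  key <- paste(a$observations$pixel_id, a$observations$date)
  tkey <- paste(a$truth_daily$pixel_id, a$truth_daily$date)
  expect_equal(a$observations$wet_kg, a$truth_daily$total_kg[match(key, tkey)])

  expect_error(canopy_sim_config(obs_per_year = 0), "> 0")
  expect_error(canopy_sim_config(lifespan_days = 40, senescence_age_days = 50),
               "lifespan_days")
})
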
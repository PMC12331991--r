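# Interpolation chain, cohort ledger bookkeeping, monthly age structure,
# and wet-to-dry conversion.

test_that("interpolate_monthly reproduces constant and linear series", {
  dates <- as.Date("2001-01-01") + seq(0, 364, by = 16)
  con <- interpolate_monthly(dates, rep(500, length(dates)))
  expect_true(all(con$wet_kg == 500))
  expect_equal(format(con$date[1], "%d"), "01")

  # linear ramp: piecewise cubics reproduce linear data exactly
  lin <- interpolate_monthly(dates, as.numeric(dates - dates[1]))
  expect_equal(lin$wet_kg, as.numeric(lin$date - dates[1]), tolerance = 1e-9)

  # no extrapolation: all months inside the observation span
  expect_true(all(lin$date >= min(dates) & lin$date <= max(dates)))
  expect_warning(one <- interpolate_monthly(dates[5], 100), "single observation")
  expect_error(interpolate_monthly(rep(dates[1], 2), c(1, 2)), "duplicate")
  expect_error(interpolate_monthly(dates[1:2], c(-1, 2)), ">= 0")
})

test_that("resample_daily telescopes and is flat on constant input", {
  monthly <- data.frame(date = seq(as.Date("2001-01-01"), by = "month", length.out = 6),
                        wet_kg = c(100, 100, 130, 160, 120, 100))
  daily <- resample_daily(monthly)
  expect_equal(sum(daily$delta_kg[-1]), daily$wet_kg[nrow(daily)] - daily$wet_kg[1])
  expect_equal(daily$wet_kg[1], 100)
  expect_equal(daily$delta_kg[1], 100)  # series start counts as appearance

  flat <- resample_daily(data.frame(date = monthly$date, wet_kg = 200))
  expect_true(all(abs(flat$delta_kg[-1]) < 1e-9))

  # one month (31 days) of +30 kg linear increase: 30/31 kg/day
  two <- resample_daily(data.frame(
    date = as.Date(c("2001-03-01", "2001-04-01")), wet_kg = c(0, 30)))
  expect_equal(mean(two$delta_kg[-1]), 30 / 31, tolerance = 1e-9)
})

test_that("track_cohorts matches hand simulations", {
  mk_daily <- function(deltas) data.frame(
    date = as.Date("2001-01-01") + seq_along(deltas) - 1, delta_kg = deltas)

  # 10 kg appears day 1, constant after: day 55 -> one cohort of age 55
  led <- track_cohorts(mk_daily(c(10, rep(0, 54))))
  expect_equal(led$mass[55, 55], 10)
  expect_equal(sum(led$mass[55, ]), 10)
  sf <- senescent_fraction(led)
  expect_equal(sf$fraction[55], 1)
  expect_equal(sf$fraction[50], 0)

  # +10 on day 40: day 55 has ages 55 (10 kg) and 16 (10 kg) -> fraction 0.5
  led2 <- track_cohorts(mk_daily(c(10, rep(0, 38), 10, rep(0, 15))))
  expect_equal(led2$mass[55, 55], 10)
  expect_equal(led2$mass[55, 16], 10)
  expect_equal(senescent_fraction(led2)$fraction[55], 0.5)

  # then -5 on day 56: oldest-first -> oldest cohort cut to 5; fraction 5/15
  led3 <- track_cohorts(mk_daily(c(10, rep(0, 38), 10, rep(0, 15), -5)))
  expect_equal(led3$mass[56, 56], 5)
  expect_equal(led3$mass[56, 17], 10)
  expect_equal(senescent_fraction(led3)$fraction[56], 5 / 15)

  # proportional loss attribution as the alternative
  led4 <- track_cohorts(mk_daily(c(10, rep(0, 38), 10, rep(0, 15), -5)),
                        loss = "proportional")
  expect_equal(led4$mass[56, 56], 10 * (1 - 5 / 20))
  expect_equal(led4$mass[56, 17], 10 * (1 - 5 / 20))

  # decrease exceeding the ledger floors at zero with a warning
  expect_warning(led5 <- track_cohorts(mk_daily(c(10, -20))), "floored")
  expect_equal(sum(led5$mass[2, ]), 0)
})

test_that("ledger daily mass budget identity holds", {
  set.seed(9)
  deltas <- round(rnorm(400, 0.2, 3), 2)
  daily <- data.frame(date = as.Date("2001-01-01") + 0:399, delta_kg = deltas)
  led <- suppressWarnings(track_cohorts(daily, lifespan_days = 120L))
  tot <- rowSums(led$mass)
  for (t in 2:400) {
    dropped <- led$mass[t - 1, 120]
    resid <- deltas[t] + dropped
    expected <- if (resid >= 0) tot[t - 1] - dropped + resid
                else max(tot[t - 1] - dropped + resid, 0)
    expect_equal(tot[t], expected, tolerance = 1e-9)
  }
  expect_true(all(led$mass >= 0))
})

test_that("monthly_age_structure splits observed biomass consistently", {
  # single cohort aging: all mature early, all senescent late
  daily <- data.frame(date = seq(as.Date("2001-01-01"), by = "day", length.out = 100),
                      delta_kg = c(30, rep(0, 99)))
  led <- track_cohorts(daily)
  obs <- data.frame(date = as.Date(c("2001-01-01", "2001-03-01")), wet_kg = c(30, 30))
  ms <- monthly_age_structure(led, obs)
  expect_equal(ms$senescent_fraction, c(0, 1))
  expect_equal(ms$mature_biomass_kg + ms$senescent_biomass_kg,
               ms$total_biomass_kg)
  expect_true(all(ms$senescent_fraction >= 0 & ms$senescent_fraction <= 1))

  # empty ledger with positive observed biomass -> flagged, fraction 0
  led0 <- track_cohorts(data.frame(date = daily$date, delta_kg = rep(0, 100)))
  ms0 <- monthly_age_structure(led0, obs)
  expect_true(all(ms0$flagged))
  expect_equal(ms0$senescent_fraction, c(0, 0))
})

test_that("wet_to_dry conversion", {
  expect_equal(wet_to_dry(1), 120)
  expect_equal(wet_to_dry(0), 0)
  expect_equal(wet_to_dry(2, ratio = 1), 2000)
  expect_error(wet_to_dry(1, ratio = 0), "ratio")
  expect_error(wet_to_dry(1, ratio = 1.5), "ratio")
  expect_error(wet_to_dry(-1), ">= 0")
})

test_that("tracker recovers truth age structure on simulated canopies", {
  can <- simulate_canopy(small_canopy_cfg(n_pixels = 2L))
  as <- regional_age_structure(can$observations)
  tr <- can$truth_region
  i <- match(as$region$date + 14, tr$date)
  ok <- !is.na(i) & tr$total_kg[i] > 0.01 * max(tr$total_kg)
  rmse <- sqrt(mean((as$region$senescent_fraction[ok] - tr$fraction[i[ok]])^2))
  expect_lte(rmse, 0.1)
  # regional split is exact against its own monthly biomass
  expect_equal(as$region$mature_biomass_kg + as$region$senescent_biomass_kg,
               as$region$total_biomass_kg)
})
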
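# Synthetic canopy biomass generator. Forward-simulates daily cohort birth
# (seasonal growth), aging, and loss at the 120-day lifespan per pixel, then
# subsamples the true total biomass at a thinned 16-day satellite revisit
# with optional multiplicative observation noise. Both the sparse
# observations and the dense truth (including the true senescent fraction)
# are returned so the cohort tracker can be validated against ground truth.

#' Configuration for the canopy simulator
#'
#' Defaults describe a small stand of Landsat-scale (30 m) pixels over a few
#' years: growth peaks in late spring so biomass peaks in late summer
#' (`seasonal_phase` = month 8), ~2 t wet canopy per pixel at peak, a 120-day
#' frond lifespan with senescence past 50 days, and ~23 cloud-free views per
#' pixel per year (a 16-day revisit with Bernoulli cloud dropout).
#'
#' @param n_pixels number of pixels.
#' @param years number of simulated years.
#' @param start_year first calendar year (simulation starts Jan 1, when
#'   canopy is near its seasonal minimum).
#' @param peak_biomass_kg target peak wet biomass per pixel (kg).
#' @param seasonal_phase month (1-12) of the biomass peak.
#' @param interannual_cv coefficient of variation of the lognormal
#'   year-to-year growth amplitude.
#' @param pixel_cv coefficient of variation of the lognormal between-pixel
#'   scale factor.
#' @param obs_per_year mean cloud-free observations per pixel per year
#'   (capped by the 16-day revisit at ~22.8).
#' @param lifespan_days fixed cohort lifespan (days).
#' @param senescence_age_days senescence onset age (days).
#' @param obs_noise_cv multiplicative observation noise CV (0 = noise-free).
#' @param seed RNG seed; fixes all outputs.
#' @return list of class `"canopy_sim_config"`.
#' @export
canopy_sim_config <- function(n_pixels = 9L, years = 3L, start_year = 2001L,
                              peak_biomass_kg = 2000, seasonal_phase = 8L,
                              interannual_cv = 0.3, pixel_cv = 0.3,
                              obs_per_year = 23.3, lifespan_days = 120L,
                              senescence_age_days = 50L, obs_noise_cv = 0.05,
                              seed = 1L) {
  cfg <- list(n_pixels = as.integer(n_pixels), years = as.integer(years),
              start_year = as.integer(start_year),
              peak_biomass_kg = peak_biomass_kg,
              seasonal_phase = as.integer(seasonal_phase),
              interannual_cv = interannual_cv, pixel_cv = pixel_cv,
              obs_per_year = obs_per_year,
              lifespan_days = as.integer(lifespan_days),
              senescence_age_days = as.integer(senescence_age_days),
              obs_noise_cv = obs_noise_cv, seed = seed)
  if (cfg$n_pixels < 1L || cfg$years < 1L) stop("n_pixels and years must be >= 1")
  if (cfg$obs_per_year <= 0) stop("obs_per_year must be > 0")
  if (!(cfg$lifespan_days > cfg$senescence_age_days &&
        cfg$senescence_age_days > 0L))
    stop("need lifespan_days > senescence_age_days > 0")
  if (cfg$peak_biomass_kg < 0) stop("peak_biomass_kg must be >= 0")
  structure(cfg, class = "canopy_sim_config")
}

# Daily cohort forward simulation: births[t] kg enters at age 1 on day t,
# ages one day per day, and is lost past lifespan_days. Returns the
# days x lifespan mass matrix (column j = biomass aged j days).
forward_cohorts <- function(births, lifespan_days = 120L) {
  nd <- length(births)
  L <- as.integer(lifespan_days)
  mass <- matrix(0, nrow = nd, ncol = L)
  ledger <- numeric(L)
  for (t in seq_len(nd)) {
    if (t > 1L) ledger <- c(0, ledger[-L])
    ledger[1L] <- ledger[1L] + births[t]
    mass[t, ] <- ledger
  }
  mass
}

# von-Mises-shaped positive seasonal growth curve over day-of-year,
# peaking `lag_days` before the biomass peak month.
growth_shape <- function(doy, peak_month, kappa = 3, lag_days = 75) {
  peak_doy <- (peak_month - 0.5) * 365.25 / 12 - lag_days
  exp(kappa * cos(2 * pi * (doy - peak_doy) / 365.25)) / exp(kappa)
}

#' Simulate pixel canopy biomass time series with ground truth
#'
#' Per pixel: a seasonal daily growth curve (lognormal year and pixel scale
#' factors, amplitude calibrated so the trailing-lifespan biomass integral
#' peaks near `peak_biomass_kg`) feeds the daily cohort simulation; the true
#' total biomass is then observed on a 16-day revisit grid thinned by
#' Bernoulli cloud dropout tuned to `obs_per_year`, with optional
#' multiplicative noise.
#'
#' @param cfg a [canopy_sim_config()].
#' @param keep_ledger return the full truth mass matrix for each pixel
#'   (memory-heavy; default FALSE).
#' @return list with `observations` (pixel_id, date, wet_kg),
#'   `truth_daily` (pixel_id, date, total_kg, senescent_kg, fraction),
#'   `truth_region` (date, total_kg, senescent_kg, fraction summed over
#'   pixels), `ledgers` (list per pixel if `keep_ledger`), and `config`.
#' @export
simulate_canopy <- function(cfg = canopy_sim_config(), keep_ledger = FALSE) {
  stopifnot(inherits(cfg, "canopy_sim_config"))
  local_seed(cfg$seed, simulate_canopy_impl(cfg, keep_ledger))
}

simulate_canopy_impl <- function(cfg, keep_ledger) {
  start <- as.Date(sprintf("%04d-01-01", cfg$start_year))
  end <- as.Date(sprintf("%04d-12-31", cfg$start_year + cfg$years - 1L))
  dates <- seq(start, end, by = "day")
  nd <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  yr_idx <- as.integer(format(dates, "%Y")) - cfg$start_year + 1L
  shape <- growth_shape(doy, cfg$seasonal_phase)

  # calibrate unit amplitude: peak of the trailing-lifespan sum of the shape
  unit_peak <- max(vapply(seq_len(nd), function(t) {
    lo <- max(1L, t - cfg$lifespan_days + 1L)
    sum(shape[lo:t])
  }, numeric(1)))

  sdlog_y <- sqrt(log(1 + cfg$interannual_cv^2))
  sdlog_p <- sqrt(log(1 + cfg$pixel_cv^2))
  year_fac <- stats::rlnorm(cfg$years, -sdlog_y^2 / 2, sdlog_y)
  pixel_fac <- stats::rlnorm(cfg$n_pixels, -sdlog_p^2 / 2, sdlog_p)

  # observation calendar: 16-day revisit per pixel with random phase,
  # Bernoulli keep probability tuned to obs_per_year
  p_keep <- min(1, cfg$obs_per_year / (365.25 / 16))

  obs_list <- vector("list", cfg$n_pixels)
  truth_list <- vector("list", cfg$n_pixels)
  ledgers <- if (keep_ledger) vector("list", cfg$n_pixels) else NULL
  old <- seq_len(cfg$lifespan_days) > cfg$senescence_age_days

  for (px in seq_len(cfg$n_pixels)) {
    amp <- cfg$peak_biomass_kg * pixel_fac[px] / unit_peak
    births <- amp * shape * year_fac[yr_idx]
    mass <- forward_cohorts(births, cfg$lifespan_days)
    total <- rowSums(mass)
    senes <- rowSums(mass[, old, drop = FALSE])
    pid <- sprintf("px%03d", px)
    truth_list[[px]] <- data.frame(
      pixel_id = pid, date = dates, total_kg = total, senescent_kg = senes,
      fraction = ifelse(total > 0, senes / total, 0),
      stringsAsFactors = FALSE)
    if (keep_ledger) ledgers[[px]] <- mass

    grid <- seq(sample.int(16L, 1L), nd, by = 16L)
    grid <- grid[stats::runif(length(grid)) < p_keep]
    if (length(grid) == 0L) grid <- sample.int(nd, 1L)
    wet <- total[grid]
    if (cfg$obs_noise_cv > 0)
      wet <- pmax(wet * (1 + stats::rnorm(length(grid), 0, cfg$obs_noise_cv)), 0)
    obs_list[[px]] <- data.frame(pixel_id = pid, date = dates[grid],
                                 wet_kg = wet, stringsAsFactors = FALSE)
  }

  truth_daily <- do.call(rbind, truth_list)
  region_total <- rowsum(truth_daily$total_kg, format(truth_daily$date))
  region_sen <- rowsum(truth_daily$senescent_kg, format(truth_daily$date))
  truth_region <- data.frame(
    date = as.Date(rownames(region_total)),
    total_kg = as.numeric(region_total), senescent_kg = as.numeric(region_sen),
    fraction = ifelse(region_total > 0, region_sen / region_total, 0)[, 1])
  rownames(truth_region) <- NULL

  list(observations = do.call(rbind, obs_list), truth_daily = truth_daily,
       truth_region = truth_region, ledgers = ledgers, config = cfg)
}
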
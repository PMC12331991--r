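# Age structure of satellite-derived kelp canopy biomass. Sparse per-pixel
# observations are interpolated to a monthly grid, resampled to daily
# resolution, and daily biomass increases are tracked as cohorts aging from
# 1 to 120 days (complete senescence and loss). Biomass older than 50 days
# is senescent. The ledger yields the monthly senescent fraction that the
# upscaling module combines with incubation-derived rates.

#' Interpolate sparse biomass observations to month boundaries
#'
#' Modified-Akima interpolation of an irregular biomass series onto the
#' first day of each calendar month inside the observation span. Values are
#' clamped at zero (canopy biomass cannot be negative) and the series is
#' never extrapolated beyond the first/last observation.
#'
#' @param dates observation dates (`Date` or coercible).
#' @param wet_kg canopy wet biomass (kg) per date, >= 0.
#' @return data.frame with `date` (first-of-month) and `wet_kg`.
#' @export
interpolate_monthly <- function(dates, wet_kg) {
  dates <- as.Date(dates)
  o <- order(dates)
  dates <- dates[o]; wet_kg <- wet_kg[o]
  if (anyDuplicated(dates)) stop("duplicate observation dates")
  if (any(wet_kg < 0)) stop("biomass must be >= 0")
  first <- dates[1L]; last <- dates[length(dates)]
  months <- seq(as.Date(format(first, "%Y-%m-01")), last, by = "month")
  months <- months[months >= first & months <= last]
  if (length(dates) == 1L) {
    warning("single observation: returning a constant series")
    return(data.frame(date = months, wet_kg = rep(wet_kg, length(months))))
  }
  vals <- makima(as.numeric(dates), wet_kg, as.numeric(months))
  data.frame(date = months, wet_kg = pmax(vals, 0))
}

#' Resample a monthly biomass series to daily resolution
#'
#' Interpolates (same modified-Akima family) onto every calendar day of the
#' monthly span and computes the day-to-day biomass difference used for
#' cohort tracking.
#'
#' @param monthly data.frame from [interpolate_monthly()] (columns `date`,
#'   `wet_kg`).
#' @return data.frame with `date`, `wet_kg` (clamped >= 0), `delta_kg`
#'   (first difference; the first day's delta is its biomass, i.e. series
#'   start counts as appearance).
#' @export
resample_daily <- function(monthly) {
  stopifnot(all(c("date", "wet_kg") %in% names(monthly)))
  d <- as.Date(monthly$date)
  if (nrow(monthly) == 1L) {
    return(data.frame(date = d, wet_kg = monthly$wet_kg, delta_kg = monthly$wet_kg))
  }
  days <- seq(d[1L], d[length(d)], by = "day")
  vals <- pmax(makima(as.numeric(d), monthly$wet_kg, as.numeric(days)), 0)
  data.frame(date = days, wet_kg = vals, delta_kg = c(vals[1L], diff(vals)))
}

#' Track daily biomass cohorts to 120 days
#'
#' The cohort ledger: each day, existing cohorts age by one day; biomass
#' reaching an age beyond `lifespan_days` is dropped (fully senesced and
#' lost). The observed daily biomass difference is then reconciled net of
#' that drop — the lifespan loss is already part of the observed decline, so
#' only the residual is attributed: a positive residual enters as a new
#' cohort of age 1; a negative residual removes mass from the oldest cohorts
#' first (senescence and wave loss preferentially strip old canopy;
#' proportional removal available via `loss = "proportional"`). Biomass
#' present on the first day is seeded as a single age-1 cohort (cold start).
#'
#' @param daily data.frame from [resample_daily()] (columns `date`,
#'   `delta_kg`).
#' @param lifespan_days maximum cohort age (days); biomass is lost beyond it.
#' @param loss `"oldest_first"` (default) or `"proportional"` attribution of
#'   biomass decreases across cohorts.
#' @return object of class `"cohort_ledger"`: list with `date`, `mass`
#'   (days x lifespan matrix; column j = biomass of age j days), and
#'   `conservation_warnings` (count of days a decrease exceeded the ledger,
#'   which floors at zero).
#' @export
track_cohorts <- function(daily, lifespan_days = 120L,
                          loss = c("oldest_first", "proportional")) {
  loss <- match.arg(loss)
  stopifnot(all(c("date", "delta_kg") %in% names(daily)))
  nd <- nrow(daily)
  L <- as.integer(lifespan_days)
  mass <- matrix(0, nrow = nd, ncol = L)
  ledger <- numeric(L)  # index = age in days
  warn_days <- 0L
  for (t in seq_len(nd)) {
    dropped <- 0
    if (t > 1L) {
      dropped <- ledger[L]  # biomass crossing the lifespan is lost
      ledger <- c(0, ledger[-L])  # age everything by one day
    }
    # the lifespan drop is itself part of the observed biomass decrease, so
    # reconcile the daily difference net of it: what remains is new growth
    # (positive) or additional loss (negative)
    dlt <- daily$delta_kg[t] + dropped
    if (dlt > 0) {
      ledger[1L] <- ledger[1L] + dlt
    } else if (dlt < 0) {
      need <- -dlt
      tot <- sum(ledger)
      if (need >= tot) {
        if (need > tot + 1e-9) warn_days <- warn_days + 1L
        ledger[] <- 0
      } else if (loss == "proportional") {
        ledger <- ledger * (1 - need / tot)
      } else {
        for (a in L:1) {
          if (need <= 0) break
          take <- min(ledger[a], need)
          ledger[a] <- ledger[a] - take
          need <- need - take
        }
      }
    }
    mass[t, ] <- ledger
  }
  if (warn_days > 0L)
    warning(warn_days, " day(s) with biomass decrease exceeding the ledger; floored at zero")
  structure(list(date = as.Date(daily$date), mass = mass,
                 conservation_warnings = warn_days),
            class = "cohort_ledger")
}

#' @export
print.cohort_ledger <- function(x, ...) {
  cat(sprintf("Cohort ledger: %d days (%s to %s), max age %d d, final total %.1f kg\n",
              length(x$date), min(x$date), max(x$date), ncol(x$mass),
              sum(x$mass[nrow(x$mass), ])))
  invisible(x)
}

#' Senescent biomass fraction of a ledger
#'
#' @param ledger a [track_cohorts()] result.
#' @param senescence_age age (days) beyond which biomass is senescent.
#' @return data.frame with `date`, `total_kg`, `senescent_kg`, `fraction`
#'   (0 when the ledger is empty).
#' @export
senescent_fraction <- function(ledger, senescence_age = 50L) {
  old <- seq_len(ncol(ledger$mass)) > senescence_age
  tot <- rowSums(ledger$mass)
  sen <- rowSums(ledger$mass[, old, drop = FALSE])
  data.frame(date = ledger$date, total_kg = tot, senescent_kg = sen,
             fraction = ifelse(tot > 0, sen / tot, 0))
}

#' Monthly age structure of canopy biomass
#'
#' Evaluates the cohort ledger at each month's midpoint to obtain the
#' senescent biomass fraction, then applies it to the observed monthly
#' biomass so that mature + senescent = observed exactly.
#'
#' @param ledger a [track_cohorts()] result.
#' @param observed_monthly data.frame (`date` first-of-month, `wet_kg`).
#' @param senescence_age senescence onset age (days).
#' @return data.frame with `date`, `total_biomass_kg`, `senescent_fraction`,
#'   `mature_biomass_kg`, `senescent_biomass_kg`, `flagged` (TRUE where the
#'   ledger was empty but observed biomass positive; fraction set to 0).
#' @export
monthly_age_structure <- function(ledger, observed_monthly, senescence_age = 50L) {
  stopifnot(all(c("date", "wet_kg") %in% names(observed_monthly)))
  frac <- senescent_fraction(ledger, senescence_age)
  mdate <- as.Date(observed_monthly$date)
  mid <- mdate + 14L  # mid-month representative day
  i <- match(mid, frac$date)
  # months whose midpoint falls outside the ledger span: use nearest covered day
  i[is.na(i)] <- pmin(pmax(
    findInterval(as.numeric(mid[is.na(i)]), as.numeric(frac$date)), 1L),
    nrow(frac))
  f <- frac$fraction[i]
  empty <- frac$total_kg[i] <= 0 & observed_monthly$wet_kg > 0
  f[empty] <- 0
  data.frame(
    date = mdate,
    total_biomass_kg = observed_monthly$wet_kg,
    senescent_fraction = f,
    mature_biomass_kg = (1 - f) * observed_monthly$wet_kg,
    senescent_biomass_kg = f * observed_monthly$wet_kg,
    flagged = empty
  )
}

#' Convert wet canopy biomass to dry mass
#'
#' @param wet_kg wet biomass (kg), >= 0.
#' @param ratio dry:wet mass ratio in (0, 1]; 0.12 is the incubation-derived
#'   average for giant kelp canopy tissue.
#' @return dry mass in grams.
#' @export
wet_to_dry <- function(wet_kg, ratio = 0.12) {
  if (!is.finite(ratio) || ratio <= 0 || ratio > 1) stop("ratio must be in (0, 1]")
  if (any(wet_kg < 0)) stop("wet_kg must be >= 0")
  wet_kg * 1000 * ratio
}

#' Per-pixel cohort tracking and regional monthly age structure
#'
#' Runs the full tracker chain for every pixel of a long-format observation
#' table (interpolate to month boundaries, resample daily, track cohorts,
#' evaluate the ledger at month midpoints) and sums mature/senescent biomass
#' over pixels per month.
#'
#' @param observations data.frame with `pixel_id`, `date`, `wet_kg`.
#' @param lifespan_days,senescence_age cohort lifespan and senescence onset
#'   (days).
#' @param loss loss attribution rule passed to [track_cohorts()].
#' @return list with `pixels` (per-pixel [monthly_age_structure()] rows) and
#'   `region` (per month: summed biomass and the implied regional fraction).
#' @export
regional_age_structure <- function(observations, lifespan_days = 120L,
                                   senescence_age = 50L,
                                   loss = "oldest_first") {
  stopifnot(all(c("pixel_id", "date", "wet_kg") %in% names(observations)))
  parts <- lapply(split(observations, observations$pixel_id), function(obs) {
    if (nrow(obs) < 2L) return(NULL)
    monthly <- interpolate_monthly(obs$date, obs$wet_kg)
    if (nrow(monthly) < 2L) return(NULL)
    daily <- resample_daily(monthly)
    ledger <- suppressWarnings(track_cohorts(daily, lifespan_days, loss))
    out <- monthly_age_structure(ledger, monthly, senescence_age)
    out$pixel_id <- obs$pixel_id[1L]
    out
  })
  pixels <- do.call(rbind, parts)
  if (is.null(pixels) || nrow(pixels) == 0L)
    stop("no pixel had enough observations to track")
  tot <- rowsum(pixels$total_biomass_kg, format(pixels$date))
  sen <- rowsum(pixels$senescent_biomass_kg, format(pixels$date))
  region <- data.frame(
    date = as.Date(rownames(tot)),
    total_biomass_kg = as.numeric(tot),
    senescent_biomass_kg = as.numeric(sen))
  region$mature_biomass_kg <- region$total_biomass_kg - region$senescent_biomass_kg
  region$senescent_fraction <- ifelse(region$total_biomass_kg > 0,
                                      region$senescent_biomass_kg / region$total_biomass_kg, 0)
  rownames(region) <- NULL
  region <- region[order(region$date), ]
  list(pixels = pixels, region = region)
}
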
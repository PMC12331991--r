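# Physiological-state metrics and their age trends: Chl:C, molar C:N,
# normalized chlorophyll, the sigmoidal Chl:C decline with age, and the
# linear decline of maximum photosynthetic rate with age.

#' Chlorophyll a to carbon mass ratio
#'
#' @param chla_mg chlorophyll a mass (mg), >= 0.
#' @param carbon_mg tissue carbon dry mass (mg), > 0.
#' @return dimensionless mass ratio (vectorized).
#' @export
chl_to_c <- function(chla_mg, carbon_mg) {
  if (any(!is.finite(carbon_mg)) || any(carbon_mg <= 0))
    stop("carbon_mg must be finite and > 0")
  chla_mg / carbon_mg
}

#' Molar carbon to nitrogen ratio
#'
#' C:N on a mol:mol basis using atomic masses 12.011 (C) and 14.007 (N).
#'
#' @param carbon_mg,nitrogen_mg elemental masses (mg); nitrogen > 0.
#' @return C:N (mol:mol, vectorized).
#' @export
molar_cn <- function(carbon_mg, nitrogen_mg) {
  if (any(!is.finite(nitrogen_mg)) || any(nitrogen_mg <= 0))
    stop("nitrogen_mg must be finite and > 0")
  (carbon_mg / 12.011) / (nitrogen_mg / 14.007)
}

#' Chlorophyll normalized to the seasonal maximum
#'
#' Blade chlorophyll a expressed as a fraction of the maximum observed in the
#' blade's seasonal cohort; the physiological-decline covariate for senescent
#' DOC exudation.
#'
#' @param chla_mg chlorophyll a masses (mg).
#' @param season season labels, same length.
#' @return fraction in (0, 1] (vectorized; 1 for the seasonal maximum).
#' @export
chl_norm <- function(chla_mg, season) {
  if (length(chla_mg) != length(season)) stop("chla_mg and season lengths differ")
  out <- rep(NA_real_, length(chla_mg))
  for (s in unique(season)) {
    sel <- season == s
    mx <- max(chla_mg[sel], na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0)
      stop("chl_norm: seasonal cohort '", s, "' has no positive chlorophyll")
    out[sel] <- chla_mg[sel] / mx
  }
  out
}

#' Fit a decreasing logistic to Chl:C vs age
#'
#' Objective replacement for a by-eye sigmoid through the age-related decline
#' of Chl:C: `chlc(age) = floor + (top - floor) / (1 + exp(k * (age - mid)))`
#' with `k > 0`. The floor defaults to the mean Chl:C of the oldest age group
#' (the convention for these curves) and the curve is constrained to have
#' essentially reached the floor by `max_age` (within 1% of the fitted range;
#' enforced by penalty and checked post-fit). Display/diagnostic only.
#'
#' @param age_days,chlc paired observations; >= 4 distinct ages.
#' @param max_age age (days) by which the curve must reach the floor.
#' @param floor minimum Chl:C; default mean of the oldest-age group.
#' @return list with `top`, `floor`, `mid`, `steepness`, `fitted` (function
#'   of age), `converged`, `constraint_ok`, `degenerate`, `sse`.
#' @export
fit_chlc_sigmoid <- function(age_days, chlc, max_age = 100, floor = NULL) {
  keep <- is.finite(age_days) & is.finite(chlc)
  age_days <- age_days[keep]; chlc <- chlc[keep]
  if (length(unique(age_days)) < 4L)
    stop("fit_chlc_sigmoid requires >= 4 distinct ages")
  if (is.null(floor)) {
    oldest <- max(age_days)
    floor <- mean(chlc[age_days == oldest])
  }
  rng <- diff(range(chlc))
  if (rng == 0) {
    return(list(top = chlc[1L], floor = floor, mid = NA_real_,
                steepness = NA_real_, fitted = function(a) rep(chlc[1L], length(a)),
                converged = FALSE, constraint_ok = FALSE, degenerate = TRUE,
                sse = 0))
  }
  model <- function(p, a) floor + (p[1L] - floor) / (1 + exp(p[3L] * (a - p[2L])))
  obj <- function(p) {
    if (p[3L] <= 0) return(1e12)
    resid <- chlc - model(p, age_days)
    pen <- max(0, model(p, max_age) - (floor + 0.01 * (p[1L] - floor)))
    sum(resid^2) + 1e4 * pen^2
  }
  p0 <- c(top = max(chlc), mid = stats::median(age_days), k = 0.2)
  fit <- stats::optim(p0, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
  p <- fit$par
  at_max <- model(p, max_age)
  list(top = unname(p[1L]), floor = floor, mid = unname(p[2L]),
       steepness = unname(p[3L]),
       fitted = function(a) model(p, a),
       converged = fit$convergence == 0,
       constraint_ok = at_max <= floor + 0.011 * (p[1L] - floor),
       degenerate = FALSE,
       sse = sum((chlc - model(p, age_days))^2))
}

#' Maximum photosynthetic rate per blade and its decline with age
#'
#' Pmax for a blade is estimated as the mean NPP over that blade's
#' saturating-light incubations (or the maximum over all light levels with
#' `estimator = "max"`); an OLS regression of Pmax on age is then fitted per
#' season.
#'
#' @param records rate table from [derive_rates()].
#' @param estimator `"mean_saturating"` (default) or `"max"`.
#' @return list with `pmax` (data.frame: blade_id, season, age_days, pmax)
#'   and `fits` (named list per season of [ols_regression()] results).
#'   Blades lacking a saturating-light measurement are dropped with a warning
#'   under the default estimator.
#' @export
pmax_by_age <- function(records, estimator = c("mean_saturating", "max")) {
  estimator <- match.arg(estimator)
  sub <- if (estimator == "mean_saturating")
    records[records$light_class == "saturating", , drop = FALSE]
  else records
  dropped <- setdiff(unique(records$blade_id), unique(sub$blade_id))
  if (length(dropped))
    warning(length(dropped), " blade(s) without a saturating-light incubation dropped")
  if (nrow(sub) == 0L) stop("no usable incubations for Pmax estimation")
  agg_fun <- if (estimator == "max") max else mean
  key <- unique(sub[c("blade_id", "season", "age_days")])
  key$pmax <- vapply(seq_len(nrow(key)), function(i) {
    agg_fun(sub$npp[sub$blade_id == key$blade_id[i]])
  }, numeric(1))
  fits <- lapply(split(key, key$season), function(d) {
    if (nrow(d) >= 3L) ols_regression(d$age_days, d$pmax) else NULL
  })
  list(pmax = key, fits = fits)
}
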
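# Incubation-derived rates: NPP from DIC drawdown, DOC exudation from DOC
# accumulation, percent extracellular release (PER), and the light / maturity
# classifications used throughout.

#' Net primary production from DIC drawdown
#'
#' NPP (umol C per g dry weight per hour) of a blade sealed in a chamber of
#' volume `volume_l` for `duration_h` hours:
#' `NPP = (dic_start - dic_end) * volume_l / (duration_h * dry_mass_g)`.
#' Negative values are apparent respiration (dark incubations) and are
#' returned as-is.
#'
#' @param dic_start,dic_end DIC concentrations (umol C / L) at the start and
#'   end of the incubation.
#' @param volume_l chamber seawater volume (L), > 0.
#' @param duration_h incubation duration (h), > 0.
#' @param dry_mass_g blade tissue dry mass (g), > 0.
#' @return NPP in umol C g_DW^-1 h^-1 (vectorized).
#' @export
compute_npp <- function(dic_start, dic_end, volume_l, duration_h, dry_mass_g) {
  check_incubation_meta(volume_l, duration_h, dry_mass_g)
  (dic_start - dic_end) * volume_l / (duration_h * dry_mass_g)
}

#' DOC exudation rate from DOC accumulation
#'
#' `DOC_ex = (doc_end - doc_start) * volume_l / (duration_h * dry_mass_g)`,
#' in umol C g_DW^-1 h^-1. Small negative values can occur (net DOC uptake or
#' measurement noise) and are returned as-is.
#'
#' @param doc_start,doc_end DOC concentrations (umol C / L) at the start and
#'   end of the incubation. If duplicate DOC samples were taken per time
#'   point, average them before calling (see [derive_rates()], which does).
#' @inheritParams compute_npp
#' @return DOC_ex in umol C g_DW^-1 h^-1 (vectorized).
#' @export
compute_doc_ex <- function(doc_start, doc_end, volume_l, duration_h, dry_mass_g) {
  check_incubation_meta(volume_l, duration_h, dry_mass_g)
  (doc_end - doc_start) * volume_l / (duration_h * dry_mass_g)
}

check_incubation_meta <- function(volume_l, duration_h, dry_mass_g) {
  if (any(!is.finite(volume_l)) || any(volume_l <= 0))
    stop("volume_l must be finite and > 0")
  if (any(!is.finite(duration_h)) || any(duration_h <= 0))
    stop("duration_h must be finite and > 0")
  if (any(!is.finite(dry_mass_g)) || any(dry_mass_g <= 0))
    stop("dry_mass_g must be finite and > 0")
  invisible(TRUE)
}

#' Percent extracellular release
#'
#' PER = 100 * DOC_ex / NPP, defined only for incubations with net positive
#' photosynthesis; `NA` is returned where `npp <= 0` (those incubations are
#' excluded from PER summaries).
#'
#' @param npp,doc_ex rates in umol C g_DW^-1 h^-1 (vectorized).
#' @return PER in percent, `NA` where `npp <= 0`.
#' @export
compute_per <- function(npp, doc_ex) {
  ifelse(is.finite(npp) & npp > 0, 100 * doc_ex / npp, NA_real_)
}

#' Classify incubation light regime
#'
#' Dark at PAR = 0; saturating above 300 umol photons m^-2 s^-1 (the
#' irradiance beyond which giant kelp NPP saturates); limiting in between.
#'
#' @param par photosynthetically active radiation, umol photons m^-2 s^-1,
#'   >= 0 (vectorized).
#' @param saturation saturating-light threshold (umol photons m^-2 s^-1).
#' @return factor with levels `dark`, `limiting`, `saturating`.
#' @export
classify_light <- function(par, saturation = 300) {
  if (any(!is.finite(par)) || any(par < 0)) stop("par must be finite and >= 0")
  factor(ifelse(par == 0, "dark", ifelse(par > saturation, "saturating", "limiting")),
         levels = c("dark", "limiting", "saturating"))
}

#' Classify blade maturity by age
#'
#' Blades older than `threshold` days (default 50) are senescent; 50 days
#' exactly is mature, consistent with the satellite rule that counts biomass
#' strictly older than 50 days as senescent.
#'
#' @param age_days blade age in days, >= 0 (vectorized).
#' @param threshold senescence onset age in days.
#' @return factor with levels `mature`, `senescent`.
#' @export
classify_maturity <- function(age_days, threshold = 50) {
  if (any(!is.finite(age_days)) || any(age_days < 0))
    stop("age_days must be finite and >= 0")
  factor(ifelse(age_days > threshold, "senescent", "mature"),
         levels = c("mature", "senescent"))
}

#' Derive rate records from an incubation table
#'
#' Takes one row per blade x light level with raw concentrations and returns
#' the tidy rate table: NPP, DOC_ex, PER, light class, maturity class.
#' Duplicate DOC measurements (columns `doc_start_b` / `doc_end_b`, if
#' present) are averaged with their primary before the rate computation.
#' Incubations flagged as damaged are dropped unless `include_damaged`.
#'
#' @param incubations data.frame with columns `blade_id`, `season`,
#'   `age_days`, `par`, `dic_start`, `dic_end`, `doc_start`, `doc_end`,
#'   `volume_l`, `duration_h`, `dry_mass_g`, and optionally `damaged_flag`,
#'   `doc_start_b`, `doc_end_b`.
#' @param include_damaged keep damaged-flagged rows (sensitivity runs).
#' @param maturity_age,par_saturation classification thresholds (days; umol
#'   photons m^-2 s^-1).
#' @return data.frame of rate records: ids and metadata plus `npp`, `doc_ex`,
#'   `per_pct`, `light_class`, `maturity`.
#' @export
derive_rates <- function(incubations, include_damaged = FALSE,
                         maturity_age = 50, par_saturation = 300) {
  req <- c("blade_id", "season", "age_days", "par", "dic_start", "dic_end",
           "doc_start", "doc_end", "volume_l", "duration_h", "dry_mass_g")
  miss <- setdiff(req, names(incubations))
  if (length(miss))
    stop("incubation table is missing columns: ", paste(miss, collapse = ", "))
  df <- incubations
  if (!include_damaged && "damaged_flag" %in% names(df))
    df <- df[!isTRUE_vec(df$damaged_flag), , drop = FALSE]
  doc0 <- df$doc_start
  doc1 <- df$doc_end
  if (all(c("doc_start_b", "doc_end_b") %in% names(df))) {
    doc0 <- rowMeans(cbind(df$doc_start, df$doc_start_b), na.rm = TRUE)
    doc1 <- rowMeans(cbind(df$doc_end, df$doc_end_b), na.rm = TRUE)
  }
  npp <- compute_npp(df$dic_start, df$dic_end, df$volume_l, df$duration_h, df$dry_mass_g)
  doc_ex <- compute_doc_ex(doc0, doc1, df$volume_l, df$duration_h, df$dry_mass_g)
  data.frame(
    blade_id = df$blade_id,
    season = df$season,
    age_days = df$age_days,
    par = df$par,
    npp = npp,
    doc_ex = doc_ex,
    per_pct = compute_per(npp, doc_ex),
    light_class = classify_light(df$par, par_saturation),
    maturity = classify_maturity(df$age_days, maturity_age),
    stringsAsFactors = FALSE
  )
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Summarize rates by class
#'
#' Mean, SD, n and range of a rate variable within each requested cell of
#' maturity x light class x season. Empty cells are absent from the output
#' (not reported as zero); single-record cells report `NA` SD.
#'
#' @param records rate table from [derive_rates()].
#' @param by grouping columns (subset of `maturity`, `light_class`, `season`).
#' @param var variable to summarize (`"doc_ex"`, `"npp"` or `"per_pct"`).
#' @return data.frame with one row per non-empty cell: grouping columns,
#'   `mean`, `sd`, `n`, `min`, `max`.
#' @export
summarize_rates <- function(records, by = c("maturity", "light_class"),
                            var = "doc_ex") {
  stopifnot(var %in% names(records), all(by %in% names(records)))
  v <- records[[var]]
  keep <- is.finite(v)
  records <- records[keep, , drop = FALSE]
  v <- v[keep]
  if (nrow(records) == 0L)
    return(data.frame())
  key <- interaction(records[by], drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(levels(key), function(k) {
    sel <- key == k
    vals <- v[sel]
    cell <- records[which(sel)[1L], by, drop = FALSE]
    cbind(cell, data.frame(
      mean = mean(vals),
      sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
      n = length(vals), min = min(vals), max = max(vals)
    ))
  }))
  rownames(out) <- NULL
  out
}
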
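# Synthetic blade-incubation generator. Emits raw DIC/DOC concentration
# pairs that invert (through the rates module) to known ground-truth NPP and
# DOC exudation, with the statistical structure the analysis assumes:
# mature DOC_ex linear in NPP (slope 0.015, intercept 0.96), senescent
# DOC_ex right-skewed (lognormal; mean 14.0, SD 14.1), light-independent and
# increasing with physiological decline, Pmax declining linearly with age,
# and exudate sugar composition shifting from fucose-rich (mature) to
# mannuronic-acid-rich (senescent).

#' Configuration for the incubation simulator
#'
#' Defaults are the stated experimental world: six replicate blades per age,
#' ages spanning early maturity (16 d) to late senescence (78 d), two
#' seasonal cohorts, three light levels per blade (dark / limiting /
#' saturating), the published mature DOC_ex-NPP line (0.015 x + 0.96), the
#' published senescent moments (14.0 +/- 14.1), NPP saturating above ~300
#' umol photons m^-2 s^-1 (half-saturation 150 with a tanh light curve), and
#' concentration noise at the reported analytical precisions (DIC 2.9,
#' DOC 0.6 umol C/L).
#'
#' @param n_blades_per_age replicate blades per age x season.
#' @param ages_days sampled blade ages (days).
#' @param seasons cohort labels.
#' @param par_levels PAR grid per blade (umol photons m^-2 s^-1; includes 0).
#' @param mature_slope,mature_intercept DOC_ex vs NPP line for mature blades
#'   (dimensionless; umol C g_DW^-1 h^-1).
#' @param senescent_mean,senescent_sd target moments of the senescent DOC_ex
#'   law (umol C g_DW^-1 h^-1).
#' @param pmax_young named per-season Pmax at age 0 (umol C g_DW^-1 h^-1).
#' @param pmax_decline_per_day named per-season linear Pmax decline
#'   (umol C g_DW^-1 h^-1 d^-1); the summer cohort declines faster.
#' @param par_half_sat light half-saturation (umol photons m^-2 s^-1).
#' @param respiration dark respiration (umol C g_DW^-1 h^-1).
#' @param noise_sd list of noise scales: `dic`, `doc` (umol C/L, measurement),
#'   `doc_bio` (umol C g_DW^-1 h^-1, biological scatter about the mature
#'   line), `pmax` (between-blade Pmax variation). Set all to 0 for exact
#'   noise-free inversion.
#' @param carb_frac_mean,carb_frac_sd carbohydrate share of released DOC (%).
#' @param seed RNG seed; fixes all outputs.
#' @return list of class `"incubation_sim_config"`.
#' @export
incubation_sim_config <- function(
    n_blades_per_age = 6L,
    ages_days = c(16, 26, 36, 43, 58, 68, 78),
    seasons = c("spring", "summer"),
    par_levels = c(0, 150, 1000),
    mature_slope = 0.015,
    mature_intercept = 0.96,
    senescent_mean = 14.0,
    senescent_sd = 14.1,
    pmax_young = c(spring = 240, summer = 250),
    pmax_decline_per_day = c(spring = 1.6, summer = 2.8),
    par_half_sat = 150,
    respiration = 10,
    noise_sd = list(dic = 2.9, doc = 0.6, doc_bio = 1.6, pmax = 15),
    carb_frac_mean = 10.3,
    carb_frac_sd = 4.9,
    seed = 1L) {
  cfg <- list(n_blades_per_age = as.integer(n_blades_per_age),
              ages_days = ages_days, seasons = seasons, par_levels = par_levels,
              mature_slope = mature_slope, mature_intercept = mature_intercept,
              senescent_mean = senescent_mean, senescent_sd = senescent_sd,
              pmax_young = pmax_young, pmax_decline_per_day = pmax_decline_per_day,
              par_half_sat = par_half_sat, respiration = respiration,
              noise_sd = noise_sd, carb_frac_mean = carb_frac_mean,
              carb_frac_sd = carb_frac_sd, seed = seed)
  if (cfg$n_blades_per_age < 1L) stop("n_blades_per_age must be >= 1")
  if (any(cfg$ages_days < 0)) stop("ages_days must be >= 0")
  if (any(cfg$par_levels < 0)) stop("par_levels must be >= 0")
  if (cfg$senescent_mean <= 0 || cfg$senescent_sd < 0)
    stop("senescent moments must be positive")
  if (any(unlist(cfg$noise_sd) < 0)) stop("noise_sd terms must be >= 0")
  if (cfg$par_half_sat <= 0) stop("par_half_sat must be > 0")
  if (!all(cfg$seasons %in% names(cfg$pmax_young)) ||
      !all(cfg$seasons %in% names(cfg$pmax_decline_per_day)))
    stop("pmax_young and pmax_decline_per_day need an entry per season")
  structure(cfg, class = "incubation_sim_config")
}

# lognormal parameters matching a target mean and SD
lognormal_params <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate blade incubations with ground truth
#'
#' Forward-simulates the incubation experiment: per blade, true NPP follows
#' `Pmax(age) * tanh(PAR / half_sat) - respiration`; mature true DOC_ex is
#' `slope * max(NPP, 0) + intercept` plus biological scatter; senescent true
#' DOC_ex is lognormal (moment-matched to the configured mean/SD),
#' light-independent, with its conditional mean increasing with the blade's
#' chlorophyll decline (progressive senescence). Raw concentration pairs are
#' produced by inverting the rate equations around fixed baselines (DIC 2000,
#' DOC 80 umol C/L) so the rates module reconstructs the truths; duplicate
#' DOC samples per time point are emitted. Tissue C, N, chlorophyll and
#' exudate sugar concentrations are generated consistently with the blade's
#' physiological state.
#'
#' @param cfg an [incubation_sim_config()].
#' @return list with `incubations` (one row per blade x light level; raw
#'   concentrations, metadata, tissue and sugar columns) and `truth` (same
#'   rows: `npp_true`, `doc_ex_true`, `maturity_true`, plus the blade's
#'   `pmax_true`, `chl_norm_true`, `man_ura_frac_true`).
#' @export
simulate_incubations <- function(cfg = incubation_sim_config()) {
  stopifnot(inherits(cfg, "incubation_sim_config"))
  local_seed(cfg$seed, simulate_incubations_impl(cfg))
}

simulate_incubations_impl <- function(cfg) {
  ns <- cfg$noise_sd
  blades <- expand.grid(season = cfg$seasons, age_days = cfg$ages_days,
                        rep = seq_len(cfg$n_blades_per_age),
                        stringsAsFactors = FALSE)
  blades$blade_id <- sprintf("%s_a%02d_r%d", blades$season, blades$age_days, blades$rep)
  nb <- nrow(blades)

  # per-blade physiology
  p0 <- cfg$pmax_young[blades$season]
  dec <- cfg$pmax_decline_per_day[blades$season]
  blades$pmax_true <- pmax(p0 - dec * blades$age_days + stats::rnorm(nb, 0, ns$pmax), 0)
  sen <- blades$age_days > 50

  # Chl:C sigmoid decline with age (spring cohort richer in pigment)
  chlc_top <- ifelse(blades$season == "spring", 0.004, 0.0025)
  chlc_floor <- 4e-4
  blades$chlc_true <- chlc_floor +
    (chlc_top - chlc_floor) / (1 + exp(0.15 * (blades$age_days - 55)))
  # severity of senescence in (0, 1]: drives senescent DOC_ex and Man-URA
  sev <- rep(0, nb)
  sev[sen] <- (blades$age_days[sen] - 50) / max(blades$age_days - 50, 1)

  # blade mean senescent DOC_ex scales with severity (population mean kept at target)
  w <- rep(1, nb)
  if (any(sen)) w[sen] <- sev[sen] / mean(sev[sen])

  # tissue composition: dry mass, C, N (seasonal C:N, rising after 50 d)
  blades$dry_mass_g <- stats::runif(nb, 4, 6)
  cfrac <- 0.30 * (1 + stats::rnorm(nb, 0, 0.03))
  blades$carbon_mg <- cfrac * blades$dry_mass_g * 1000
  cn_base <- ifelse(blades$season == "spring", 11.8, 34.6)
  cn <- cn_base + ifelse(sen, 0.25 * (blades$age_days - 50), 0) +
    stats::rnorm(nb, 0, 0.05 * cn_base)
  blades$nitrogen_mg <- blades$carbon_mg * (14.007 / 12.011) / cn
  blades$chla_mg <- blades$chlc_true * blades$carbon_mg *
    exp(stats::rnorm(nb, 0, 0.08))
  blades$disk_dry_mass_g <- stats::runif(nb, 0.05, 0.12)

  # exudate composition: Man-URA rises and fucose falls with severity;
  # means anchored at the mature (5%, 47%) and senescent (34%, 32%) states
  mean_sev <- if (any(sen)) mean(sev[sen]) else 1
  man_ura <- 0.05 + (0.34 - 0.05) * sev / mean_sev + stats::rnorm(nb, 0, 0.02)
  fucose <- 0.47 - (0.47 - 0.32) * sev / mean_sev + stats::rnorm(nb, 0, 0.03)
  man_ura <- pmin(pmax(man_ura, 0.01), 0.60)
  fucose <- pmin(pmax(fucose, 0.05), 0.60)
  rest_props <- c(rhamnose = 8, arabinose = 6, galactosamine = 5, glucosamine = 5,
                  galactose = 14, gal_ura = 5, glc_ura = 5)
  rest_props <- rest_props / sum(rest_props)
  rest <- outer(1 - man_ura - fucose, rest_props) *
    matrix(exp(stats::rnorm(nb * length(rest_props), 0, 0.15)), nrow = nb)
  sugar_frac <- cbind(fucose = fucose, rest, man_ura = man_ura)
  sugar_frac <- sugar_frac / rowSums(sugar_frac)
  sugar_frac <- sugar_frac[, SUGAR_MONOMERS, drop = FALSE]
  blades$carb_frac_pct <- pmin(pmax(
    stats::rnorm(nb, cfg$carb_frac_mean, cfg$carb_frac_sd), 1), 25)

  # one incubation row per blade x light level
  rows <- blades[rep(seq_len(nb), each = length(cfg$par_levels)), , drop = FALSE]
  rows$par <- rep(cfg$par_levels, times = nb)
  rows$volume_l <- 10
  rows$duration_h <- round(stats::runif(nrow(rows), 2, 3), 2)
  n <- nrow(rows)
  rsen <- rows$age_days > 50

  npp_true <- rows$pmax_true * tanh(rows$par / cfg$par_half_sat) - cfg$respiration
  doc_true <- numeric(n)
  doc_true[!rsen] <- cfg$mature_slope * pmax(npp_true[!rsen], 0) +
    cfg$mature_intercept + stats::rnorm(sum(!rsen), 0, ns$doc_bio)
  if (any(rsen)) {
    wrow <- w[rep(seq_len(nb), each = length(cfg$par_levels))][rsen]
    mu <- cfg$senescent_mean * wrow
    lp <- lognormal_params(1, cfg$senescent_sd / cfg$senescent_mean)
    doc_true[rsen] <- mu * stats::rlnorm(sum(rsen), lp$meanlog, lp$sdlog)
  }

  # invert the rate equations to raw concentrations, then add measurement noise
  fac <- rows$duration_h * rows$dry_mass_g / rows$volume_l
  dic0 <- 2000
  doc0 <- 80
  rows$dic_start <- dic0 + stats::rnorm(n, 0, ns$dic)
  rows$dic_end <- dic0 - npp_true * fac + stats::rnorm(n, 0, ns$dic)
  rows$doc_start <- doc0 + stats::rnorm(n, 0, ns$doc)
  rows$doc_start_b <- doc0 + stats::rnorm(n, 0, ns$doc)
  rows$doc_end <- doc0 + doc_true * fac + stats::rnorm(n, 0, ns$doc)
  rows$doc_end_b <- doc0 + doc_true * fac + stats::rnorm(n, 0, ns$doc)
  rows$damaged_flag <- FALSE

  # reconstructable truths: noise entered only through the emitted
  # concentrations, so noise-free configs invert exactly
  npp_rec <- (rows$dic_start - rows$dic_end) / fac
  doc_rec <- (rowMeans(cbind(rows$doc_end, rows$doc_end_b)) -
                rowMeans(cbind(rows$doc_start, rows$doc_start_b))) / fac

  # sugar monomer concentrations: composition is a blade-level measurement
  # (one exudate sample per blade), so pool the blade's DOC release across
  # its incubations. Total umol C released: delta[DOC] * V = rate * T * m.
  doc_release_umol_c <- pmax(doc_rec, 0) * fac * rows$volume_l
  blade_release <- as.numeric(rowsum(doc_release_umol_c, rows$blade_id)[rows$blade_id, ])
  sugar_c <- rows$carb_frac_pct / 100 * blade_release
  frac_rows <- sugar_frac[rep(seq_len(nb), each = length(cfg$par_levels)), , drop = FALSE]
  conc <- frac_rows * (sugar_c / 6) / rows$volume_l  # ~6 C atoms per monomer
  colnames(conc) <- paste0("sugar_", SUGAR_MONOMERS)

  keep <- c("blade_id", "season", "age_days", "par", "dic_start", "dic_end",
            "doc_start", "doc_end", "doc_start_b", "doc_end_b", "volume_l",
            "duration_h", "dry_mass_g", "damaged_flag", "carbon_mg",
            "nitrogen_mg", "chla_mg", "disk_dry_mass_g", "carb_frac_pct")
  incub <- cbind(rows[keep], as.data.frame(conc))
  rownames(incub) <- NULL
  truth <- data.frame(
    blade_id = rows$blade_id, season = rows$season, age_days = rows$age_days,
    par = rows$par,
    npp_true = npp_true, doc_ex_true = doc_true,
    maturity_true = ifelse(rsen, "senescent", "mature"),
    pmax_true = rows$pmax_true, chlc_true = rows$chlc_true,
    man_ura_frac_true = frac_rows[, "man_ura"],
    stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL
  list(incubations = incub, truth = truth, config = cfg)
}
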
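# End-to-end orchestration: configuration, stage runners, CSV/JSON output
# and a small command-line front end. Every source of randomness is seeded
# from a single root seed so two runs of the same config are byte-identical.

#' Pipeline configuration
#'
#' Collects the thresholds and settings for the full synthetic-to-regional
#' run. Serializes losslessly through JSON ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param maturity_age senescence onset age (days).
#' @param lifespan_days cohort lifespan (days); must exceed `maturity_age`.
#' @param par_saturation saturating-light threshold (umol photons m^-2 s^-1).
#' @param wet_dry_ratio dry:wet canopy mass ratio.
#' @param photoperiod_h daylight hours for mature tissue.
#' @param n_sim bootstrap simulations.
#' @param bootstrap_statistic `"median"` or `"mean"`.
#' @param seed root RNG seed (all stage seeds derive from it).
#' @param include_damaged keep damaged-flagged incubations (sensitivity).
#' @param loss cohort loss attribution (`"oldest_first"`/`"proportional"`).
#' @param n_perm PERMANOVA permutations.
#' @param output_dir where [run_pipeline()] writes its outputs.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(maturity_age = 50, lifespan_days = 120,
                            par_saturation = 300, wet_dry_ratio = 0.12,
                            photoperiod_h = 12, n_sim = 100000L,
                            bootstrap_statistic = c("median", "mean"),
                            seed = 1L, include_damaged = FALSE,
                            loss = "oldest_first", n_perm = 999L,
                            output_dir = tempfile("kelpdoc_run_")) {
  bootstrap_statistic <- match.arg(bootstrap_statistic)
  cfg <- list(maturity_age = maturity_age, lifespan_days = lifespan_days,
              par_saturation = par_saturation, wet_dry_ratio = wet_dry_ratio,
              photoperiod_h = photoperiod_h, n_sim = as.integer(n_sim),
              bootstrap_statistic = bootstrap_statistic,
              seed = as.integer(seed), include_damaged = include_damaged,
              loss = loss, n_perm = as.integer(n_perm),
              output_dir = output_dir)
  if (any(c(cfg$maturity_age, cfg$lifespan_days, cfg$par_saturation,
            cfg$photoperiod_h) <= 0))
    stop("thresholds must be positive")
  if (cfg$lifespan_days <= cfg$maturity_age)
    stop("lifespan_days must exceed maturity_age")
  if (cfg$wet_dry_ratio <= 0 || cfg$wet_dry_ratio > 1)
    stop("wet_dry_ratio must be in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

# deterministic child seeds below 2^31, derived from the root seed
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 7919L + stage * 104729L) %% 2000000011L
}

#' Run the full synthetic pipeline
#'
#' Simulate incubations and canopy, derive rates and classes, bootstrap the
#' three rate-class distributions, run the physiology and composition
#' analyses, track canopy cohort age structure, and upscale to regional
#' monthly/annual DOC production with and without senescence. Writes tidy
#' CSVs and a `metrics.json` report to `config$output_dir` and returns the
#' full result list invisibly.
#'
#' @param config a [pipeline_config()].
#' @param incubation_cfg,canopy_cfg optional simulator configs; by default
#'   they are built from the pipeline seed.
#' @param write write output files (default TRUE).
#' @return (invisibly) list with all stage results and `metrics`.
#' @export
run_pipeline <- function(config = pipeline_config(), incubation_cfg = NULL,
                         canopy_cfg = NULL, write = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[kelpDOC %s] ", format(Sys.time(), "%H:%M:%S")), sprintf(...))

  if (is.null(incubation_cfg))
    incubation_cfg <- incubation_sim_config(seed = derive_seed(config$seed, 1L))
  if (is.null(canopy_cfg))
    canopy_cfg <- canopy_sim_config(seed = derive_seed(config$seed, 2L),
                                    lifespan_days = config$lifespan_days,
                                    senescence_age_days = config$maturity_age)

  log_stage("simulating incubations")
  sim <- simulate_incubations(incubation_cfg)
  log_stage("deriving rates (%d incubation rows)", nrow(sim$incubations))
  rates <- derive_rates(sim$incubations, include_damaged = config$include_damaged,
                        maturity_age = config$maturity_age,
                        par_saturation = config$par_saturation)

  rate_summary <- summarize_rates(rates, by = c("maturity", "light_class"))
  stat_fun <- if (config$bootstrap_statistic == "mean") mean else stats::median

  log_stage("bootstrapping rate classes (n_sim = %d)", config$n_sim)
  boot_seed <- derive_seed(config$seed, 3L)
  class_values <- list(
    mature_dark = rates$doc_ex[rates$maturity == "mature" & rates$light_class == "dark"],
    mature_light = rates$doc_ex[rates$maturity == "mature" & rates$light_class == "saturating"],
    senescent = rates$doc_ex[rates$maturity == "senescent"])
  boots <- lapply(seq_along(class_values), function(i)
    bootstrap_stat(class_values[[i]], stat_fun, n_sim = config$n_sim,
                   seed = boot_seed + i))
  names(boots) <- names(class_values)
  rdist <- rate_distributions(
    mature_dark = boots$mature_dark[c("median", "ci_low", "ci_high")],
    mature_light = boots$mature_light[c("median", "ci_low", "ci_high")],
    senescent = boots$senescent[c("median", "ci_low", "ci_high")])

  log_stage("physiology and composition")
  pm <- pmax_by_age(rates)
  mature_fit <- model2_regression(
    rates$npp[rates$maturity == "mature"], rates$doc_ex[rates$maturity == "mature"])

  blade_rows <- !duplicated(sim$incubations$blade_id)
  sugars <- as.matrix(sim$incubations[blade_rows, paste0("sugar_", SUGAR_MONOMERS)])
  colnames(sugars) <- SUGAR_MONOMERS
  pos <- rowSums(sugars) > 0
  mole_pct <- compute_mole_pct(sugars[pos, , drop = FALSE])
  maturity_blade <- classify_maturity(sim$incubations$age_days[blade_rows],
                                      config$maturity_age)[pos]
  pca <- composition_pca(mole_pct, maturity_blade)
  perm <- permanova(scale(mole_pct), maturity_blade, n_perm = config$n_perm,
                    seed = derive_seed(config$seed, 4L))
  blade_doc <- tapply(rates$doc_ex, rates$blade_id, mean)
  blade_ids <- sim$incubations$blade_id[blade_rows][pos]
  manura_fit <- docex_vs_manura(as.numeric(blade_doc[blade_ids]),
                                mole_pct[, "man_ura"])

  log_stage("simulating canopy and tracking cohorts (%d pixels)", canopy_cfg$n_pixels)
  canopy <- simulate_canopy(canopy_cfg)
  age_struct <- regional_age_structure(canopy$observations,
                                       lifespan_days = config$lifespan_days,
                                       senescence_age = config$maturity_age,
                                       loss = config$loss)

  log_stage("upscaling to regional DOC production")
  with_sen <- annual_production(age_struct$region, rdist, "with_senescence",
                                config$wet_dry_ratio, config$photoperiod_h)
  without_sen <- annual_production(age_struct$region, rdist, "without_senescence",
                                   config$wet_dry_ratio, config$photoperiod_h)
  share <- senescence_share(with_sen, without_sen)

  metrics <- list(
    n_incubations = nrow(rates),
    rate_summary = rate_summary,
    mature_docex_npp = unclass(mature_fit)[c("slope", "intercept", "r_squared", "n", "p_value")],
    bootstrap = lapply(boots, function(b) unclass(b)[c("median", "se", "ci_low", "ci_high")]),
    permanova = perm[c("F", "r_squared", "p_value")],
    docex_vs_manura = unclass(manura_fit)[c("slope", "intercept", "r_squared", "n")],
    carb_fraction_mean = mean(sim$incubations$carb_frac_pct),
    annual_with_gg = mean(with_sen$annual$production_gg_c),
    annual_without_gg = mean(without_sen$annual$production_gg_c),
    senescence_share_pct = share$mean,
    global_extrapolation_tg = global_extrapolation(max(with_sen$annual$production_gg_c_hi)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- list(config = config, incubation_sim = sim, rates = rates,
                 rate_summary = rate_summary, bootstraps = boots,
                 rate_distributions = rdist, pmax = pm,
                 mature_fit = mature_fit, mole_pct = mole_pct, pca = pca,
                 permanova = perm, manura_fit = manura_fit, canopy = canopy,
                 age_structure = age_struct, with_senescence = with_sen,
                 without_senescence = without_sen, share = share,
                 metrics = metrics)

  if (write) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, nm) utils::write.csv(df, file.path(config$output_dir, nm),
                                            row.names = FALSE)
    wr(sim$incubations, "incubations.csv")
    wr(sim$truth, "truth_incubations.csv")
    wr(rates, "rates.csv")
    wr(rate_summary, "rate_summary.csv")
    wr(canopy$observations, "canopy_observations.csv")
    wr(canopy$truth_region, "truth_canopy_region.csv")
    wr(age_struct$region, "monthly_age_structure.csv")
    wr(rbind(with_sen$monthly, without_sen$monthly), "doc_production_monthly.csv")
    wr(rbind(with_sen$annual, without_sen$annual), "doc_production_annual.csv")
    # drop non-scalar entries JSON can't round-trip compactly, and the wall
    # clock (the written report must be byte-identical across runs)
    m <- metrics
    m$rate_summary <- NULL
    m$elapsed_s <- NULL
    jsonlite::write_json(m, file.path(config$output_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_pipeline_config(config, file.path(config$output_dir, "config.json"))
    log_stage("outputs written to %s", config$output_dir)
  }
  invisible(result)
}

#' Command-line entry point
#'
#' Minimal subcommand front end used by the `inst/cli/kelpdoc` script:
#' `simulate` (write synthetic tables), `rates` (incubation CSV to rates
#' CSV), `run` (full pipeline). Options are `--key value` pairs; `--seed`,
#' `--out` and `--config` are understood everywhere.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
kelpdoc_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: kelpdoc <simulate|rates|run> [--seed N] [--out DIR] [--config FILE]\n")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opts <- list(seed = 1L, out = "kelpdoc_out", config = NULL, input = NULL)
  i <- 2L
  while (i < length(args) + 1L) {
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) stop("missing value for --", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  seed <- as.integer(opts$seed)
  cfg <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
         else pipeline_config(seed = seed, output_dir = opts$out)
  cfg$output_dir <- opts$out
  status <- 0L
  switch(cmd,
    simulate = {
      dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
      sim <- simulate_incubations(incubation_sim_config(seed = seed))
      utils::write.csv(sim$incubations, file.path(opts$out, "incubations.csv"),
                       row.names = FALSE)
      utils::write.csv(sim$truth, file.path(opts$out, "truth_incubations.csv"),
                       row.names = FALSE)
      can <- simulate_canopy(canopy_sim_config(seed = seed))
      utils::write.csv(can$observations, file.path(opts$out, "canopy_observations.csv"),
                       row.names = FALSE)
      utils::write.csv(can$truth_region, file.path(opts$out, "truth_canopy_region.csv"),
                       row.names = FALSE)
    },
    rates = {
      if (is.null(opts$input)) stop("rates needs --input incubations.csv")
      inc <- utils::read.csv(opts$input)
      dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(derive_rates(inc), file.path(opts$out, "rates.csv"),
                       row.names = FALSE)
    },
    run = {
      run_pipeline(cfg)
    },
    {
      message("unknown subcommand: ", cmd)
      status <- 1L
    })
  invisible(status)
}
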
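# Shared fixtures: small, seeded configurations used across test files.

noise_free_cfg <- function(seed = 7L, ...) {
  incubation_sim_config(noise_sd = list(dic = 0, doc = 0, doc_bio = 0, pmax = 0),
                        seed = seed, ...)
}

small_canopy_cfg <- function(seed = 42L, n_pixels = 3L, years = 2L, ...) {
  canopy_sim_config(n_pixels = n_pixels, years = years, obs_noise_cv = 0,
                    seed = seed, ...)
}

# a minimal hand-built incubation table (one blade, one row)
one_incubation <- function(dic_start = 2000, dic_end = 1990, doc_start = 80,
                           doc_end = 83, volume_l = 10, duration_h = 2,
                           dry_mass_g = 5, age_days = 30, par = 500,
                           season = "spring", blade_id = "b1") {
  data.frame(blade_id = blade_id, season = season, age_days = age_days,
             par = par, dic_start = dic_start, dic_end = dic_end,
             doc_start = doc_start, doc_end = doc_end, volume_l = volume_l,
             duration_h = duration_h, dry_mass_g = dry_mass_g,
             damaged_flag = FALSE, stringsAsFactors = FALSE)
}

# exhaustive one-way PERMANOVA on a 1-D Euclidean toy: enumerate every
# assignment of the observations to the two group sizes
permanova_enumerate <- function(values, sizes) {
  n <- length(values)
  d2 <- as.matrix(dist(values))^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  f_of <- function(idx_a) {
    idx_b <- setdiff(seq_len(n), idx_a)
    sw <- 0
    for (sel in list(idx_a, idx_b)) {
      sub <- d2[sel, sel, drop = FALSE]
      sw <- sw + sum(sub[upper.tri(sub)]) / length(sel)
    }
    ((ss_total - sw) / 1) / (sw / (n - 2))
  }
  combos <- utils::combn(n, sizes[1L])
  fs <- apply(combos, 2L, f_of)
  list(f_all = fs, ss_total = ss_total)
}
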
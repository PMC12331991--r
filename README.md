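# kelpDOC

Partitioning giant kelp (*Macrocystis pyrifera*) net primary production
into dissolved organic carbon (DOC) release — from closed-chamber blade
incubations up to regional annual DOC production driven by satellite-style
canopy biomass and a daily cohort-age ledger.

Kelp releases DOC by two mechanisms with very different controls. Mature
tissue *exudes* a small, steady fraction of fresh photosynthate, so its
release rate follows NPP and light. Senescent tissue (blades older than ~50
days) *solubilizes*: bacterial degradation of cell-wall polysaccharides
such as alginate converts standing biomass carbon directly into DOC, at
high, light-independent rates that often exceed simultaneous NPP. Because
a large share of canopy biomass is senescent for much of the year, the
solubilization pathway dominates annual kelp DOC production. kelpDOC
implements the full analysis that quantifies this: incubation rate
equations, physiological-state classification, exudate sugar composition
statistics, an age-structured cohort tracker for canopy biomass, and
bootstrap upscaling to regional annual production.

The package is aimed at coastal carbon-cycle and remote-sensing ecologists
who want to reproduce, stress-test, or extend this style of blue-carbon
budget with their own incubation tables or biomass time series.

## Core quantities

For a blade of dry mass *m* (g) in a sealed chamber of volume *V* (L) for
*T* hours:

    NPP    = ([DIC]0 − [DIC]t) · V / (T · m)      (µmol C g_DW⁻¹ h⁻¹)
    DOC_ex = ([DOC]t − [DOC]0) · V / (T · m)      (µmol C g_DW⁻¹ h⁻¹)
    PER    = 100 · DOC_ex / NPP                    (only where NPP > 0)

Light classes: dark (PAR = 0), limiting, saturating (PAR > 300 µmol
photons m⁻² s⁻¹). Maturity: senescent strictly past 50 days of blade age.
Canopy biomass is tracked as daily cohorts aging to a 120-day lifespan;
monthly senescent fractions multiply the observed biomass and feed

    gC/day = 12.011e-6 · [ m_mature·(12·r_dark + 12·r_light) + m_senescent·24·r_sen ]

with the three rate classes summarized by a 100,000-resample bootstrap
(median ± SE, 95% percentile CI).

## Worked example

Everything below runs on the package's own synthetic generator, which is
seeded and emits ground truth alongside the raw concentration tables:

```r
library(kelpDOC)

sim   <- simulate_incubations(incubation_sim_config(seed = 1))
rates <- derive_rates(sim$incubations)
summarize_rates(rates, by = c("maturity", "light_class"), var = "doc_ex")
#>    maturity light_class mean   sd  n   min  max
#> 1    mature        dark  1.2  1.4 48 -2.16  4.3
#> 2 senescent        dark 16.5 16.8 36  1.13 86.0
#> 3    mature    limiting  2.9  2.1 48 -2.65  7.0
#> 4 senescent    limiting 12.9 10.6 36  2.89 46.2
#> 5    mature  saturating  3.7  1.7 48  0.35  7.5
#> 6 senescent  saturating  8.8 11.1 36  0.10 56.9
```

Mature DOC release sits at a few µmol C g_DW⁻¹ h⁻¹ and scales with light;
senescent release is several-fold higher, highly variable (SD ≈ mean), and
indifferent to light — the solubilization signature.

```r
m <- rates$maturity == "mature"
model2_regression(rates$npp[m], rates$doc_ex[m])
#> Model II (SMA) fit: y = 0.0251 x + 0.1772  (R2 = 0.304, n = 144, p = 7.82e-13)

sen <- rates$doc_ex[rates$maturity == "senescent"]
bootstrap_stat(sen, median, n_sim = 100000, seed = 2)
#> Bootstrap median (n = 108, 100000 simulations): 8.48 +/- 1.37 (95% CI 6.4-11.3)
```

Mature exudation is linearly coupled to NPP (the generative law is
0.015·NPP + 0.96; the SMA slope reads higher than the generative
coefficient whenever R² < 1 — see the methods vignette). The skewed
senescent rates bootstrap to a median well below their mean (~14).

The canopy chain, from sparse observations to regional production:

```r
can <- simulate_canopy(canopy_sim_config(seed = 1))
age <- regional_age_structure(can$observations)   # interpolate, track, split
w   <- annual_production(age$region, rate_distributions(), "with_senescence")
wo  <- annual_production(age$region, rate_distributions(), "without_senescence")
senescence_share(w, wo)$mean                       # % of production from senescence
```

And the global upper-limit arithmetic:

```r
global_extrapolation(c(8.2, 5.8, 14.8))   # Gg C/yr per 50 km2 -> Tg C/yr globally
#> [1] 321.44 227.36 580.16
```

A single call runs the whole pipeline (simulate → rates → composition →
canopy age → upscaling) and writes tidy CSVs plus a deterministic
`metrics.json`:

```r
run_pipeline(pipeline_config(seed = 7, output_dir = "out"))
```

There is also a small CLI (`inst/cli/kelpdoc`) with `simulate`, `rates`
and `run` subcommands.

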
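# weedclim

Linking occurrence records of root-parasitic weeds to satellite-style
environmental grids: heat-moisture coupling detection, altitudinal trend
models, and host-crop cross-referencing.

## The problem

*Striga*, *Orobanche* and *Phelipanche* (Orobanchaceae) are root parasites
of cereals and legumes whose dormant seeds only respond to host germination
stimulants after a temperature- and moisture-dependent *preconditioning*
phase. *Striga* species precondition best hot and wet; most *Orobanche*
prefer moderate temperatures. Climate trends should therefore leave
species-specific fingerprints in where and when these weeds are recorded.

`weedclim` is for researchers who have species occurrence tables (GBIF-style
CSV) and monthly gridded land-surface temperature (LST), root-zone
soil-moisture percentile (RZSM) and elevation fields, and want the full
analysis chain as tested, reusable functions:

- **cleaning** — duplicate and bad-coordinate removal with a counted,
  reconciling report;
- **enrichment** — nearest-cell extraction of LST/RZSM at lags 0, 1, 2
  months (calendar-correct across year boundaries), cell-climatology LST
  percentiles, elevation;
- **coupling** — a *heat-moisture coupling event* is a month with
  LST ≥ 25 °C **and** RZSM percentile ≥ 70 at one location; an occurrence
  is associated with coupling if such a month exists at any configured lag.
  Per-species association percentages with strict missing-value semantics;
- **trends** — tie-corrected Mann-Kendall tests (S, τ, continuity-corrected
  z, two-sided p) on monthly series; logistic trends of the > 1000 m
  occurrence indicator per species and of monthly coupling indicators per
  location, with Wald tests, separation flagging, odds-ratio/probability
  summaries, and increase/decrease classification stratified by elevation;
- **comparisons** — one-way ANOVA + Tukey HSD with compact-letter displays,
  standardized 3-variable PCA with deterministic sign orientation and time
  windows;
- **hosts** — presence of a species' host crops (harvested area > 0 at the
  nearest cell) across two harvested-area epochs;
- **synthetic data** — a scenario generator with planted niches, trends and
  host withdrawal, providing ground truth for every stage.

## Core statistics

For a monthly series x₁…xₙ, Mann-Kendall uses S = Σᵢ<ⱼ sign(xⱼ − xᵢ),
var(S) = [n(n−1)(2n+5) − Σₜ t(t−1)(2t+5)]/18 over tie groups t,
τ = S/√(D(D−T)), and a ±1 continuity-corrected normal score. Trend models
are logistic fits logit P(y=1) = a + b·t by IRLS on centered time
(tolerance 1e-8, cap 25 iterations); separation is flagged and reported,
never fatal. Coupling at one month is the inclusive conjunction
1{LST ≥ 25 °C} · 1{RZSM ≥ 70}; over the window, one decided true
short-circuits missing lags, otherwise any missing lag makes the record
undecidable and excluded.

## Worked example

Simulate the bundled synthetic world, clean and enrich the records, and
compute the coupling association and an elevation trend:

```r
library(weedclim)

sc  <- scenario_config(seed = 1)          # 8 species, 2006-2022, planted trends
env <- generate_env_grids(sc)             # monthly LST + RZSM, static elevation
occ <- generate_occurrences(sc, env)

path <- tempfile(fileext = ".csv")
write.csv(occ, path, row.names = FALSE, na = "")
cleaned <- clean_occurrences(read_occurrences(path))
print(cleaned$report)
#> cleaning_report: 1820 rows in, 1750 retained
#>   dropped missing_coordinates:       35
#>   dropped duplicate:                 35

enr <- enrich_occurrences(cleaned$records, env$lst, env$rzsm, env$elev)
species_association(enr)
#>                  species n_complete n_coupled pct_coupled
#> 1      Orobanche crenata        249         1       0.402
#> 2       Orobanche cumana        199         8       4.020
#> 3        Orobanche minor        248         1       0.403
#> 4 Phelipanche aegyptiaca        150         3       2.000
#> 5     Phelipanche ramosa        198         1       0.505
#> 6        Striga asiatica        299        68      22.742
#> 7    Striga gesnerioides        199        66      33.166
#> 8     Striga hermonthica        200        48      24.000

tr <- elevation_trend(enr[enr$species == "Striga asiatica", ])
tr$fit
#> logit_fit: slope = 0.124837 (SE 0.03241), z = 3.852, p = 0.0001171, n = 300
cat(sprintf("total odds ratio %.1f, probability change %+.3f\n",
            tr$odds$odds_ratio_total, tr$odds$delta_probability))
#> total odds ratio 7.4, probability change +0.298
```

The wet-hot *Striga* niches couple in 22–33% of records versus < 5% for
the cool or dry niches — the planted contrast — and the *S. asiatica*
analogue's odds of being recorded above 1000 m grow ~7-fold over the span
(log-odds +0.125/yr), recovering its planted +25 m/yr upslope drift.

`run_pipeline(run_config(output_dir = "out", scenario = sc))` executes
every stage and writes one artifact per stage (cleaning report, enriched
table, letter-annotated species summaries, per-species trend rows, coupling
associations, per-location trends with stratified classification, host
presence per epoch, windowed PCA loadings) plus a reconciling manifest. A
thin CLI wrapper lives at `inst/scripts/run_pipeline.R`.

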
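---
title: "Methods: heat-moisture coupling and altitudinal trends in parasitic weed records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat-moisture coupling and altitudinal trends in parasitic weed records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weedclim)
```

## The scientific problem

Root-parasitic weeds of the Orobanchaceae — *Striga*, *Orobanche* and
*Phelipanche* — destroy cereal and legume harvests across Africa, the
Mediterranean and Asia. Their seeds lie dormant in soil for years and only
become responsive to host-exuded germination stimulants after a
*preconditioning* phase whose success depends on temperature and moisture.
*Striga* species precondition best under hot, wet conditions; most
*Orobanche* species prefer moderate temperatures; *O. cumana* and
*P. aegyptiaca* germinate without preconditioning.

`weedclim` operationalizes this biology as a screening statistic on
occurrence records: a **heat-moisture coupling event** is a month in which,
at one location, the land-surface temperature (LST) is at or above
25&nbsp;°C *and* the root-zone soil-moisture (RZSM) percentile is at or
above 70 — hot and wet **in the same month**. An occurrence is *preceded*
by a coupling if such a month exists in the observation month or either of
the two preceding months (lags 0, 1, 2; the lag set is configurable via
`coupling_config()`). The package links occurrence tables to monthly
environmental grids, computes per-species coupling associations, and fits
the temporal models described below.

## Data model and conventions

**Occurrence cleaning** (`clean_occurrences()`). Rows are dropped for:
missing species; missing coordinates; out-of-range coordinates
(|lon| > 180, |lat| > 90); coordinates exactly (0, 0) — the canonical junk
coordinate in biodiversity databases; an unusable event date (all lag
arithmetic needs a month). Exact duplicates on
(species, lon, lat, year, month) keep the first row in file order. Each row
receives exactly one fate, reasons checked in that fixed order, so
`survivors + sum(drops) = input rows` always reconciles. Records missing
only elevation are kept — elevation is enriched from a grid later. No
uncertainty-radius heuristics are applied; the rule used is echoed in the
cleaning report.

**Grids and extraction** (`monthly_grid()`, `sample_grid()`,
`enrich_occurrences()`). Grids are regular lon/lat axes with an optional
contiguous monthly time axis. Point extraction is nearest-cell with ties
broken toward the lower index, and never extrapolates: points outside the
grid, or months outside the time axis, are missing. Interpolation is
deliberately avoided — the source products are coarse, and interpolating
would invent data. Month lags are calendar-correct across year boundaries
(lag 2 from January is November of the previous year).

**Units and percentiles.** LST inputs in scaled Kelvin are decoded as
`celsius = dn * scale + offset - 273.15` (`kelvin_to_celsius()`). RZSM is
carried directly on the percentile scale (0–100), the drought-indicator
convention of its source product, so the ≥ 70 threshold reads "upper ~
tercile, wet soil". LST percentiles (reported in the per-species summary
tables) rank a lagged value within its **cell's full monthly climatology**
using the inclusive convention
`100 · #(reference ≤ value) / #reference` — so "≥ 70" has unambiguous
inclusive semantics, and a value equal to the climatological maximum ranks
at 100. Ranking against the same calendar month only is available as
`climatology = "month"`; the all-months default matches the convention of
the moisture percentiles the temperature is coupled to.

**Per-analysis completeness.** A record missing RZSM is excluded from the
moisture and coupling analyses but kept for the temperature analysis; each
stage excludes exactly its own incomplete records via the
`complete_temp` / `complete_moist` / `complete_coupling` flags.

**Missing-value propagation in coupling.** A month with either constituent
missing is undecidable (`NA`), not `FALSE` — note that naive `&` logic in R
would decide `NA & FALSE` as `FALSE`. Over the lag window, one decided
`TRUE` short-circuits missing lags; otherwise any undecidable lag makes the
record undecidable, and undecidable records are excluded from both the
numerator and denominator of the per-species association percentages.

## Statistical machinery

**Mann-Kendall trend test** (`mann_kendall()`), for monotonic trends in
monthly series. `S = Σ_{i<j} sign(x_j − x_i)`;
`var(S) = [n(n−1)(2n+5) − Σ_t t(t−1)(2t+5)]/18` over tie groups of size
`t`; `τ = S / sqrt(D(D−T))` with `D = n(n−1)/2`, `T = Σ_t t(t−1)/2`
(tau-b against the tie-free time axis). The normal score uses the ±1
continuity correction — which maps |S| ≤ 1 to z = 0 — and a two-sided
p-value. The plain (non-seasonal) test with the normal approximation is
used at all n: the intended series are ≥ 24 months, where the
approximation is accurate and exact small-n tables add nothing. All-equal
series are the documented degenerate: τ = 0, p = 1.

**Logistic trend fits** (`fit_logit_trend()`), used both for the yearly
high-elevation indicator of each species and for monthly coupling
indicators at locations. The fit is IRLS on centered time (centering for
conditioning only; the slope is per original time unit and shift-invariant
to < 1e-6), tolerance 1e-8 on the coefficient step, cap 25 iterations.
Complete or quasi-separation — including constant responses — makes the
MLE diverge; the fit is then *flagged and reported* rather than failed,
because the diverged estimate with its enormous standard error is itself
the recognizable signature of the phenomenon (a species never seen above
the cutoff, a location where coupling never occurs). Detection: at the
iteration cap, |slope| > 15, SE(slope) > 100, |intercept| > 15 or
SE(intercept) > 100. `odds_summary()` converts a fit to the total odds
ratio `exp(slope · (t1 − t0))` and the change in fitted probability
between the endpoints, in the centered parameterization.

**Trend classification** (`coupling_frequency_trend()`,
`classify_all_locations()`). A location is "increase" iff slope > 0 and
Wald p < α, "decrease" iff slope < 0 and p < α, else "none";
separation-flagged fits are "none". The gate is α = 0.05, the conventional
level used everywhere else in the package. Per-location coupling uses the
lag-0 monthly conjunction — a location's month either is or is not a
coupling month; the three-lag window belongs to the occurrence-linked
analysis only. Stratification above/below the elevation cutoff uses the
strict reading (> 1000 m).

**Elevation cutoffs.** The trend analyses use strict `> 1000 m`
("exceeded"); the host-crop analysis uses inclusive `≥ 1000 m` ("1000 m or
higher"). The two readings are preserved as separate per-analysis defaults
and explicit arguments rather than silently unified.

**ANOVA, Tukey HSD, compact letters** (`anova_tukey_letters()`). One-way
ANOVA, then all pairwise Tukey-Kramer comparisons via the
studentized-range distribution (base R's `ptukey`, accurate to ~1e-4
against published tables at k = 3, df = 27). The compact-letter display
uses insert-and-absorb: start with one column holding all groups; for each
significant pair, split every column containing both; absorb columns
contained in others. Two groups share a letter iff their HSD comparison is
non-significant. Letters are assigned by descending group mean, so "a"
always marks the top group. Zero within-group variance is defined, not
fatal: equal means give F = 0, p = 1, one shared letter; unequal means
give F = ∞, p = 0.

**PCA** (`pca_3var()`, `windowed_pca()`). Three standardized variables
(elevation, lag-1 LST, lag-1 RZSM), decomposed via the singular values of
the standardized matrix. Each component's sign is fixed so its
largest-magnitude loading is positive — a deterministic orientation, since
SVD signs are otherwise arbitrary. Biplot arrows are
`loading · sqrt(eigenvalue)`. A zero-variance variable is a named failure.
Windowed PCA restricts to an inclusive year range; the full-range window
reproduces the unwindowed result exactly.

## The synthetic world

Real analyses of this kind rest on third-party occurrence downloads and
global satellite rasters. For validation, `weedclim` instead ships a
generator (`scenario_config()`, `generate_env_grids()`,
`generate_occurrences()`, `generate_crop_grids()`) whose **planted
structure is the ground truth** every pipeline stage is tested against.

The default world is a 24 × 40 cell grid (1° × 1.25°) spanning
10–34° E, 10° S–40° N over 2006–2022 (204 months): a hot tropical south
grading to cool mid-latitudes (0.35 °C per degree of latitude), one tall
tropical massif (peak ~2070 m) and one lower mid-latitude massif
(~1500 m). LST follows
`baseline(lat) − 6.5 °C/km · elev + 3 °C seasonal sinusoid + trend + N(0, 1.5)`
with the seasonal peak in July north of the equator and January south of
it. RZSM is generated directly on the percentile scale,
`baseline(lat) + trend + N(0, 10)` clipped to [0, 100]; no raw-moisture to
percentile conversion is simulated, matching the drought-indicator
convention of the real product.

**Planted trends.** Designated cells — by default the 1100–1700 m flank of
the *tropical* massif — receive +0.2 °C/yr LST and +2.0 percentile/yr
RZSM. This band is a deliberate choice: the planting contract is that the
monthly coupling probability at designated cells rises from a few percent
to roughly one half over the span, and that contract can only be realized
where the baseline climate keeps the 25 °C threshold within reach. Above
~1800 m (and on the cold mid-latitude massif) no moisture trend can
produce coupling events, so those cells are left stationary by design. All
other cells are stationary, giving the classifier's false-positive surface.

**Occurrences** are placed by importance sampling over (cell, month)
candidates — weights are Gaussian niche densities in lag-1 LST and lag-1
RZSM times a Gaussian elevation preference — rather than rejection
sampling, to bound runtime. The eight default niches mirror the study
system's contrasts: hot/wet *Striga* (with the *S. asiatica* and
*S. gesnerioides* preferred elevations drifting upslope at +25 and
+20 m/yr), cool *O. crenata* (preferred elevation declining at −30 m/yr
from the mid-latitude massif), hot-but-dry *P. aegyptiaca* whose records
essentially never follow a coupling. The default niches separate the
wet-hot and cool species' coupling associations by well over 20
percentage points — the planted margin asserted in the tests. Configurable
fractions of defective rows (missing coordinates, exact duplicates;
default 2% each) exercise the cleaning stage.

**Crops.** Harvested-area grids for seven host crops are generated once
and copied to the second epoch (host persistence), after which each
withdrawal entry zeroes one crop above an elevation cutoff in one epoch.
The default withdraws beans, peas and lentils — the *O. crenata* hosts —
above 1000 m in the 2015 epoch, reproducing the qualitative signature of
interest: high-elevation host presence collapses while overall presence
barely moves, and the cereal hosts of *S. asiatica* persist.

**Determinism.** One master seed drives three named substreams (env,
occurrences, crops), so modules can be regenerated independently;
identical seeds give bit-identical grids, occurrence tables and crop
layers, and `run_pipeline()` reruns are byte-identical.

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real data: spatially correlated noise and weather
systems (noise is iid per cell-month), cloud-mask artefacts and sensor
physics, coastlines and real topography, observation effort bias and
spatial clustering of collectors, taxonomic misidentification, and
coordinate imprecision beyond the planted missing/duplicate defects. The
tests establish that the *methods* recover known structure; they cannot
certify any substantive claim about real occurrence databases.

## Numerical choices and degenerate inputs

- Nearest-cell ties go to the lower index; exact threshold values couple
  (both thresholds inclusive).
- IRLS: tolerance 1e-8, cap 25; weights floored at 1e-10; non-finite
  iterates terminate with the last finite iterate, flagged.
- Mann-Kendall needs ≥ 3 usable values; location trends require ≥ 24
  usable months, else a missing result carrying the reason.
- Letters: ordered by descending mean; duplicate columns absorbed.
- PCA requires ≥ 3 complete rows and positive variance in every variable.
- Percentile ranks use `findInterval` on the sorted reference — O(log n)
  per query, identical to the direct ≤-count.

## Problem sizes in the test-suite

The suite validates against brute-force oracles and planted effects at
sizes chosen to keep the full run under half a minute while leaving the
Monte-Carlo bands far wider than the simulation error: 10,000 randomized
coupling samples against the brute-force scan; 1,000 short series against
pair enumeration; Mann-Kendall size at 2,000 Gaussian series of length
100; Wald coverage at 500 replicates; planted-effect recovery across the
102 designated and 150 sampled stationary cells of the full bundled
scenario; upslope-drift recovery at 25 generator replicates of the single
drifting species. `scripts/acceptance.R` recomputes the headline
quantities from scratch on the bundled scenario at a caller-supplied seed.

## Known limitations

- No spatial autocorrelation modelling, changepoint detection, or seasonal
  detrending of the monthly series; the Mann-Kendall test sees seasonal
  cycles as noise (conservative for LST, immaterial for percentile RZSM).
- No multiple-testing correction across species or locations, matching the
  descriptive character of the analysis.
- The coupling statistic is a screening definition, not a germination
  model: thresholds are biologically motivated constants, and the lag
  window is coarse (calendar months).
- Grid serialization is plain long-format CSV; the package does not read
  satellite archive formats directly — upstream conversion is assumed.
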
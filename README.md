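# floodcontam

Quantifies long-term **contamination of native fish assemblages by
non-native species** in floodplain monitoring surveys, for community
ecologists working with long-term, gear-structured survey data (e.g. the
quarterly gillnet/seine monitoring of Neotropical floodplain lakes and
river channels). The package computes the statistics, fits the temporal
models, and ships a mechanistic survey simulator so the whole pipeline can
be validated by parameter recovery.

## What it computes

For each sampling unit *s* (one gillnetting or seining event), with native /
non-native species richness R<sub>n</sub>, R<sub>nn</sub> and
area-standardised biomass B<sub>n</sub>, B<sub>nn</sub>
(B<sub>j</sub> = Σω<sub>ij</sub>/A, g·m⁻²):

| Index | Definition | Meaning |
|---|---|---|
| CI<sub>r</sub> | R<sub>nn</sub>/(R<sub>nn</sub>+R<sub>n</sub>) | richness contamination |
| CI<sub>b</sub> | B<sub>nn</sub>/(B<sub>nn</sub>+B<sub>n</sub>) | biomass contamination |
| CI<sub>e</sub> | R<sub>nn</sub>B<sub>nn</sub>/(R<sub>nn</sub>B<sub>nn</sub>+R<sub>n</sub>B<sub>n</sub>) | ecosystem (interaction) contamination |
| CI<sub>a</sub> | (CI<sub>b</sub>+CI<sub>r</sub>)/2 | additive form |
| CI<sub>sq</sub> | √(CI<sub>b</sub>·CI<sub>r</sub>) | multiplicative (geometric-mean) form |

plus **Kempton's Q** per locality, Q = (R/2)/ln(B₄/B₂) with B₄, B₂ the
75th/25th percentiles of the per-species biomass distribution (averaged
across localities per campaign), **Spearman rho** between biomass and
richness with exact small-sample p-values, and **penalized-spline temporal
trends** with AR(1) residual correlation and locality random intercepts
(`mgcv::gamm` + `nlme::corAR1`, with a likelihood-ratio trend test whose
size is verified by simulation). Mann–Whitney comparisons (exact by
enumeration for n₁+n₂ ≤ 10) compare rho distributions between origins.

The seeded generator (`simulate_survey()`) emulates the monitoring design —
9 localities, 368 m² gillnet effort, seine areas ≈ 247.69 ± 51.52 m²,
quarterly campaigns 2000–2017, a 42:26 native:non-native pool, lognormal
abundance and body mass, gear size selectivity, and non-native colonization
that accelerates through time and spikes in flood years — and emits the
realized true state for recovery scoring.

## Worked example

```r
library(floodcontam)

# simulate a default-design survey and summarise it
sim <- simulate_survey(default_config(seed = 1))
sim$survey
#> <survey_table>
#>   units:   972 (9 localities, 72 campaigns)
#>   catches: 33897
#>   registry: 68 species ( 42 native, 26 non-native, 0 unclassified )

# per-unit indices -> per-campaign mean richness contamination -> trend
us <- contamination_indices(summarize_units(sim$survey))
m <- us |>
  dplyr::filter(gear == "gillnet") |>
  dplyr::group_by(campaign) |>
  dplyr::summarise(ci = mean(CI_r, na.rm = TRUE), t = mean(time))
fit_smooth_trend(m$t, m$ci, label = "gillnet CI_r")
#> <trend_fit> gillnet CI_r
#>   n = 68, engine = gamm-ar1, transform = none
#>   edf = 8.72 (ref 8.72), F = 2302.44, p = 2e-10, adj-R2 = 0.996
#>   beta = 0.01371 +/- 0.000214 per year, phi = -0.124

# score the estimate against the simulator's true state
recovery_report(sim)
#> <recovery_report>
#>   n = 972 units; bias = 0.0361; rmse = 0.0468
#>   slopes: estimated 0.01425 vs true 0.01327 (sign agreement: TRUE)
```

The trend fit says richness contamination rises by ≈ 0.014 per year
(p = 2×10⁻¹⁰) in this replicate — the accelerating-colonization signal the
generator encodes — and the recovery report confirms the per-unit CI_r
tracks the true resident non-native fraction to within ≈ 0.04.

Locality-average index arithmetic works directly on published summaries
too; the additive index is linear, so locality means obey it exactly:

```r
ref <- reference_locality_ci()            # packaged 15-row reference table
row <- subset(ref, locality == "lgua" & method == "gillnet")
round_half_away(ci_additive(row$CIb, row$CIr), 2)
#> [1] 0.58
```

## Layout

- `R/` — data model and I/O, validation, indices, Kempton's Q, rank
  statistics, trend layer, simulator, pipeline runners, plots.
- `tests/testthat/` — oracle-based unit tests, property tests, and the
  acceptance suite.
- `vignettes/floodplain-contamination.Rmd` — the methods vignette: model
  assumptions, parameter choices, calibration evidence, limitations.
- `inst/extdata/parana_locality_ci.csv` — published locality-average
  contamination indices (reference surface for consistency checks).
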
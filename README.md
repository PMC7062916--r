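# tmfcarbon

Carbon stock estimation and altitudinal trend analysis for tropical
montane forest inventory plots.

Tropical montane forests store large amounts of carbon, partitioned among
aboveground biomass, coarse roots and the soil organic layer, and the
partitioning shifts along altitudinal and climatic gradients. This package
implements the full estimation chain used in plot-based carbon accounting
for such forests, for ecologists working with stem censuses, branch
wood-density samples, soil cores and plot climate tables:

- **Census handling** — long-format stem tables with a 2.5 cm DBH inclusion
  threshold; multi-stem individuals collapse to an effective DBH
  \(D = \sqrt{\sum_i d_i^2}\) and the tallest stem's height.
- **Wood density** — branch cylinders (dry mass / fresh volume, g cm⁻³)
  aggregated to species means and SDs, with a species → family → removal
  imputation ladder and SD imputation via the site-level SD/mean ratio.
- **Allometry** — per-individual aboveground biomass from the pantropical
  three-variable model AGB = 0.0673 (WD·DBH²·H)^0.976 (kg), lianas via
  AGB = e^(−1.484 + 2.657 ln DBH), coarse roots via BGB = 0.285 DBH^1.993;
  carbon = 50% of biomass; plot stocks in Mg ha⁻¹.
- **Soil carbon** — fixed-depth stock SOC = C·BD·LTH·FE/10 from core bulk
  density, fine-earth fraction and organic-carbon concentration.
- **Uncertainty** — Monte-Carlo propagation of 5% relative errors in height
  and DBH and the taxon SD in wood density (default 1000 iterations).
- **Climate metrics** — precipitation seasonality (BIO15 convention), its
  95%-coverage extreme-month interpretation, and a Pearson r > 0.8
  representative-variable screen.
- **Trend models** — Gamma GLMs (inverse link) of each compartment on
  altitude (linear + quadratic, per site) and on temperature × seasonality
  (pooled), with sequential chi-squared analysis of deviance, explained
  deviance D² = (null − residual)/null, and the quadratic extremum −b/(2c).
- **Synthetic studies** — a generator that plants known belt means, trend
  shapes (unimodal / flat / altitude-invariant), wood-density missingness
  and seasonality, so every stage is testable end to end.

## Worked example

```r
library(tmfcarbon)

res <- run_pipeline(study_config(seed = 1), n_iter = 1000)
subset(res$belts, compartment == "AGC")
#>          site belt compartment   mean     sd n_plots
#> 1  gradient_A  low         AGC  52.26 17.346      10
#> 5  gradient_A  mid         AGC  71.46 27.921      10
#> 9  gradient_A high         AGC  22.57  9.099      10
#> 13 gradient_B  low         AGC 106.53 34.244      10
#> 17 gradient_B  mid         AGC  88.87 23.489      10
#> 21 gradient_B high         AGC 102.05 37.474      10
```

Aboveground carbon (Mg ha⁻¹, mean ± SD over the ten plots of each belt)
peaks at mid altitude at site A and is flat at site B — the planted
patterns. The altitude models recover the unimodal shape:

```r
subset(res$altitude_trends, site == "gradient_A" & response == "agc")
#>              term deviance df  p_value d_squared  estimate std_error
#> 1      altitude_m     1.68  1 3.55e-04     0.158 -7.40e-05  1.36e-05
#> 2 I(altitude_m^2)     5.05  1 5.74e-10     0.475  2.36e-08  4.11e-09

rows <- subset(res$altitude_trends, site == "gradient_A" & response == "agc")
quadratic_peak(rows$estimate[1], rows$estimate[2])
#> [1] 1566.768
#> attr(,"type")
#> [1] "maximum"
```

Each row is one term of the sequential analysis of deviance: its deviance
drop, chi-squared p-value, explained deviance D², and the full-model
coefficient with its standard error on the inverse-link scale. The negative
linear and positive quadratic coefficients place the fitted maximum of
aboveground carbon near 1567 m. Per-plot stocks carry the Monte-Carlo
summaries alongside the point estimates (e.g. plot `A_low_01`: AGC 51.45,
MC mean 51.61 ± 1.55 Mg ha⁻¹).

The numbered drivers under `analysis/` run the same workflow as a
narrative: `01_simulate.R` (study generation), `02_estimate_stocks.R`
(stocks + uncertainty), `03_trend_analysis.R` (deviance tables),
`04_report.R` (recovery against the planted ground truth), writing their
tables under `results/`.

## Layout

```
R/                   package code (census, wood density, allometry, soil,
                     climate, uncertainty, trend models, generator, pipeline)
analysis/            numbered workflow drivers
scripts/acceptance.R headline-quantity recomputation
tests/testthat/      unit, property and acceptance tests
vignettes/           methods vignette (model, assumptions, design choices)
```
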
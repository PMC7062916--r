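---
title: "Methods: carbon stocks and their altitudinal trends in montane forest plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon stocks and their altitudinal trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmfcarbon)
```

## What the package computes

`tmfcarbon` estimates how much carbon a tropical montane forest plot stores
in three compartments — aboveground biomass (AGC), coarse-root belowground
biomass (BGC) and the upper soil layer (SOC) — and models how those stocks
change along altitudinal and climatic gradients. The pipeline is: stem
census → wood-density assignment → per-individual allometry → plot stocks
(with Monte-Carlo measurement-error propagation) → belt summaries and
Gamma-GLM trend models. A synthetic-study generator with known ground truth
makes every stage testable without field data.

## Census conventions

Stems enter the census at a diameter at breast height (DBH, measured at
130 cm) of 2.5 cm and above; smaller diameters are treated as recording
errors by default (`on_small_dbh = "drop"` relaxes this for messy files).
Multi-stemmed individuals are collapsed to one record whose effective DBH is
the root-sum-of-squares of the stem DBHs — the diameter of the circle with
the summed basal area — and whose height is that of the tallest stem.
Heights are visual estimates; the error model below assumes they carry ~5%
relative error. Lianas may lack heights entirely because their allometry
does not use height. Tree ferns are recorded in the census but contribute to
no biomass compartment; their counts are reported so the exclusion is
auditable.

## Wood density

Branch sections are treated as cylinders measured fresh; wood density is
oven-dry mass over fresh volume (g cm^-3), a proxy for stem wood density.
Species values are means over all conspecific samples with the sample SD
(n − 1 denominator; the estimator choice is ours, made for convention).
Missing values walk a deterministic ladder:

1. species mean and SD, when the species was sampled;
2. for single-sample species, SD = mean × the site-level SD/mean ratio
   (computed over species with a defined SD; the reference study sites give
   0.200 and 0.234);
3. otherwise the family mean with SD imputed the same way;
4. otherwise the individual is removed from all biomass computations, and
   counted.

Family means average species means rather than raw samples so that heavily
sampled species do not dominate; `family_wd_table(method = "samples")`
switches this. Whether the SD/mean ratio averages over species or over
samples is genuinely ambiguous in the field literature; the default
averages over species, `sd_mean_ratio(over = "samples")` weights by sample
counts. Densities outside (0.1, 1.5) g cm^-3 warn but pass through — field
data can be extreme, and silent clamping would bias stocks.

## Allometry and stocks

Trees and palms use the three-variable pantropical model
AGB = 0.0673 (WD · DBH² · H)^0.976, lianas the diameter-only power law
AGB = exp(−1.484 + 2.657 ln DBH), and coarse roots
BGB = 0.285 · DBH^1.993. All three return kg per individual with WD in
g cm^-3, DBH in cm and H in m — the unit conventions of their source
calibrations; the package never rescales inputs. Carbon is 50% of biomass
in both compartments. Plot stocks are summed per plot, converted to
Mg ha^-1 over the plot area (0.1 ha by default). Lianas contribute to AGC
only; no published root equation covers them, so they are excluded from BGC
by default (`liana_bgb = TRUE` routes them through the tree root equation
if wanted).

The soil stock uses the fixed-depth convention
SOC = C · BD · LTH · FE / 10 (Mg ha^-1), with C the organic-carbon
concentration (g kg^-1), BD the bulk density from three cores
(total oven-dry mass over total volume), LTH the layer thickness (15 cm
default, the 0–15 cm sampling layer) and FE the fine-earth mass fraction
(< 2 mm, excluding coarse plant residue). No equivalent-soil-mass
correction is applied — fixed depth is the deliberate methodological
choice, matching the dominant practice in SOC accounting. The coarse plant
residue is not subtracted from the core mass in BD (the formula is taken as
printed); its percentage is reported separately.

## Monte-Carlo error propagation

Measurement error is propagated by forward simulation: per iteration, every
individual's height and DBH are redrawn from normal distributions whose SD
is 5% of the estimate (so bigger trees carry bigger absolute errors), and
wood density from the taxon's mean and SD. Non-positive draws are redrawn
(up to 100 rounds, then clamped at 1e-6 with a warning); redrawing rather
than folding avoids upward-biasing small trees. Within an iteration BGC
shares the DBH draws with AGC — one measurement feeds two equations — a
coupling the source description leaves open but that we consider physically
right. Draws are independent across individuals and iterations; no error
correlation structure is imposed, and the soil stock is not perturbed. The
default 1000 iterations reproduce the reference analysis scale; summaries
report the mean, SD and 2.5/97.5% quantiles next to the point estimate
(whether reported values should be point estimates or Monte-Carlo means is
unstated in the source, so the pipeline emits both). Per-plot random
substreams are keyed to the plot id, making summaries independent of row
order and reproducible under a fixed seed.

## Climate metrics

Precipitation seasonality (PS) is the SD of the twelve monthly totals as a
percentage of their mean, using the population SD — the bioclim BIO15
convention (`sd_type = "sample"` switches). Its normal-approximation
reading: 95% of months lie within two SDs of the mean, so the
rainiest-minus-driest difference is about 4 × PS percent of the monthly
mean (`expected_extreme_range()`; z = 1.96 available for the exact
quantile, but the two-sigma rule is the default because the published
interpretation of PS = 50% as a 200% spread implies z = 2 exactly). A
Pearson screen (`correlation_screen()`, threshold |r| > 0.8) formalises
letting one temperature variable represent the correlated
temperature-related bioclim set.

## Trend models

Each compartment (and the total) is modelled with a Gamma GLM — stocks are
positive and right-skewed with roughly constant coefficient of variation.
The canonical inverse link is the default: the sign pattern and ~1e-5
magnitude of published altitude coefficients, with a negative linear and
positive quadratic term placing a mean maximum near 1563 m, are consistent
with the inverse link and raw (uncentred) predictors; a log link and a
centring option exist for numerical work. Altitude models (linear +
quadratic) are fitted per site; climate models (temperature, seasonality,
interaction) pool sites. Significance uses sequential (type-I) analysis of
deviance: each term's deviance drop, scaled by the Pearson dispersion of
the fullest model, against chi-squared — the standard Gamma convention when
only "the chi-squared statistic" is named. Per-term estimates and SEs come
from the full model (the step-wise alternative is defensible but less
conventional). Explained deviance D² = (null − residual)/null decomposes
sequentially, so each row satisfies D² × null deviance = deviance drop. No
multiplicity correction is applied, matching the reference analysis. The
altitude of a quadratic extremum is −b/(2c) on the link scale; under the
inverse link a minimum of the linear predictor is a maximum of the mean.

At the study's size (30 plots per site) the chi-squared convention is
slightly anti-conservative: on pure Gamma draws the quadratic term is
rejected at about 6.7% rather than 5%. This is a property of the test
convention, not of the data; the F-test alternative would cure it but is
not what the convention prescribes.

## The synthetic-study generator

`generate_study()` emulates the reference design: two sites, belts at
800–1100, 1900–2100 and 2700–2900 m, ten 0.1-ha plots per belt, about 320
censused individuals per plot, 4% lianas, 2% tree ferns, 10% multi-stemmed
individuals, and planted wood-density missingness (6.2% family-imputed /
0.6% removed at site A, 8.5% / 1.3% at site B — planted as exact counts so
the imputation report recovers them exactly).

Plot-level expected AGC follows an inverse-link polynomial in altitude:
site A unimodal with its peak at 1563 m and a peak mean of 95 Mg ha^-1
(coefficients on the published scale), site B flat at 86 Mg ha^-1. Expected
BGC is tied to AGC through the belt-level ratio of expected root to shoot
biomass per individual — a consequence of generating both compartments from
the same stems — and with the total-invariance toggle (the default) the
expected SOC is the complement total − AGC − BGC, with totals of 245 and
212 Mg ha^-1. Realised plot stocks are Gamma draws around these
expectations with shape 8 (CV ≈ 0.35, the residual dispersion implied by
the reference deviance tables).

The stem layer is then constructed *to compose* the planted draw: stems are
sampled iid from belt-specific distributions (truncated-exponential DBH
above 2.5 cm with a rate calibrated by moment matching so mean stem count
hits the design value; heights H = a·DBH^0.5 with belt-specific a and 20%
lognormal scatter; species-level lognormal wood density) and kept while
they still fit under the plot's biomass target, so the realised stock
reproduces the planted Gamma draw to within the smallest stem (measured
error +0.1% ± 2.2% per plot). Naive alternatives — a Poisson number of iid
stems, or a renewal stopping rule — leave heavy-tailed stem-level noise on
top of the planted Gamma law and visibly inflate the quadratic false-alarm
rate at the flat site; pinning the totals keeps the plot-level noise law
exactly as planted. The price is that per-plot stem composition is very
mildly conditioned near the target boundary; moments are unbiased to well
under one standard error.

Soils are back-computed so the fixed-depth formula returns the planted SOC
exactly, with belt-trending bulk density (decreasing with altitude, higher
at site A), fine-earth fractions in 0.75–0.95, and pH/C-to-N trends
matching the qualitative gradient (more acid, more organic soils upslope).
Monthly precipitation series are phase-randomised sinusoids affinely
standardised to exact first two moments, so recomputing seasonality returns
the planted value to 1e-9; the construction is infeasible above ~70%
seasonality (a pure sinusoid's non-negativity limit) and errors explicitly
there, well below the theoretical 12-point bound of √11 × 100%. Site
temperature follows a linear lapse fitted to the reference ranges
(21.1→12.2 °C and 23.9→11.5 °C across the gradients); seasonality belts use
32/27/30% (site A) and 33/42/50% (site B), inside the reference ranges.

One global seed drives a per-stage seed sequence, so regeneration is
byte-identical and individual tables can be reproduced independently.

### What the generator does not emulate

No spatial structure within plots, no temporal dynamics, no taxonomic
realism beyond name-level pools, no correlation between soil properties and
stand structure beyond the planted trends, and plot-level noise that is
exactly Gamma by construction. Passing recovery tests therefore shows the
estimation and inference machinery is correct and unbiased under the
planted model — not that real censuses satisfy that model.

## Problem sizes and numerical choices

Tests fit GLMs at n = 5000 (coefficient recovery within 3 SE), n = 200 ×
500 replicates (type-I calibration of the sequential test within
[0.03, 0.07]), and full 60-plot studies over 50 seeds for pattern recovery;
the Monte-Carlo checks use 1e5 iterations on a single tree. Belt-mean
recovery is checked by pooling five replicate studies and requiring the
pooled mean within two single-study standard errors (sd/√10) of the planted
value: a bias test at the two-standard-error scale. A per-cell single-study
check over all 18 site × belt × compartment cells would fail for a perfect
generator about 60% of the time by multiplicity alone, which is why the
pooled form is used. GLM convergence is declared at a relative deviance
change of 1e-8 (at most 100 iterations); rank deficiency is an error naming
the collinear terms, except inside sequential tables where an aliased
(duplicate) term is reported as a zero-deviance, zero-df row. Degenerate
inputs are errors with row context rather than silent repairs, with two
exceptions chosen deliberately: empty plots yield zero biomass stocks with
a warning, and missing coarse-fraction masses yield a fine-earth fraction
of 1 with a loud warning.

## Known limitations

Allometric model error (the residual scatter of the biomass equations
themselves) is not propagated — only measurement error in H, DBH and WD.
SOC carries no measurement uncertainty. The wood-density ladder never
consults external trait databases; an inventory whose species are absent
from the branch-sample table will lean heavily on family means. The
Gamma/inverse-link choice can place fitted means near a pole when
extrapolated far outside the sampled altitude range; `quadratic_peak()`
reports the extremum type so such cases are visible.
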
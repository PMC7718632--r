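---
title: "Models and methods behind phenomicStress"
author: "phenomicStress maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenomicStress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomicStress)
```

phenomicStress analyses factorial heat-by-drought phenomics experiments on
flowering crops: twelve genotypes crossed with two heat levels and two
watering levels in randomized complete blocks, stressed for seven days from
the start of flowering, and phenotyped non-destructively (stomatal
conductance, bud/leaf temperatures, reflectance and fluorescence indices,
gas exchange, three-view imaging) alongside destructive fresh weight and
maturity seed yield. This vignette explains the models the package
implements, the choices made where the design was open, and what the
synthetic-data generator does and does not emulate.

## The FvCB photosynthesis model and the A/Ci fitting engine

Net CO2 assimilation is modelled as the Farquhar–von Caemmerer–Berry (FvCB)
minimum of three limitations, written against intercellular CO2 `Ci`
(infinite mesophyll conductance is assumed throughout, so `Ci` stands in
for chloroplastic CO2 — a documented bias, not an option, because no
mesophyll conductance data exist in this measurement protocol):

* Rubisco-limited: `Ac = Vcmax (Ci - G*) / (Ci + Kc (1 + O / Ko)) - Rd`
* RuBP-regeneration-limited: `Aj = J (Ci - G*) / (4 Ci + 8 G*) - Rd`
* TPU-limited: `Ap = 3 TPU - Rd` (baseline form, without the glycolate
  export extension; the plateau is flat in `Ci`)

with `G*` the CO2 compensation point without day respiration and `Kc`,
`Ko` the Michaelis constants. One subtlety matters at the instrument's low
`Ci` steps (0, 50, 75 umol mol-1): below `G*` the *net* branch curves
cross (`Aj < Ac` there for realistic `J/Vcmax`), so a literal pointwise
minimum of the three net branches would label sub-compensation points as
RuBP-limited and break the physiological ordering. The package therefore
takes the minimum over the *gross* carboxylation rates
`Wc = Vcmax Ci / (Ci + Kc (1 + O/Ko))` and `Wj = J Ci / (4 Ci + 8 G*)` and
forms `A = (1 - G*/Ci) min(Wc, Wj)`, capped by `Ap`. For `Ci >= G*` this
is identical to the naive three-branch minimum (the tests assert equality
there); below `G*` it keeps the Rubisco branch operative, so limitation
states are always contiguous and ordered rubisco → rubp → tpu along
ascending `Ci`. At `Ci = 0` the binding branch is chosen by the smaller
initial slope, the limit of the same rule.

**Kinetic constants.** `G* = 42.75`, `Kc = 404.9` umol mol-1,
`Ko = 278.4` mmol mol-1 at 25 °C — the standard tobacco-derived companions
of this fitting approach — with Arrhenius temperature scaling
`x(T) = x25 exp[(Ha/R)(1/298.15 - 1/(T+273.15))]` and activation energies
(J mol-1) 65,330 (Vcmax), 43,540 (J), 53,100 (TPU), 46,390 (Rd), 37,830
(G*), 79,430 (Kc), 36,380 (Ko). All are user-overridable
(`arrheniusEnergies()`, the `kinetics` argument of `fitAci()`), since gas
exchange protocols rarely state them. Under these defaults Vcmax at a
35 °C leaf is 2.81 times its 23 °C value — which is why heat-stressed
curves show a more-than-doubled fitted Vcmax, and why the package treats
reported Vcmax as *at leaf temperature*, not normalized to 25 °C (the
doubling observed under heat is only consistent with the leaf-temperature
convention; `temperatureAdjust()` converts when the other convention is
wanted).

**Fitting.** `fitAci()` enumerates every contiguous partition of the
ascending-Ci points into (rubisco | rubp | tpu) segments subject to
minimum sizes — rubisco ≥ 3 (to separate Vcmax from Rd), rubp ≥ 2, tpu
optional — and estimates the parameters per partition. Conditional on a
partition and fixed kinetic constants, the model is *linear* in
`(Vcmax, J, TPU, Rd)`, so each candidate is solved exactly by QR least
squares; no iterative optimizer or multi-start is needed, the per-partition
optimum is global, and the non-convexity of the free-assignment problem is
handled by the exhaustive enumeration itself. Partitions whose fitted
parameters' own minimum rule disagrees with the assignment are rejected;
among the survivors the smallest SSE wins, with ties broken toward more
rubisco points, then more rubp points (prefer the earlier limitation).
Day respiration is bounded to [0, 10] umol m-2 s-1; estimates outside are
clamped and refitted with the flag `rdClamped`. A segment that is absent
leaves its parameter `NA` with an identifiability flag — a curve that
never reaches the TPU plateau reports `tpu_identifiable = FALSE` rather
than a fabricated value. On noiseless self-generated 8-point curves the
engine recovers the generating parameters to better than 1e-6 relative
whenever each expressed regime holds enough points; at the instrument
noise level (SD 0.5 umol m-2 s-1) median relative errors across a full
simulated experiment are about 2–3% (Vcmax), below 1% (J), and ~1% (TPU),
medians taken over the curves in which the regime is expressed.
`bruteForceFit()` is a deliberately naive grid-search oracle over the same
admissible model space, used by the tests to bound the engine's SSE.

## Imaging and volumes

Pixels are classified in HSV: hue in [70°, 160°) is plant green, hue in
[40°, 70°) is flower yellow, and anything with saturation below 0.15 is
background regardless of hue; every pixel gets exactly one class, flowers
take precedence over plant. These windows are configuration, not
constants, because the commercial imaging platform's classifier is
unpublished. No morphological cleanup is applied by default so that the
raw classifier can be tested for pixel-exact recovery on synthetic
renders; opening/closing belongs to a pre-processing step the user
controls.

Whole-plant volume follows the three-view product formula of common
phenotyping platforms: `VolWP = top × side0 × side90` on the calibrated
view areas (mm²). As printed, that product is dimensionally mm⁶, not a
volume; the package implements it literally as the default (faithfulness
to the platform convention) and offers `geometric_mean` (square root of
the product) and `cube_root` estimators behind a switch. All three are
monotone transformations of one another, so the correlation, clustering
and ranking analyses downstream are essentially invariant to the choice —
only absolute scales change. Flower volume is computed identically from
the yellow-class areas. A volume is zero exactly when any constituent
view area is zero.

## The factorial mixed-model ANOVA

Each trait × day combination is fitted as
`value ~ genotype * heat * drought + (1 | block)` by REML (lme4), with
sum-to-zero contrasts so that in a balanced design the per-term Wald F
statistics coincide exactly with the classical sequential ANOVA mean
squares. The random block does not consume residual degrees of freedom:
the denominator df is N minus the rank of the fixed-effects design matrix
(12 × 2 × 2 × 3 gives 144 − 48 = 96; the two-block fresh-weight design
gives 48). Fitting block as a fixed factor would instead give 94 — the
REML convention is the one consistent with the residual df this kind of
study reports. When the block variance component is estimated at its zero
boundary the fit reduces *exactly* to the ordinary least-squares ANOVA
without block, and the package falls back to OLS outright when only one
block level is present (seed yield, measured on the third block only).
Significance stars follow the two-threshold convention: `*` for
0.01 < p < 0.05, `**` for p < 0.01; no multiple-testing correction is
applied by default, matching the per-term presentation such tables use (a
Benjamini–Hochberg option would be a one-liner on the output and is left
to the user). Missing cells are tolerated: aliased coefficients are
dropped and F statistics use the adjusted rank-based df. A DAT0 baseline
covariate can be supplied and consumes exactly one residual df; it is off
by default because the design's printed df are consistent with no
covariate. Monte-Carlo calibration under the null (2000 simulations)
puts every fixed term's type-I error between 4.6% and 5.5% at the nominal
5%.

Traits with multiplicative noise can be log-transformed either explicitly
or by an automatic screen (Bartlett's test across the G × H × D cells at
α = 0.05); the transform refuses non-positive values by naming the
offending rows.

## Genotypic correlations and heatmaps

"Genotypic correlation" here means the Pearson correlation of genotype
*means* (over blocks) between two trait_DAT columns within one treatment —
not a pedigree-based genetic correlation. With 12 genotypes the default n
is 12 and two-sided p-values come from `t = r sqrt((n-2)/(1-r²))` on
n − 2 df; at that n the 5% critical |r| is ≈ 0.576, which is worth keeping
in mind when reading starred tables from small panels (published tables in
this area sometimes star |r| ≈ 0.41–0.47, implying a larger effective n
than the genotype count; the package follows the caption convention,
n = genotypes, and exposes a per-plant option through the input table).
Zero-variance columns yield flagged `NA`s, never fabricated values.
Heatmap ordering is average-linkage hierarchical clustering on the
distance 1 − r (signed, not 1 − |r|: strongly negative pairs should sit
apart), with subtrees at every merge oriented by the alphabetically first
column label, making the leaf order invariant to input column permutation.
Heatmaps are rendered straight to pixel rasters on a blue-white-red
diverging scale centred at zero, so identical inputs give byte-identical
PNGs.

## The synthetic-data generator

The generator exists so that every analysis stage has a parameter-recovery
test with known truth; its defaults are the study conditions the package
emulates, chosen once:

* **Design**: 12 genotypes × 2 heat × 2 drought × 3 blocks; in-cabinet
  traits at DAT 1/3/5/7, imaging at DAT 0/3/7, gas exchange at DAT 1/3/7;
  fresh weight at DAT7 on blocks 1–2, seed yield and 100-seed weight at
  maturity on block 3.
* **Water balance**: pots start saturated at 4000 g capacity; each day a
  fixed evapotranspiration loss (655 g at normal temperature, 750 g under
  heat) is removed and a fraction of the previous day's loss is replaced —
  1.0 for well-watered, 0.5 for stressed pots. Published experiments of
  this type report only the SWC endpoints, not pot evapotranspiration, so
  the loss rates are calibrated, not derived: they land the day-7 minima
  near 43% (drought) and 34% (heat + drought), with well-watered pots
  staying above ~80%.
* **Stress driver**: the biologically active signal is the *pre-watering*
  SWC (the previous day's low), mapped to a deficit that is 0 above 60%
  SWC and 1 at/below 30%. Under combined heat and drought an evaporative
  demand offset (8 SWC points) advances the response — the same soil
  dryness bites harder at high vapour-pressure deficit — which reproduces
  the observed pattern that combined stress depresses stomatal conductance
  earlier (by DAT3) than drought alone. Stomatal conductance is baseline
  × a multiplier falling linearly from 1 to a floor of 0.25 across the
  deficit range, taking well-watered plants from ~400 to under
  ~150 mmol m-2 s-1 by DAT7 under combined stress. Bud and leaf
  temperatures rise with the deficit (leaf faster than bud: 3.5 vs 2.0 °C
  at full deficit), generating the heat × drought interactions in the
  derived T1/T2/T3 traits.
* **Photosynthesis truth**: genotype Vcmax at 25 °C ~ N(100, 18) with
  J = 1.7 Vcmax and TPU = J/14; heat sets the 35 °C leaf temperature
  (Arrhenius scaling, ×2.81 on Vcmax) with a genotype-specific heat
  response of SD 10% of the mean response (the G × H interaction; 10%
  keeps the interaction-to-main-effect ratio realistic while every
  genotype's ratio stays above 2); drought multiplies capacities from DAT3
  onward in proportion to the deficit (up to −40%), with a
  genotype-specific sensitivity of SD 15% (the G × D interaction). No
  drought effect is applied at DAT1 — drought takes days to reach the
  photosynthetic machinery in this protocol, and the generator reproduces
  that timing.
* **Outcomes**: fresh weight = 427.9 g × genotype size × treatment decline
  (48.2% D, 11.4% H, 69.4% H+D at DAT7) × 5% noise; seed yield = 3.0 g ×
  decline (40.8% D, 57.3% H and H+D) × genotype deviation. Under the
  heat-stressed treatments the genotype-level seed-yield deviations are
  constructed from the standardized true heat Vcmax at DAT1 plus an
  orthogonalized residual so that the genotypic correlation equals the
  configured target (0.878 by default) *exactly in-sample*; under control
  and drought the deviations are independent. Genotype deviations are
  standardized within the panel (sum-to-zero; multiplicative effects have
  in-sample mean 1) so treatment-level calibration targets are met without
  relying on large-sample averaging over only 12 genotypes. Seed-yield
  variability enters at the genotype level — one plant per genotype
  reaches maturity — so no further measurement noise is added there.
* **Images**: each plant/day is drawn as a green ellipse (area ∝
  biomass^(2/3), so the three-view product volume scales as biomass²) with
  two yellow flower blobs (area ∝ flowering^(2/3)) on a neutral gray
  background, at 150 × 150 px. Pixel noise and hue jitter exist but are
  off by default: the exact-recovery oracle (segmentation equals the
  recorded ground-truth masks pixel for pixel) requires a noiseless mode,
  and that oracle is the foundation of the imaging tests.

**What the generator does not emulate.** Real canopies are not ellipses:
occlusion between views, specular highlights, soil and pot pixels,
illumination drift and classifier confusion are all absent, so pixel-exact
segmentation on synthetic renders says nothing about segmentation accuracy
on real images — it validates the bookkeeping (windows, class precedence,
area and volume arithmetic), not the vision problem. Likewise the additive
trait model with Gaussian noise cannot exhibit the variance heterogeneity,
dropout patterns or temporal autocorrelation of real repeated phenotyping;
passing calibration and power tests on this generator demonstrates that
the statistical machinery is correct under its stated assumptions, not
that those assumptions hold for any particular glasshouse. Vernalization,
photoperiod, pollen biology and pod development are out of scope.

## Numerical and reproducibility choices

* Every generator stage draws from its own sub-seed derived from the one
  configuration seed, so stages are independently reproducible and
  insertion of a new stage does not shift the others' streams.
* CSV outputs serialize doubles with 17 significant digits; re-ingesting a
  run's own exports therefore reproduces the analysis byte for byte, which
  the round-trip tests assert via file hashes. Every CSV carries the seed
  and a configuration hash in a comment header.
* Ties in the min rule go to the earlier limitation (rubisco before rubp
  before tpu); ties in partition SSE (within 1e-9) go to the partition
  with more rubisco, then more rubp points.
* Degenerate inputs are flagged, not patched: constant columns in the
  regression/correlation modules return `NA` with a flag, a water loss
  exceeding the available water is clamped with a flag, and log transforms
  name their offending rows.
* Problem sizes used by the package's validation studies: 432 fitted
  curves for recovery, 100 plant pairs for the heat-doubling check,
  500–1000 null experiments for type-I calibration, 200 experiments for
  interaction power, 200 replicates for the seeded-correlation recovery.
  These sizes put Monte-Carlo standard errors comfortably inside the
  property bands being checked.

## Known limitations

* `Ci ≈ Cc`: fitted Vcmax is biased low relative to a mesophyll-explicit
  analysis; all comparisons within the package are internally consistent
  but absolute values inherit the bias.
* The TPU branch is the flat baseline form; declining high-Ci assimilation
  (glycolate export) would be mis-assigned or left to inflate the SSE.
* The Wald F with REML plug-in variance slightly understates denominator
  uncertainty when the block variance is large and blocks are few; the
  calibration study shows the effect is negligible at this design size.
* Genotypic correlations at n = 12 have wide sampling bands (±0.58 at the
  5% level); the package reports them with their p-values rather than
  pretending more precision than a 12-genotype panel can give.
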
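# phenomicStress

Analysis toolkit for factorial **heat × drought phenomics experiments at
flowering** in crops such as oilseed *Brassica*: a panel of genotypes (G)
is crossed with two temperature levels (H) and two watering levels (D) in
randomized complete blocks, stressed for seven days from first open
flower, and phenotyped non-destructively every few days. The package
covers the full analysis chain for such experiments, plus a
ground-truthed synthetic-data generator so every stage can be validated
without access to raw experimental data.

## What it computes

* **FvCB A/Ci curve fitting** — net assimilation is the
  Farquhar–von Caemmerer–Berry minimum of three limitations,

  ```
  Ac = Vcmax (Ci − Γ*) / (Ci + Kc (1 + O/Ko)) − Rd     (Rubisco)
  Aj = J (Ci − Γ*) / (4 Ci + 8 Γ*) − Rd                (RuBP regeneration)
  Ap = 3 TPU − Rd                                      (triose phosphate use)
  ```

  `fitAci()` estimates **Vcmax, J (ETR), TPU, Rd** from an 8-point CO₂
  response curve by exhaustively enumerating contiguous limitation
  partitions along ascending Ci and solving each by exact least squares,
  with per-point limitation labels, identifiability flags and Arrhenius
  temperature adjustment of the kinetic constants.
* **Three-view imaging** — HSV segmentation of plant (green) and flower
  (yellow) pixels, per-view areas, and the platform-style product volume
  `VolWP = top × side0 × side90`, with alternative estimators.
* **Factorial mixed-model ANOVA** — per trait and day,
  `value ~ G * H * D + (1 | block)` by REML with Wald F tests against the
  fixed-rank residual df (96 for a 12 × 2 × 2 × 3 design; 48 for the
  two-block fresh-weight design), star codes, optional log transform and
  DAT0 covariate.
* **Genotypic correlations** — Pearson correlations of genotype means per
  treatment with t-based p-values, average-linkage clustering on 1 − r,
  and deterministic pixel-rendered heatmaps.
* **Synthetic experiments** — deficit-irrigation water balance (100% /
  50% replacement of the previous day's loss), trait time courses,
  gas-exchange curves, three-view plant images and outcomes (fresh
  weight, seed yield) with known ground truth, seeded G×H / G×D
  interactions and a seeded yield–Vcmax genotypic correlation.

## Worked example

Fit one noisy CO₂-response curve generated from known truth
(Vcmax = 100, J = 140, TPU = 10, Rd = 1.5, noise SD 0.5):

```r
library(phenomicStress)
p  <- FvCBParameters(vcmax = 100, j = 140, tpu = 10, rd = 1.5)
ci <- c(0, 50, 75, 100, 150, 400, 800, 1600)
set.seed(42)
a  <- forwardAci(ci, p) + rnorm(8, 0, 0.5)
fitAci(aciCurve(ci, a, curveId = "demo"))
#> AciFit 'demo' (SSE 5.371)
#> FvCBParameters @ 25.0 C: Vcmax=98.04  J=135.42  TPU=NA  Rd=1.17
#>   limitation: rubisco rubisco rubisco rubisco rubisco rubp rubp rubp
#>   identifiable: vcmax, j
```

Vcmax is recovered within 2%, J within 4%; this noise draw flattens the
single TPU point into the RuBP segment, so TPU is honestly reported as
unidentifiable rather than invented.

Run a complete synthetic study (6 genotypes here for speed) and look at
the factorial ANOVA of fitted Vcmax on day 1:

```r
cfg <- runConfig("out", design = designSpec(genotypes = sprintf("G%02d", 1:6),
                                            inCabinetDays = c(1, 7),
                                            imagingDays = c(0, 7),
                                            gasExchangeDays = c(1, 7)),
                 sim = simulationConfig(seed = 1, imageSize = 100L))
res <- runSyntheticStudy(cfg)
subset(res$anova, trait == "Vcmax" & dat == 1)[, c("term", "df", "F", "p", "stars")]
#>   term df        F        p stars
#>      G  5 1.31e+03 4.51e-50    **
#>      H  1 4.80e+04 1.13e-73    **
#>      D  1 4.38e-03 9.48e-01
#>    GxH  5 5.00e+02 3.69e-40    **
#>    GxD  5 5.73e-01 7.20e-01
#>    HxD  1 1.34e-01 7.16e-01
#>  GxHxD  5 5.84e-01 7.12e-01
res$volumeFwRegression$r
#> [1] 0.975
```

The seeded structure is recovered: heat more than doubles Vcmax at leaf
temperature (huge H effect), genotypes differ in their heat response
(G×H significant), drought has no day-1 effect on photosynthesis by
construction, and image-derived whole-plant volume tracks fresh weight
(r = 0.975). `out/` holds the full report bundle: CSV tables headed by
seed and config hash, clustered correlation heatmaps per treatment, and
a markdown summary of seeded truth vs recovered estimates.

A thin CLI over the same functions lives in `inst/cli/phenomics.R`
(subcommands `simulate`, `run-all`, `ingest`, `fit-aci`, `phenovol`,
`anova`, `gcorr`).

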
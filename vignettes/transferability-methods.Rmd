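---
title: "Assessing temporal transferability of ecological niche models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing temporal transferability of ecological niche models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmtransfer)
```

## The question and the protocol

Correlative ecological niche models (ENMs) are routinely calibrated on
present-day occurrence and climate data and then projected onto future
climate scenarios. Whether such temporal transfers can be trusted is hard
to test directly — the future has not happened. `enmtransfer` implements a
paired-model protocol that turns the past into a test bed: a model is
trained on *historical* occurrences and climate and projected to *modern*
climate (Distribution 1, a simulated "future" prediction whose target
period we can actually observe), and compared against a model trained
directly on *modern* occurrences and climate (Distribution 2). If an
algorithm transfers well, the two predictions should coincide.

Each pair is compared in environmental and geographic space:

* **Schoener's D** on the continuous suitability surfaces, after
  normalizing each map to sum to one: `D = 1 - 0.5 * sum |p - q|`.
* **Stability S**: the percentage of presence cells shared by the two
  binarized distributions.
* **Range-size variation RSV**: the signed percent difference in
  predicted range size, `100 (|A1| - |A2|) / |A2|`; positive values mean
  the projection overestimates.
* A single figure of merit, the Euclidean **distance d** from the
  theoretical-best point `(D, S, RSV) = (1, 100, 0)`:
  `d = sqrt((1 - D)^2 + (100 - S)^2 + RSV^2)`.

The three axes are deliberately mixed on their raw scales (D spans one
unit, S and RSV are percentages). The stability axis therefore dominates
d, and for |RSV| of a few percent the attainable ceiling is just above
100. We keep this convention because it reproduces the empirical
behaviour of the protocol as used in practice: procedures are effectively
ranked by stability first, D second. Distances are classified as low
(d < 60), intermediate (60 ≤ d ≤ 70) and high (d > 70); the lower bound
of the intermediate class is closed.

Procedure differences are tested nonparametrically: a Kruskal–Wallis test
per metric followed by pairwise Mann–Whitney tests with Bonferroni
correction at α = 0.01. These wrap `stats::kruskal.test` and
`stats::wilcox.test` (tie-corrected normal approximation, no continuity
correction); fully tied pairs are reported as p = 1, and the fully
degenerate Kruskal–Wallis case (all values identical) as H = 0, p = 1.

## The synthetic world

Real historical floristic archives are irreplaceable but uncontrolled.
The package instead ships a seeded virtual-species generator so that
every downstream stage is testable against a known truth; real rasters
and occurrence tables can be substituted wherever a generated object is
accepted.

**Climate.** `make_climate_pair()` builds monthly minimum/maximum
temperature and precipitation grids for two periods. Fields are
deterministic latitudinal gradients plus smoothed seeded white noise
(Gaussian blur, width `roughness` cells) — cheap, and spatially
autocorrelated like real climate without geostatistical machinery.
Monthly temperatures follow a sinusoidal seasonal cycle around the
cellwise annual mean; `tmin`/`tmax` are generated as mean ∓ half a
cellwise diurnal range, so `tmax ≥ tmin` holds by construction. The
modern period is the historical one plus an additive drift
(constant and/or north–south gradient offsets per variable) and seeded
cellwise noise; temperature noise perturbs the monthly mean so the
diurnal range is preserved. The default drift — +1 °C on all temperature
layers, −3 mm per month of precipitation, with small cellwise noise — is
a moderate, century-scale climate shift.

**Variables.** `derive_bioclim()` computes the 19 standard bioclimatic
variables plus monthly and annual Thornthwaite potential
evapotranspiration. Quarters are all 12 runs of three consecutive months
with wrap-around (Dec–Jan–Feb counts), ties broken by the first run
scanning January to December — the dominant convention. The Thornthwaite
day-length correction is disabled by default (12-hour days, 30-day
months) so the synthetic grids stay latitude-free; it can be enabled with
per-row latitudes. Two variable sets feed the models, mirroring the two
standard strategies: three a-priori, biologically interpretable layers
(annual mean temperature, annual precipitation, annual PET), or the
first three axes of a PCA over the full standardized layer set. The PCA
set here is built from the 19 bioclimatic layers plus the PET family;
other derived families (aridity and continentality indices) are not
generated natively, but precomputed layers can be appended to a raw
stack before `pca_reduce()`.

**Species.** A virtual species is a multivariate Gaussian suitability
function in environmental space. `make_virtual_species()` centres the
niche on the environment of a random cell and solves the niche breadth
in closed form so that a target fraction of cells (default 3%, range
1–5%) is suitable — emulating stenochorous endemics with narrow,
well-defined ranges. Occurrences are drawn weighted by suitability,
historical samples half the size of modern ones by default, mimicking
sparser historical archives. The generator assumes perfect equilibrium:
occupancy tracks climatic suitability instantly in both periods. Real
species lag climate, interact, and are sampled with spatial bias — none
of which the generator emulates, so passing tests demonstrate correctness
of the machinery and the protocol's discriminative power under ideal
data, not performance on real archives.

## Occurrence cleaning

`clean_occurrences()` chains the cascade applied per species and
variable set, with all counts logged in a `cleaning_report`:

1. **Thinning** to at most one record per cell and period.
2. **Environmental outlier removal**, per period: records whose squared
   Mahalanobis distance from the period centroid exceeds the χ² quantile
   at level 0.975 (configurable; degrees of freedom = number of layers)
   are dropped in a single pass. Periods are screened separately; the
   pooled alternative would let a large modern dataset define
   "normality" for the historical one.
3. **Balancing**: the larger period dataset is reduced to the smaller
   one's size by greedy one-at-a-time deletion, each step removing the
   record whose removal maximizes the Monte Carlo Jaccard overlap of the
   two level-0.975 niche ellipsoids (ties broken by input order). Greedy
   deletion approximates the combinatorial subset search of reference
   implementations deterministically and auditably in O(n²). The
   candidate scan is vectorized through a quadratic-feature matrix
   product over a per-step uniform sample (5000 points by default for
   the ranking; the public `ellipsoid_overlap()` uses 20 000).

Modern records discarded by balancing become the independent modern test
set used by the evaluation metrics. Because the screen works in
environmental space, the `apriori3` and `pca3` pipelines legitimately
retain different record subsets.

## Algorithms

All procedures sit behind one adapter interface (fit → predict in
[0, 1]); the registry (`procedure_registry()`) records each procedure's
contrast design. Native implementations: the BIOCLIM percentile envelope
(midpoint tie convention for the empirical CDF; values strictly outside
the training range score 0), the DOMAIN Gower-similarity scorer, a
Gaussian product-kernel KDE with per-dimension Silverman bandwidth
normalized by the densest training presence, and a logistic GLM on
standardized linear plus quadratic terms fitted by iteratively
reweighted least squares with a 1e-6 ridge. The Maxent slot is an
L1-regularized logistic regression against a large background sample
(`maxent_surrogate`) — it shares Maxent's exponential-family form but is
not Maxent. Remaining slots delegate to standard engines: rpart (CTA),
randomForest (RF), e1071 (SVM), nnet (ANN), mgcv (GAM) and MASS::lda
for the discriminant slot (linear DA standing in for flexible DA). A
MARS engine is not available in this dependency set, so that slot is
absent from the registry. The ensemble combines seven classifier members
by test-AUC-weighted mean, dropping members below AUC 0.7 (falling back
to all members if none pass).

Background samples describe the whole study area and may include
presence cells; pseudoabsence samples exclude exact presence cells.
Fixed-size contrast rules (1000 cells; 10 000 for the Maxent slot) are
capped at the study-area size, which synthetic study areas are often
smaller than.

## Workflow

`run_replicates()` performs the 10-replicate subsampling workflow:
per replicate, a fresh seeded 70/30 train/test split of the presences, a
fresh contrast sample (propagating contrast-sampling uncertainty into
the average), a fit, and a prediction over the study area; the averaged
map is the procedure's suitability surface. `project()` re-evaluates
every replicate's fitted adapter on the other period's stack and
averages — a re-evaluation of models, never a resampling of the map.

Binarization converts suitability `s` to occurrence probability through
a logistic curve `P = plogis((s - beta) / alpha)` whose midpoint `beta`
is solved by root-finding so that the mean of `P` over the study area
equals the species' prevalence (tolerance 1e-6). Prevalence is defined
as cleaned presence cells over valid study-area cells for the
period that trained the model. The steepness `alpha` defaults to 0.05 on
the suitability scale — steep enough that well-separated maps binarize
almost deterministically, shallow enough to keep the probabilistic
reading meaningful. The default mode draws each cell as an independent
Bernoulli trial (honouring the probabilistic conversion); the
`expected_threshold` mode (`P >= 0.5`) is its deterministic limit.
Reproducibility relies on fixed seeds rather than on the deterministic
mode, because a flat suitability surface calibrated to a low prevalence
never reaches `P = 0.5` anywhere — the thresholded limit cannot even
binarize the degenerate control the benchmark depends on.

## Evaluation metrics

Per pair, the package reports training/testing AUC (rank-based; the
negative class is the replicate's contrast sample — the standard
presence-background reading, logged per run), their difference
(overfitting), the 10% omission rate (threshold at the 10th percentile
of training presence scores), a bootstrapped partial ROC (ratio of the
model's partial AUC over the ≤ 5% omission region to the diagonal's
analytic area over the same region, so 1 is uninformative and 2 the
ceiling; 500 iterations, half the test points resampled per iteration,
the ROC evaluated exactly at the resampled test-score thresholds), and
the Continuous Boyce Index for
both the projected and the modern map against the independent modern
test records (101 overlapping windows of width 0.1 × the observed
suitability range; windows with zero expected fraction skipped).

The MOP extrapolation screen compares the modern (projection)
environment with the historical (calibration) one: strict extrapolation
is any variable outside the calibration min–max; the distance surface is
the mean standardized Euclidean distance to the nearest 10% of
calibration cells, scaled by its maximum, with exact calibration
analogues fixed at 0. In a drift-free world strict extrapolation is
exactly zero, which the tests assert.

## Numerical and design choices

* Every stage derives its seed from the master seed and a string path
  (species, variable set, procedure, replicate), so any grid subset
  reruns bit-identically and the full experiment is a pure function of
  (config, seed).
* Binarization root-finding brackets the curve midpoint 50 steepness
  units beyond the observed suitability range; a constant map is
  rejected (no curve can be calibrated on it).
* PCA axes are computed per period independently. Because independently
  derived axes can flip sign, the modern stack is re-oriented by
  positively correlating its loadings with the historical ones
  (`align_to`); projection onto an unaligned cross-period PCA stack is
  refused. Alignment fixes signs only — it cannot undo rotation or the
  re-centring performed by per-period standardization. Consequently a
  spatially uniform climate drift, which standardization removes from
  the layers but which displaces a climate-tracking species' records,
  reappears as a shift of the niche *in PC space*. For narrow-ranged
  species this measurably degrades cross-period projection under `pca3`
  while the same models transfer well under `apriori3` — an instructive,
  real property of the independent-PCA design, not an implementation
  artifact (with zero drift the two variable sets perform alike).
* The distance-to-ideal axes are not rescaled (see above); a
  `denominator` option switches stability between the union-of-presences
  reading (default; consistent with reported magnitudes for
  narrow-ranged species) and the whole-study-area one.

## The default benchmark

The behavioural-recovery benchmark (`benchmark_config()`,
`run_benchmark()`) runs 10 virtual species × 7 genuine procedures
(BIOCLIM, DOMAIN, GLM, KDE, the Maxent surrogate, RF, discriminant
analysis) plus a deliberately degenerate control — a logistic GLM
trained on randomly permuted labels — on the a-priori variable set of a
60 × 60 world with the default moderate drift, 150 modern / 75
historical records per species, without the evaluation-metric layer
(comparison statistics only). Problem sizes were chosen so a full
benchmark seed completes in about a minute on one CPU. The expected
picture, asserted across master seeds by the test suite: several genuine
procedures reach low-to-intermediate distances (d < 70) while the
control — whose two distributions are unrelated noise — lands far into
the high-distance class. This demonstrates that the protocol's summary
statistic separates working transfer from degenerate transfer under
controlled conditions.

## Limitations

* The virtual world is in perfect equilibrium and free of sampling
  bias, detection failure and biotic interactions; absolute metric
  values are optimistic relative to real archives.
* The "independent" modern test set is whatever the balancing step
  discarded. Because greedy balancing removes precisely the records
  that most reduce cross-period niche overlap, the held-out set is
  biased toward the modern niche edge, and the bias grows with the
  discard fraction. With the default historical:modern ratio of 1:2,
  half the modern records are held out and the test-based metrics
  (omission rate, Boyce index) are pessimistic — the Boyce index of the
  modern map against these points can even turn negative, since the
  retained records (and hence the model) concentrate on the
  historically overlapping niche core. This is a property of the
  protocol itself, inherited faithfully from its definition of the test
  set, and worth keeping in mind when reading the evaluation columns.
* Grids are planar; no geographic coordinate systems or reprojection.
  User-supplied CRS metadata is carried through untouched.
* The Maxent surrogate is not Maxent (no feature classes or
  regularization path), linear DA stands in for flexible DA, and MARS
  is absent.
* Only random subsampling is offered for replication (no spatial block
  cross-validation), matching the protocol being studied.
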
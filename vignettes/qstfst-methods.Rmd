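---
title: "Qst–Fst divergence testing: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qst–Fst divergence testing: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qstfst)
```

## The scientific question

Phenotypic differences between geographically distant populations can arise
from genetic drift alone. Invoking divergent selection for a trait — here,
aspects of human nose shape measured from 3D facial surfaces — requires
showing that its between-population differentiation exceeds the neutral
expectation. The neutral yardstick is Fst estimated from genome-wide SNPs:
for a neutrally evolving additive polygenic trait, the quantitative-genetic
differentiation index Qst is expected to match the Fst of neutral markers.
This package implements that comparison end to end: morphometric trait
extraction, covariate-adjusted Qst, Weir–Cockerham θ, a stratified bootstrap
divergence test, heritability-ratio sensitivity analysis, mixed-model
heritability estimation (within- and between-population), and
kinship-corrected phenotype–climate association.

## Qst from phenotypic variance components

For additive genetic variances between ($\sigma^2_{gb}$) and within
($\sigma^2_{gw}$) populations,

$$Q_{st} = \frac{\sigma^2_{gb}}{\sigma^2_{gb} + 2\sigma^2_{gw}}.$$

Additive variances require common-garden designs that are impossible in
humans, so Qst is computed from *phenotypic* components
$\sigma^2_{pb}, \sigma^2_{pw}$ and the heritability ratio $r = c/h^2$,
where $h^2$ is the within-population heritability and $c$ its
between-population analogue:

$$Q_{st}(r) = \frac{r\,\sigma^2_{pb}}{r\,\sigma^2_{pb} + 2\sigma^2_{pw}}.$$

`varianceComponents()` fits a linear model with population as a fixed effect
and sex, age and BMI as covariates, and converts mean squares by the
standard one-way moment equations: with $a$ populations of sizes $n_i$,

$$n_0 = \frac{1}{a-1}\Big(\textstyle\sum_i n_i -
  \frac{\sum_i n_i^2}{\sum_i n_i}\Big),\qquad
  \hat\sigma^2_{pw} = MSW,\qquad
  \hat\sigma^2_{pb} = \frac{MSB - MSW}{n_0}.$$

Choices that were genuinely open, and how they were settled:

* **Marginal MSB.** The population sum of squares is the residual-sum
  difference between the covariate-only and the full model (type-II style),
  not a sequential SS: covariates are nuisance adjustment and should not
  absorb credit by ordering.
* **Clamping.** A negative $\hat\sigma^2_{pb}$ (possible for near-zero
  differentiation) is clamped to 0 with a message; a variance cannot be
  negative and clamping keeps Qst defined. Clamping also applies per
  bootstrap draw.
* **Missing data.** Listwise deletion with the dropped count recorded on
  the result object.
* **Pigmentation scale.** Qst for pigmentation is computed on the raw
  melanin index; the inverse-melanin transform (`inverseMelaninIndex()`,
  closer to normal) is reserved for the likelihood-ratio climate test,
  mirroring the measurement conventions of the field.

## Weir–Cockerham θ

`wcTheta()` computes, per biallelic SNP, the 1984 variance components $a$
(among populations), $b$ (among individuals within populations) and $c$
(within individuals), using observed heterozygote frequencies — no
Hardy–Weinberg assumption — and diploid individuals. Multi-locus θ is the
ratio of sums $\sum a / \sum(a+b+c)$, the standard estimator; per-SNP
negative values are retained because the divergence test resamples from the
realized distribution. SNPs are excluded (and counted) when monomorphic
across all populations, observed in fewer than two populations, or when the
estimator is undefined. The test suite checks the vectorized implementation
against an independent, deliberately literal scalar transcription of the
component formulas, and checks that multi-locus θ on Balding–Nichols
simulations recovers the generating F within ±0.015 at 20,000 SNPs.

## The stratified bootstrap divergence test

`bootstrapQst()` draws pseudo-samples by resampling individuals with
replacement *within population-by-sex strata*, so every pseudo-sample keeps
the exact number of males and females per population, and recomputes the
covariate-adjusted components per draw (10,000 draws by default).
`qstFstTest()` pairs each Qst draw with one per-SNP θ drawn uniformly with
replacement from the genome-wide distribution and reports the empirical
p-value as the share of Qst − Fst differences below zero. A zero share is
reported as "< 1/n_boot" rather than 0.

Two readings of "randomly sampling from the per-SNP Fst distribution" are
possible: one SNP's θ per pseudo-sample, or a full multi-locus θ from a
resampled SNP set. The single-SNP draw is the default (it is the literal
reading and carries the evolutionary variance that makes the neutral test
calibrated); the multi-locus variant is available via
`fstMode = "multilocus"`.

`sensitivityCurve()` re-evaluates every stored draw's components at each
ratio of a $c/h^2$ grid (default 0.01–1.00 in steps of 0.01) — an exact
algebraic rescaling, so no re-resampling is needed — and reports the
critical ratio at which the 2.5% Qst quantile meets the 97.5% quantile of
the same Fst draws used in the test. Curves that never cross are flagged
as "> grid maximum". `bonferroniReport()` applies a strict
$p < \alpha/n_{tests}$ rule (0.05/7 ≈ 0.0071 for the seven-trait nose-shape
family).

## Heritability: $h^2_g$ and $h^2_y$ (an estimator of $c$)

`grm()` builds the standardized genetic relationship matrix
$K_{ij} = \frac{1}{M}\sum_s \frac{(x_{si}-2p_s)(x_{sj}-2p_s)}{2p_s(1-p_s)}$
with mean imputation of missing dosages and monomorphic SNPs skipped.
`ancestryGrm()` applies the same averaging to local-ancestry dosages of an
admixed cohort but standardizes each SNP by its empirical mean and SD: the
two ancestry copies of one individual share that individual's global
ancestry and are therefore positively correlated, so the binomial
(Hardy–Weinberg) variance would mis-scale the matrix. Variance explained by
local ancestry ($h^2_y$) captures only between-parental-population genetic
variation and is interpreted as an estimate of $c$.

`remlH2()` fits the single-component model
$y = X\beta + g + e,\; g \sim N(0, K\sigma^2_g),\; e \sim N(0, I\sigma^2_e)$
by REML after one eigendecomposition of $K$, maximizing the profiled
likelihood over $h^2 \in [0,1]$ with Brent's method (tolerance $10^{-6}$)
and taking the SE from the numerical curvature of the profile. Numerical
choices: eigenvalues below $10^{-10}$ of the maximum are snapped to exact
zero (a centred GRM is always singular in the constant direction), which
makes the profiled likelihood $-\infty$ at the $h^2 = 1$ boundary and keeps
the optimizer off the singular point; genuinely negative eigenvalues are
clipped with a warning; boundary estimates are flagged. `topPCs()` returns
root-eigenvalue-scaled eigenvectors with a deterministic sign convention
(largest-magnitude loading positive).

## Phenotype–climate association

Humidity is derived from long-term temperature and vapor pressure with
standard forms: Magnus saturation vapor pressure
$e_s(T) = 6.1094\,\exp(17.625\,T/(T+243.04))$ hPa, relative humidity
$100\,e/e_s(T)$ (capped at 100), and absolute humidity
$216.7\,e/(T+273.15)$ g/m³ (ideal-gas water-vapor density). The upstream
derivation that produced the study's climate grids is not spelled out in
the source material; these are the standard meteorological stand-ins and
are documented as such. `ancestralClimate()` averages parental-birthplace
values, falling back to the single available parent.

`kinshipLmmSlope()` fits $y = X\beta + \varepsilon$ with
$\mathrm{Var}(\varepsilon) = \sigma^2_g K + \sigma^2_e I$ by **maximum
likelihood** — not REML, because the likelihood-ratio test compares models
with different fixed effects, and REML likelihoods are not comparable
across fixed-effect structures. The covariance model as literally printed
(a pure kinship covariance with no iid term) is typically singular; the
default therefore includes the residual component, matching what standard
mixed-model software actually fits, and the strict pure-kinship GLS is
available via `residual = FALSE`. Slope, SE and t come from GLS at the ML
variance ratio; the LRT p-value is from $\chi^2_1$. The eigen-rotated
likelihood core is the same code path used by `remlH2()`.
`leaveOnePopulationOut()` refits after dropping each population and flags
which 95% slope intervals overlap zero. Sex is excluded as a covariate by
default because the climate-analysis design is single-sex; it is an
argument, not a hard-coded rule.

## Morphometrics

`procrustesAlign()` performs generalized Procrustes superimposition with
translation and rotation removed; **scale is deliberately not removed** by
default because the traits are absolute distances (mm) and areas (mm²) —
superimposition serves orientation and symmetry only. Since rigid
superimposition preserves Euclidean distances, computing the five linear
distances before or after alignment is equivalent; the package computes
them directly from landmarks. Reflection for symmetrization negates x and
swaps left/right labels (the map is checked to be an involution), and
`symmetrizeConfig()` averages original and relabeled reflection, which
provably places midline landmarks on the symmetry plane. Region areas are
sums of half cross-product norms over the triangles fully inside a vertex
mask; the nostril-area trait averages the left and right regions. Replicate
averaging follows the measurement protocol: within observer first, then
across observers. `iccReliability()` uses the two-way model (observer
fixed, subject random, via `nlme::lme`) and returns
$\sigma^2_{subj}/(\sigma^2_{subj}+\sigma^2_{err})$; a degenerate fit with
numerically zero replicate noise returns ICC = 1 by definition. The melanin
index is $100\log_{10}(1/\text{reflectance})$ with reflectance as a
fraction; percent-scale inputs (> 1) are detected and rescaled with a
warning, since observed index magnitudes (~26–60) are only consistent with
the fractional form.

## What the synthetic-data generator emulates — and what it does not

`simulateGenotypes()` draws population allele frequencies from the
Balding–Nichols Beta model around a uniform ancestral frequency, with the
drift parameter F interpreted as the target Weir–Cockerham θ, and samples
Hardy–Weinberg dosages within populations. Defaults mirror the study
design: four populations of 40/236/127/73 individuals and a 20,000-SNP
panel standing in for an LD-pruned array (independent SNPs at desk scale).

`simulatePhenotype()` composes population genetic means, genotype-built
within-population additive deviations (centred within population), and
Gaussian homoscedastic environmental noise scaled so the within- and
between-population heritabilities equal `h2` and `c`. Between-population
effects have two modes, fixed at design time:

* `"exact"` (default): realized effects are scaled so the between-population
  variance matches `sigma2gb` exactly, against the size-weighted ANOVA
  estimand (so unbalanced cohorts are on target too), with the
  environmental population effects orthogonalized against the genetic ones
  — with only a handful of populations their chance covariance would
  otherwise dominate. This gives parameter-recovery tests their meaning.
* `"drift"`: effects are drawn $N(0, \sigma^2_{gb})$. The evolutionary
  sampling variance this injects *is* the null hypothesis of the
  divergence test, so the type-I calibration uses this mode.

With `h2 = 0` the additive deviation is omitted and the within-population
variance is purely environmental, of magnitude `sigma2gw`.
Sex is Bernoulli(0.5), age Uniform(18, 40), BMI Normal(24, 3) — arbitrary
but fixed. `simulateAdmixedCohort()` lays local ancestry down in
geometric-length tracts (a two-state Markov chain per haplotype whose
stationary frequency is the individual's Beta-distributed global ancestry;
concentration 8 gives a Cape-Verde-like spread around mean 0.6), draws
genotypes from parental frequencies drifted apart by `parentalFst` = 0.15,
and builds the trait from standardized local-ancestry dosages so the
variance explained equals `hy2Target`. `simulateLandmarks()` perturbs an
anatomically plausible seven-landmark template (between-subject SD 1.5 mm
per coordinate) and adds observer placement noise; at the distance level a
placement SD of one third the subject SD yields a 9:1 variance ratio, i.e.
ICC ≈ 0.9. `simulateClimate()` adds within-population noise to
population-level temperature / vapor pressure / UVB means chosen to
resemble the four study regions.

Not emulated: linkage disequilibrium and realistic haplotype structure,
mutation, X-linked variation, genotyping error, platform batch effects,
non-Gaussian environments, and assortative mating. Passing
parameter-recovery tests therefore shows the estimators are correct under
the stated model, not that real data meet the model's assumptions.

## Problem sizes used in the checks

The routine test suite runs at reduced scale chosen to keep each property
informative: 20,000 SNPs for F-recovery, 200 replicate traits for the
type-I calibration of the divergence test (1,000 bootstrap draws each),
REML recovery at n = 1,000 / M = 5,000 (genotype) and n = 400 / M = 2,000
(local ancestry), climate fits at n = 140 with 200 permutations, and ICC at
200 subjects. The full 10,000-draw bootstrap is exercised once on the
study-sized synthetic cohort by the acceptance script.

## Reconstruction from published summary statistics

The study's individual-level records are not publicly archived. The
package bundles the published per-population-by-sex summary table
(`inst/extdata/cohort_summary_stats.tsv`) and `summaryStatCohort()` builds
a synthetic individual-level cohort realizing those cell means and SDs
exactly (deterministic scaled z-scores — cell statistics are sufficient for
any linear-model ANOVA, so the sex-adjusted components are exact).
`summaryStatQst()` then yields sex-adjusted Qst per trait. What this cannot
do is age/BMI adjustment, which requires the real records: traits whose
published Qst depended materially on those covariates will deviate from
the sex-only-adjusted reconstruction, and the acceptance checks make that
deviation visible rather than hiding it.

## Known limitations

* Qst here is univariate; shape-space (multivariate) Qst is out of scope.
* The REML machinery is single-component; no multi-component or bivariate
  GREML.
* The bootstrap p-value is empirical; with n_boot draws its resolution is
  1/n_boot.
* Critical-ratio detection is grid-based (one-grid-step resolution).
* Mesh support covers ASCII OBJ/PLY with vertex-index region masks;
  dense-correspondence registration of raw scans is upstream of this
  package.
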
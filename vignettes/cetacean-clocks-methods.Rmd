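---
title: "Methods: multi-species epigenetic clocks and meta-EWAS"
author: "cetClocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-species epigenetic clocks and meta-EWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the models, the tunable parameters and their defaults, what the
synthetic data emulate (and what they do not), and the numerical and design
choices made where more than one defensible option existed.

## The clock model

An epigenetic clock here is a sparse linear model on CpG beta values
$\beta_{j} \in [0,1]$ predicting a transformed chronological age:

$$ f(\widehat{age}) = b_0 + \sum_{j \in S} w_j \beta_j $$

fitted by elastic-net regression with the mixing parameter fixed at
$\alpha = 0.5$, midway between ridge and lasso. $\alpha$ is a modelling
commitment, not a tuned quantity: the ridge component stabilizes the many
correlated age-tracking CpGs, the lasso component produces the sparse CpG
set $S$. The penalty $\lambda$ is the only data-chosen hyperparameter,
selected by internal 10-fold cross-validation minimizing mean squared
error on the transformed-age scale (`lambdaRule = "min"`; the 1-SE rule is
available but not the default, matching common usage in the clock
literature). Internal CV folds are assigned by a seeded shuffle,
stratified by species whenever a species contributes at least two
samples, so species are balanced across folds and fits are reproducible.

Numerical choices worth knowing about:

- **The regularization path is laid out explicitly**, from the
  data-derived $\lambda_{max}$ down to $\lambda_{max} \times 10^{-5}$
  (`lambdaMinRatio`). The underlying coordinate-descent implementation
  otherwise stops the path early once deviance gains become small; with
  strong, nearly noiseless age signal that truncation can leave the
  CV-optimal $\lambda$ at the path boundary and bias predictions
  noticeably. An explicit path lets the CV minimum be interior.
- **Coefficients are reported unstandardized** (on the beta scale);
  predictors are standardized internally by the fitting routine.
- **Missing probe values** are mean-imputed at training time, and the
  training means of the selected CpGs travel with the model so prediction
  can impute the same way. A sample missing more than 20% of a model's
  CpGs (configurable) is refused rather than silently imputed.
- **Internal CV error switches to ungrouped averaging** when folds fall
  below 3 observations (small training sets); the fitting code accepts
  that fallback silently since it is the correct behaviour there.
- **Negative predicted ages are reported as-is.** Flooring at zero would
  shrink residual metrics for young animals and bias accuracy summaries.

## The age transform

Ages enter the regression through a strictly increasing "log-like"
transform, compressing old ages because wildlife panels are heavily
skewed toward young animals. Two families are provided behind the
`AgeTransform` class:

- `log1p` (default): $f(x) = \log(x + c)$, offset $c = 1$ year so
  $f(0) = 0$.
- `loglinear`: $f(x) = \log\frac{x+c}{k+c}$ below an adult-age knot $k$
  and $f(x) = \frac{x-k}{k+c}$ above it; the two branches match in value
  and first derivative at the knot. The knot may be a single value or
  per-species (named vector), since species' ages at maturity differ
  widely.

The exact transform used in any given wildlife-clock publication varies
(and is often only in supplements); isolating it behind `AgeTransform`
makes the choice swappable without touching the clock code. Both
families invert exactly (round-trip identity to $10^{-12}$ over the
0–139-year range is asserted in the tests), and all accuracy metrics are
computed **after** inverse transformation, in years, so they are
invariant to the transform used internally.

## Cross-validation and accuracy metrics

- **LOO CV** refits the entire pipeline once per sample (the left-out
  sample never contributes to fold assignment, standardization, penalty
  selection or coefficients) and reports the Pearson correlation between
  predicted and observed ages plus the median absolute error in years.
  The penalty is re-selected within every fold — the honest variant; a
  global-$\lambda$ shortcut would leak information across folds.
- **LOSO CV** refits once per species and predicts all of that species'
  samples. Because species differ in sample count and age range, the
  summary is the repeated-measures correlation (below) and the median
  across species of per-species median absolute errors, so a large or
  easy species cannot dominate.
- **Repeated-measures correlation** is the common within-group
  correlation from the ANCOVA formulation: center predicted and observed
  ages on species means, then correlate the centered values, taking the
  sign of the common within-species slope. With one group it reduces to
  the ordinary Pearson correlation; groups contributing a single sample
  are excluded (with a warning) since they carry no within-group
  information.

"Median MAE" is deliberately read two ways, matching how the two schemes
are reported in this literature: per-sample absolute residuals →
median across samples (LOO), and per-species medians → median across
species (LOSO).

## The meta-EWAS

Associations are screened per species × tissue stratum, eligible at
$n \ge 15$:

- **Age**: Pearson correlation $r$ per CpG;
  $t = r\sqrt{n-2}/\sqrt{1-r^2}$; two-sided p from the t-distribution;
  $z = \mathrm{sign}(r)\,\Phi^{-1}(1 - p/2)$.
- **Sex**: OLS of each CpG on a female indicator and age
  (`lm(CpG ~ Female + Age)`); the female coefficient's t (df $= n-3$)
  maps to z the same way. Female = 1, male = 0, unknown sex excluded;
  positive z means higher methylation in females. Single-sex or
  rank-deficient strata are skipped with a notice.

**Everything p-valued is kept in natural-log space.** Meta-analyses over
many strata produce p-values on the $10^{-100}$ scale; `pt(..., log.p)`
and `qnorm(..., log.p)` avoid underflow and saturation entirely (the
tests exercise $|z| = 23$, i.e. $p \approx 10^{-117}$).

The combination is the unweighted Stouffer method,
$z_{meta} = \sum_i z_i / \sqrt{k}$, applied in two steps for the
all-tissue and sex analyses: tissues within a species first, then
species. A species with one eligible stratum passes its z through
unchanged. Tissue-restricted analyses (blood-only, skin-only) are a
single step across that tissue's species strata. Per-CpG $k$ counts only
strata where the statistic existed; a zero-variance CpG in one stratum
reduces $k$ rather than being imputed as $z = 0$, which would bias toward
the null. The z-from-two-sided-p-plus-sign convention (rather than
one-sided z) matches the screening convention of the WGCNA-style tools
this analysis style descends from.

Top CpG lists (default 1000 per direction) are ordered by $|z_{meta}|$
with deterministic tie-breaks (log p, then CpG id). The genome-wide
reference line is the Bonferroni threshold $\alpha / n_{tests}$; for the
20,150-CpG mappable universe that is $2.48 \times 10^{-6}$, and the
number actually tested in a run is reported alongside.

## Enrichment analyses

All enrichment tests are exact one-sided hypergeometric tests of a
foreground CpG set against a background universe (the array CpGs with map
positions; sizes are recorded per row). Fold change is
$FC = k/(nK/N)$; enrichment means $FC > 1$ (upper tail), depletion
$FC < 1$ (lower tail); rankings use the enrichment tail. The odds ratio
applies the Haldane–Anscombe 0.5 correction only when a contingency cell
is zero, so displayed ORs are finite while exact p-values are untouched.

Interval conventions: CpG positions are 1-based single-base (manifest
convention) and BED input is 0-based half-open; a CpG at position $p$
occupies the half-open interval $[p-1, p)$, expanded by a buffer $b$ on
both sides where applicable. The TF analysis uses $b = 200$ bp (around
the CpG, per the method it reimplements), chromatin states use point
overlap ($b = 0$) since the source method states no buffer there; both
are arguments.

- **PRC annotation**: a CpG is PRC1/PRC2-bound iff it overlaps peaks of
  at least two *distinct* member TFs of that complex (PRC1: RING1, RNF2,
  BMI1; PRC2: EED, SUZ12, EZH2).
- **TF enrichment**: TFs with member/background ratio $K/N > 0.5$ are
  dropped unless they are OCT4, SOX2, KLF4 or MYC; among a TF's multiple
  datasets the row with the median enrichment p is reported — for an even
  count, the more significant of the two middle rows, so a concrete
  dataset's full row (not an interpolation) is always reported.
- **GREAT-style gene association**: strand-aware basal domains (5 kb
  upstream, 1 kb downstream of the TSS), extended up to 50 kb per flank
  but stopping at the nearest neighboring gene's basal boundary and at
  the chromosome start. Gene sets are reported only with ≥ 3
  foreground-overlapping genes and enrichment p < 0.001. The test unit is
  the CpG (region-based), against the array background, to avoid
  gene-size and probe-density bias.

## The synthetic data generator

`generatePanel` emulates the structure of a pooled, consortium-scale
cetacean methylation panel: by default 13 species with maximum lifespans
from 20 to 139 years, blood and skin sampled at ~42 samples per stratum
(~1090 samples), and an array-scale universe of 37,000 CpGs. Ages are
uniform on [0, lifespan] by default; `agePower > 1` skews sampling toward
young animals, the shape real panels have.

Planted age CpGs follow
$\beta = \mathrm{squash}(b_{0,s} + m\, f(age)) + \varepsilon$: effects
are **linear on the transformed-age scale**, so the elastic net on
transformed age is correctly specified and parameter recovery is a sharp
test (placing effects on raw age instead turns the same fixture into a
misspecification test — `transform` is a scenario field). Slope
magnitudes are drawn near 0.08 beta units per transformed-age unit
(s.d. 0.02), signs balanced; species-specific baselines shift by
N(0, 0.02); `sharedFraction` controls whether slopes transfer across
species (1 = fully shared, the regime where a left-out species is
predictable; 0 = per-species redrawn slopes, the regime where LOSO must
fail). Sex CpGs add a signed female effect of 0.08–0.2 beta units and
are placed on a designated sex chromosome label (`chrX_sim`) so
localization of sex associations is testable. Gaussian noise
(s.d. 0.03, an array-realistic scale) is added and values clamped to
[0, 1]; planted means are kept inside [0.001, 0.999] so clamping is rare
and monotonicity survives.

What the generator does **not** emulate: probe chemistry and detection
failure patterns, batch and study-of-origin effects, cross-hybridization,
the real array's per-CpG variance heterogeneity, and right-skewed,
census-like age distributions (beyond the `agePower` knob). Passing
recovery tests on these fixtures therefore demonstrates correctness of
the estimators under their stated model, not real-data accuracy — real
clock accuracies depend on data this package does not ship.

`generateAnnotationFixture` emits mock chromatin-state, TF-peak and
PRC-member region sets in which planted positive-age CpGs are included at
`enrichmentFactor` times a background rate (default 0.08). With 2000
CpGs of which ~100 are planted positive, a factor-5 fixture yields an
observable fold change near $5/(1 + 4 \cdot 0.05) \approx 4.2$ — the
foreground's own membership inflates the background rate, which is why
recovered FC sits below the nominal factor.

## Problem sizes and determinism

The recovery scenario used by the test-suite and the acceptance script is
6 species × 2 tissues × 40 samples (480 samples), 2000 CpGs with 200
planted age CpGs and 50 sex CpGs — large enough that stratum EWAS
(n = 40 per stratum), two-step combination (12 strata), and the elastic
net (480 × 2000) all operate in their intended regime, while a full LOO
pass (480 refits with per-fold penalty selection) stays in the minutes
range on one core. Type-I calibration uses a separate null scenario
(one stratum, n = 100, 2000 CpGs, nothing planted).

Every stochastic step takes an explicit integer seed; simulation, fold
assignment and fixtures draw from named substreams derived from the one
config seed, and RNG state is always restored, so identical configs give
byte-identical outputs.

## Known limitations

- LOO CV refits the full path per sample: quadratic-ish cost in samples;
  for panels in the thousands a grouped k-fold scheme (not provided)
  would be the pragmatic substitute.
- The per-stratum age EWAS assumes an (approximately) linear
  beta–transformed-age relation within each stratum; strongly nonlinear
  trajectories will be under-ranked.
- The sex EWAS handles missing betas CpG-by-CpG (pairwise complete); with
  heavy missingness the effective design can become rank-deficient per
  CpG and those CpGs are dropped silently from the stratum.
- `MethylExperiment` keeps the full dense beta matrix in memory;
  array-scale data (37k CpGs × thousands of samples) fits comfortably,
  whole-genome bisulfite matrices would not.
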
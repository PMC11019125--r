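---
title: "Methods: elastic-net age clocks from chromatin accessibility and DNA methylation"
author: "epiAgeClock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elastic-net age clocks from chromatin accessibility and DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiAgeClock)
```

# Overview

`epiAgeClock` reimplements, as a tested and reusable pipeline, the analysis
behind a companion-dog epigenetic-clock study design: peripheral blood
mononuclear cells from a cohort of dogs are profiled for chromatin
accessibility (ATAC-seq peak counts) and CpG methylation (RRBS
methylated/unmethylated counts), each feature is screened for association
with age, and penalized regression clocks predict chronological age from
each data type alone and combined. Because the study's raw sequencing data
live in external archives, the package ships a synthetic-cohort generator
with known ground truth; every downstream stage is exercised and judged
against that stated world.

The pipeline stages are:

1. **Simulation** (`simulateDataset()`): cohort metadata, methylation
   counts, accessibility counts, a chromatin-state segmentation and a gene
   annotation, plus a ground-truth manifest.
2. **Feature processing** (`processAtac()`, `processMethylation()`):
   summit-distance peak merging, coverage/contig filters, RPKM and
   log/center/scale for accessibility; fraction computation, depth and
   intermediate-methylation filters, center/scale for methylation.
3. **Association** (`fitFeatureAgeModels()`): per-feature OLS of the form
   *feature ~ age + weight + sex + exercise + cell.CD8 + cell.DN*, BH
   adjustment, and direction classification.
4. **Annotation** (`assignState()`, `stateEnrichment()`, `nearestGene()`):
   chromatin-state assignment by maximal overlap, Fisher's exact
   enrichment of states among age-increasing vs age-decreasing peaks, and
   nearest-gene mapping with cross-clock overlap.
5. **Clocks** (`loocvClock()`): elastic-net regression fit by our own
   cyclic coordinate descent, with inner K-fold cross-validation for the
   penalty and an outer manual leave-one-out loop, for the data types
   `atac`, `dnam` and `combined`, each offered "meta features" (all
   cell-type proportions and the ordinal breed-weight category).
6. **Evaluation** (`evaluatePredictions()`, `residualAge()`): predicted vs
   observed regression R², raw RMSE, breed-size strata, residual age (age
   acceleration) and its association with breed weight, and cross-clock
   residual correlations.

# The model

The clock solves, for ages $y_i$ and standardized predictor rows $x_i$,

$$\min_{\beta_0,\beta}\;\frac{1}{2N}\sum_{i=1}^N\left(y_i-\beta_0-x_i^T\beta\right)^2
+\lambda\left[\frac{1-\alpha}{2}\lVert\beta\rVert_2^2+\alpha\lVert\beta\rVert_1\right],$$

with $\alpha = 0.5$ (an equal ridge/lasso blend) and $\lambda$ selected by
cross-validation. The solver is cyclic coordinate descent with
soft-thresholding: for column $j$ with $v_j = \tfrac1N\sum_i x_{ij}^2$ and
partial residual correlation
$\rho_j = \tfrac1N\sum_i x_{ij}(r_i + x_{ij}\beta_j)$,

$$\beta_j \leftarrow \frac{S(\rho_j,\lambda\alpha)}{v_j + \lambda(1-\alpha)},
\qquad S(z,\gamma)=\operatorname{sign}(z)\max(|z|-\gamma,0).$$

The path solver adds sequential strong-rule screening with a full KKT pass
per $\lambda$, so excluded coordinates are provably zero at the returned
solution. Every returned fit carries a KKT certificate (`kktCheck()`)
at tolerance $10^{-6}\,\mathrm{sd}(y)$, and the objective is
non-increasing across sweeps (exposed via `trace = TRUE`). At $\lambda = 0$
the solver reproduces OLS; at $\alpha = 0$ it reproduces the closed-form
ridge solution under the $1/(2N)$ convention; at
$\lambda \ge \lambda_{max} = \max_j |x_j^T(y-\bar y)|/(N\alpha)$ it returns
the exact null model. glmnet is used in the test suite as an independent
reference (note glmnet internally standardizes the response to unit
$1/n$-variance, so comparisons hand it a unit-variance response), never as
the implementation.

## Nested cross-validation

The outer loop is a "manual" leave-one-out: for each of the $N$ samples,
`cvSelectLambda()` runs seeded K-fold cross-validation (default $k = 10$)
on the remaining $N-1$ samples over a log-spaced path of 100 penalties from
$\lambda_{max}$ down to $10^{-2}\lambda_{max}$ (the $N \le p$ convention;
$10^{-3}$ when $N > p$), picks the $\lambda$ minimizing mean held-out
squared error (ties to the heavier penalty; a one-standard-error rule is
available via `rule = "1se"`), refits at that $\lambda$, and predicts the
held-out sample. This yields exactly $N$ final models, $N$ held-out
predictions, and per-feature selection frequencies in $0..N$.

## Standardization order and leakage

By default (`scaling = "global"`) features are centered and scaled once on
the full cohort *before* the leave-one-out loop — the order stated by the
emulated study ("centered and scaled prior to model building"). This leaks
the held-out sample's location and scale into training. The leakage-free
variant (`scaling = "fold"`) restandardizes each training fold and applies
the fold's statistics to the held-out row; the null-calibration tests use
it, and the honest-performance comparison is one flag away.

# Design choices on points the emulated design leaves open

* **Merge semantics.** "Summits closer than 500 bp merge" is applied as
  single-linkage chaining (transitively closed), which is deterministic
  and idempotent; the merged summit is the midpoint of the merged span and
  count rows are summed. The distance cut is strict (`< 500`, so 500 does
  not merge).
* **Filters.** Median peak coverage is a strict `> 20`; CpG mean depth is
  an inclusive `>= 5`; the median-methylation band `[0.1, 0.9]` is
  inclusive at both ends. Mitochondrial/scaffold contigs are recognized by
  a configurable name pattern (`chrM`/`MT`/`scaffold`/`chrUn`/`random`).
* **Normalization.** RPKM divides by peak width (kb) and per-sample
  library size (millions); the library size is the column sum of the raw
  count matrix, since genome-wide mapped totals do not exist
  post-quantification. Accessibility is then `log2(x + 1)`; methylation
  stays on the fraction (beta) scale with no transform. Scaling uses the
  sample SD (n−1).
* **Missing methylation cells** (zero depth) surviving the filters are
  imputed with the site's across-sample mean fraction — the penalized
  regression needs complete data.
* **Multiple testing.** The step-up Benjamini–Hochberg procedure is the
  default (the standard Benjamini & Hochberg 1995 procedure); the
  Benjamini–Yekutieli variant is available by flag. "Age-associated" means
  BH q < 0.05.
* **Age-model covariates.** Exercise enters as unordered dummy-coded
  categories; sex as a single indicator; the two age-associated T-cell
  proportions enter as numeric covariates. Sex is *not* a clock predictor
  (the meta-feature set is the cell panel plus breed-weight category,
  coded ordinally 1/2/3 and standardized like any column); no column is
  exempted from the penalty.
* **State assignment** uses maximal base-pair overlap (ties to the earlier
  interval); a midpoint-containment mode exists. **Nearest genes** are
  measured to the gene body with ties broken toward the smaller gene
  start, then the lexicographically smaller name; a TSS mode exists.
  Distances are computed directly per chromosome because
  `distanceToNearest(select = "all")` can drop equal-distance candidates
  on the opposite side of a feature, which would defeat the deterministic
  tie-break.
* **Fisher's exact test** is the probability-ordering two-sided
  definition: sum the hypergeometric probabilities of all tables with the
  observed margins that are no more probable than the observed table
  (relative tolerance $10^{-7}$ against floating-point ties). The odds
  ratio is the sample OR with a 0.5 continuity correction only when a
  zero cell occurs.

# The synthetic world

The generator's defaults restate the study design: 71 dogs with
owner-reported integer ages uniform on 1–16 years (owner reports give
whole years and only the range; uniformity is an assumption exposed in the
config), a 31-type flow panel on the percent-of-parent-gate scale (so the
types are not a simplex), two designated T-cell populations drifting
upward by 0.8 percentage points/yr, and an exercise-vigor category whose
latent score declines with age. Breed mean weights come from a fixed
breed table spanning the size classes; the small/medium/large cut-offs
(10 and 25 kg) are arbitrary but explicit and configurable, as no standard
definition of the size classes exists.

Methylation counts are binomial over negative-binomial depths (mean 30
reads, per-site dispersion log-normal), with
$\mathrm{logit}(p_{ij}) = b_i + s_i\,\mathrm{age}_j$; 5% of sites carry
slopes drawn $N(0, 0.15)$ (logit/yr), and 5% are constitutively hyper- or
hypo-methylated to exercise the median filter. Accessibility counts are
negative binomial with
$\log\mu_{ij} = b_i + s_i\,\mathrm{age}_j + \log \ell_j$, slopes
$N(0, 0.05)$ (log/yr) on 5% of peaks, library factors spanning at least
two-fold, a low-coverage subset, and decoy features on `chrM`/`scaffold_*`
contigs. Baselines are anchored at the mid-cohort age so an age slope does
not itself push a feature out of the filter bands.

**What a green test does and does not establish.** The generator draws
independent features with linear age effects and no batch structure,
breed genetic structure, cell-composition confounding beyond the two
designed populations, or shared variation across neighboring sites. Under
this world the clocks are far *more* accurate (adjusted R² ≈ 0.97–0.99 at
the default effect sizes) than any real cohort — real epigenomes carry
correlated noise the simulation deliberately omits. Green tests therefore
establish correctness of the machinery (solver optimality, calibration
under the null, recovery of planted signal, determinism), not a forecast
of real-data performance.

# Evaluation conventions

R² is taken from the OLS regression of predicted on observed age (so it
is invariant to affine miscalibration of the clock), adjusted with the
single-predictor correction $(n-1)/(n-2)$; RMSE is computed on the raw
prediction errors (the regression-residual variant is reported alongside
as `rmse_model`). Residual age is the signed residual of that regression
("predicted versus observed" orientation; the swapped orientation is one
argument away for sensitivity analysis).

One subtlety matters for null calibration: in a leave-one-out design the
null model for fold $i$ predicts $\overline{y_{-i}}$, which is an exactly
*decreasing* linear function of the held-out age. A clock with no skill
therefore shows a near-perfect unsigned correlation with negative slope.
`evaluatePredictions()` reports the signed Pearson `r` alongside R², and
the null-calibration tests judge skill by $\mathrm{sign}(r)\,R^2_{adj}$,
which equals $R^2_{adj}$ whenever the clock has genuine positive skill.

# Numerical and degenerate-input policy

Zero-variance feature columns are left at zero after centering and
flagged, never NaN. Depth-zero methylation cells are missing, never 0.
Empty post-filter feature sets stop the pipeline with an explicit error
(accessibility warns first at the filter stage). Coordinate conventions:
BED files are 0-based half-open on disk, bismark coverage files 1-based;
everything is 1-based closed `GRanges` in memory. Strand is ignored
throughout. Convergence of the solver is declared when the largest
coefficient change in a sweep falls below `tol * sd(y)` (default
$10^{-7}$; the final per-fold fits use $10^{-9}$ so every stored model
passes the KKT certificate). All randomness flows from explicit seeds;
two runs of `runPipeline()` with the same config are byte-identical.

# Known limitations

* The simulation's independence assumptions (above) make absolute
  performance numbers incomparable to real cohorts.
* The global-scaling default reproduces the emulated study's information
  leak by design; use `scaling = "fold"` for honest error estimates.
* Library size is in-peak total, not genome-wide mapped reads.
* Cross-validation fold assignment uses the caller's RNG stream; seed
  before calling (the pipeline does).
* No mixed models, kinship/breed random effects, or time-to-death clocks.
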
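---
title: "Methods: multiclass breathomics and VOC network remodeling"
author: "breathomics package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiclass breathomics and VOC network remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind the package, the
parameters that matter, the design decisions taken where the design was
genuinely open, and what the synthetic cohort generator does and does not
emulate.  Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The data model

A `BreathomicsExperiment` extends `SummarizedExperiment`: one assay
(`"intensity"`) of m/z features × participants, with the diagnosis group
(BA, COPD, CF, LAM, Control) and clinical covariates (age in years, sex,
BMI in kg/m², smoking status never/former/current) in `colData` and the
numeric m/z of every feature in `rowData`.  Each participant contributes
exactly one breath sample, so sample and participant identifiers coincide;
splitting is therefore automatically participant-level.  Intensities are
ion counts per second on an arbitrary positive scale; whether they are
breath-phase-averaged or integrated peak areas is irrelevant to every
method in the package, which treats them as abstract positive intensities.

## Preprocessing

**Feature filtering.** Features with m/z < 42 are removed (the boundary
value 42.0 is retained), along with an optional exclusion list for
instrument calibration ions.  The exclusion list defaults to empty because
no canonical list of calibration masses exists for arbitrary instruments;
it is a configuration input.

**Stratified split.** The training size is fixed at
`floor(fraction × N)` and per-class counts are allocated by the
largest-remainder rule.  This reproduces the 590/253 partition of the
843-participant cohort exactly regardless of per-class rounding ambiguity,
and bounds every class's train share within one participant of the global
fraction.  Remainder ties break toward the larger fractional part, then
table order — arbitrary but fixed.

**Control-referenced normalization.** Per feature, center = median and
scale = IQR of the *training-set control samples only*, applied
identically to all samples.  Normalizing against the healthy reference
(rather than the pooled distribution) prevents disease-related variance
from leaking into the scale and makes patient values interpretable as
deviations from health.  Features with zero control IQR receive scale 1 — a
guard for near-constant features; the alternative (dropping them) would
silently change the candidate set.  One percentile convention — linear
interpolation between order statistics (R type 7) — is used everywhere in
the package: the normalizer IQR, the panel threshold, bootstrap CI
percentiles and the network deviation thresholds.

## Stability selection

Per iteration: a stratified 50% subsample without replacement, SMOTE
balancing of all classes up to the majority count (synthetic point
`x + u·(x_nn − x)`, `u ~ U(0,1)`, nearest neighbors within class, `k`
reduced to class size − 1 for small classes), then a multiclass
gradient-boosted tree fit whose per-feature *gain* importance is recorded.
Two aggregates are kept: the **selection probability** (fraction of
iterations with strictly positive gain) and the **mean gain**.  The panel
threshold is the 75th percentile of the selection probabilities over
features with nonzero stability, with `≥` at the boundary so features
exactly at the percentile are retained.  Panel order is descending
probability, then descending mean gain, then ascending m/z.

The inner learner is deliberately modest and configurable
(`stabilityLearnerConfig()`; default 200 rounds, depth 6).  Its capacity
trades off against the informativeness of the probability: a very large
ensemble touches every feature in every iteration and saturates all
probabilities at 1, while a sparse one lets null features drop out.  The
test suite and acceptance script use a sparse configuration (8 rounds,
depth 2) at 100 iterations — problem sizes chosen so the whole suite runs
quickly — and verify that features planted at a 1.5-control-SD shift
outrank the null median in ≥ 18 of 20 replicates.

Clinical covariates (Age, Sex, BMI, Smoking — sex as a male indicator,
smoking encoded ordinally 0/1/2, a minimal encoding adequate for tree
models) enter the candidate set alongside the VOCs.  A `"protected"`
policy force-retains all four covariates in the full panel irrespective of
their probability; it is off by default, because a protected covariate can
simultaneously carry selection probability 0 — the two notions (always in
the model vs stably informative) are distinct, and the package surfaces
both rather than reconciling them.

## Multiclass model and evaluation

The training pipeline is scaler → SMOTE → XGBoost, with both the
control-referenced scaler and the oversampling fitted strictly inside the
(fold-)training data; the test suite includes leakage probes that perturb
held-out rows and assert the fitted parameters do not move.  The tuned
hyperparameter grid is depth {7, 12} × L1 {0.1, 1, 10} × L2 {0.1, 1, 10}
at 800 fixed boosting rounds, scored by repeated stratified 10×3
cross-validated macro OvO AUC; ties break toward the smaller depth, then
the stronger L2 regularization.  The learning rate (0.1) and remaining
learner settings are implementation defaults.  Exhaustive grid search is
the single search mode implemented; a successive-halving search would
optimize the same criterion over the same grid and was not worth a second,
separately-tested code path.

Pairwise OvO AUCs use the normalized pair score `p_i/(p_i + p_j)`,
restricted to samples of the two classes — the standard construction,
chosen because it makes each pair AUC invariant to probability mass on the
remaining classes.  AUCs are Mann–Whitney statistics with mid-rank tie
handling (ties count ½).  Per-pair decision thresholds maximize Youden's J
over midpoints of sorted unique *training* scores (±∞ sentinels included;
smallest maximizer on ties); thresholds derive from refit-on-full-training
scores rather than cross-validated scores, the simpler and more common
choice.  Binary metrics with zero-denominator cells are reported as
undefined (`NA` plus a flag), never coerced to 0.  Bootstrap percentile
CIs (default 1000 replicates; 500 available via `nBoot`) resample test
instances; resamples on which a metric is undefined are redrawn with a cap
of 10× the requested replicates.

## Univariate statistics

Per VOC: a global Kruskal–Wallis test (base R, tie-corrected), and — only
upon global rejection at 0.05 — all 10 pairwise Mann–Whitney tests, exact
for ≤ 8 observations per side without ties and normal-approximated with
continuity and tie correction otherwise.  Holm–Bonferroni correction is
applied *within one VOC's pair family*: the post hoc family is the 10
pairwise contrasts that follow one global test, while cross-VOC
multiplicity is reported but not corrected, mirroring how such panels are
conventionally presented.  Tests run on normalized data; summaries (mean ±
SD, median, IQR) are emitted on both normalized and original scales.

## Network analysis

**Signed distance correlation.** Association strength is the sample
(V-statistic) distance correlation — sensitive to nonlinear dependence —
multiplied by the sign of Kendall's τ-b for monotone direction.  A zero τ
(including constant vectors) gives a signed correlation of exactly 0,
which the 1e-6 edge rule then drops: direction-free association is handled
deterministically.  Per group, 500 subsamples of `max(2, floor(n/3))`
observations are drawn without replacement and the entrywise median taken.
Size-2 subsamples are degenerate for distance correlation (the statistic
is identically 1 for any non-constant pair) and therefore contribute
zeros rather than an arbitrary value.

**Graph and centralities.** Edges require |r| strictly above 1e-6; weights
are |r| with the sign retained for interpretation.  Weighted degree is the
sum of incident absolute weights.  Betweenness uses shortest paths with
edge length 1/|w| — the reciprocal makes stronger associations shorter,
the standard convention for strength-weighted betweenness (the complement
1 − |w| is available via `lengthTransform`); normalization is over
undirected pairs excluding endpoints.  Eigenvector centrality is computed
by power iteration (tolerance 1e-10, ≤ 10⁴ iterations) on the
absolute-weight adjacency, with a positive diagonal shift so the iteration
converges on bipartite topologies whose spectrum is symmetric about zero
(the shift leaves eigenvectors unchanged).  Katz centrality solves
`(I − αA)x = 1` with α = 0.9/λmax.  Both spectral measures use absolute
weights, consistent with degree and cliques; signed spectra would break
the non-negativity assumptions behind both.

**Deviations and thresholds.** Centralities are min–max normalized to
[0, 1] within each group (a constant metric maps to all zeros — arbitrary
but fixed), and deviations are Δ = norm(disease) − norm(control).  The
adaptive thresholds are the 5th and 95th percentiles of the *signed*
pooled Δ distribution per metric (pooling all nodes and all non-control
groups): the two 5% tails together select the 10% most extreme
deviations, and signed pooling is the only reading consistent with
negative lower thresholds.  Flags are strict inequalities, so a degenerate
all-zero pooled distribution flags nothing and control-vs-control is
identically zero.

**Cliques.** Edges at |w| ≥ r with r = d/√(d² + 4) for d = 0.5 (the
equal-group-size point-biserial conversion, r ≈ 0.2425); maximal cliques
are enumerated by Bron–Kerbosch with pivoting (igraph) and scored by total
internal edge weight, with ties going to the larger clique and then the
lexicographically smallest node set.  The aggregated (median) matrix, not
the per-bootstrap graphs, is what is thresholded.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
with the study conditions as defaults: group sizes 160/128/102/51/402
(843 total); covariate distributions per group (age and BMI as truncated
normals — ages clipped to 18–89 years, BMI to a physiological 13–60 —
sex and smoking categorical, LAM all female, CF all never-smokers);
lognormal intensity marginals whose control-group means and SDs for 13
core ions sit on the published scale (e.g. phenol-like m/z 95.05 at
0.213 ± 0.130 counts per second in controls), with multiplicative
group shifts derived from the corresponding group means (CF phenol
0.050/0.213); and a Gaussian copula imposing group-specific latent
correlation.  Lognormal marginals were chosen over additive Gaussians
because breath intensities are positive and right-skewed (SDs often
exceed means), and the copula lets the correlation structure be specified
exactly and independently of the marginals.  Covariate–class confounding
is generated deliberately (age, BMI, sex and smoking differ by class), so
the covariate-vs-VOC incremental-value comparison is exercised.

The control correlation structure places hubs at m/z 85.07, 85.10, 97.09,
97.10, 71.06 and 71.08 (latent hub–hub correlation 0.75), with secondary
high-degree nodes at 119.96 and 107.96.  Disease rewiring: BA boosts
235.21; COPD boosts 149.10, 235.21 and 181.01; CF boosts 159.07 and 96.06
and detaches 119.96; LAM boosts 149.10 and 103.08 with a higher overall
integration level (base 0.30 vs 0.15) — and all diseases except LAM
depress the 71.xx hub connectivity.  Modified matrices are projected to
the nearest positive-definite correlation matrix.  Non-informative
features share the control distribution in all groups; non-core ion
marginals use plausible positive targets with coefficient of variation
around 1, fixed deterministically.  The per-observation log-scale noise SD
defaults to 0.1, a mild measurement-noise level that perturbs intensities
by ~10% without masking the planted structure.

What the generator does *not* emulate: raw spectra, breath-phase dynamics,
instrument drift, batch effects, medication or diet effects, or the actual
dependence structure of real exhaled breath.  Passing recovery tests
therefore demonstrates that the pipeline recovers structure *of the kind
it assumes*, under realistic sizes and noise — not that the original
cohort's performance figures (macro OvO AUC 0.866/0.888, CF pair AUCs near
0.99, panel sizes 31/29) are reproducible; those require the undeposited
cohort data and are out of scope by design.

## Numerical choices and problem sizes

Tolerances: distance correlation is validated to 1e-12 against a
brute-force double-centering oracle; Katz solutions satisfy
‖(I − αA)x − 1‖∞ < 1e-8; power iteration converges to 1e-10; PD repair
targets a smallest eigenvalue ≥ 1e-8.  Seeds: every stochastic function
takes an explicit seed, applied via a local RNG scope so the caller's RNG
state is untouched; iteration seeds derive as seed + index, pipeline stage
seeds as root seed + a stage-name hash.  The test suite and acceptance
script run the recovery studies at 20 replicates, 100 stability
iterations, 100 network bootstrap subsamples, 500 null simulations and 200
coverage datasets — sizes chosen as the package's own compromise between
Monte-Carlo precision and a fast, reproducible run.

## Interfaces

This package is driven from R: the exported functions are the module
surface (`generateDataset`, `readFeatureTable`/`writeFeatureTable`,
`filterFeatures`, `stratifiedSplit`, `fitControlNormalizer`/
`applyNormalizer`, `smoteBalance`, `runStabilitySelection`/`selectPanel`,
`fitPipeline`/`evaluateModel`/`tuneHyperparameters`, `univariateStats`,
`bootstrapAssociationMatrix`/`buildNetwork`/`computeCentralities`/
`deviationReport`/`maxWeightedClique`), and `runFullPipeline()` plus a
YAML `RunConfig` orchestrate the whole analysis with a run manifest.  No
shell entry point is shipped; an R session or Rscript one-liner over these
functions is the intended command-line usage.

## Known limitations

Selection probabilities saturate under a high-capacity inner learner (see
above).  Distance-correlation medians over small subsamples carry a known
upward bias under independence, so near-zero edges should be interpreted
with the 1e-6 rule in mind, not as significance.  The deviation analysis
is descriptive: no differential-network significance test is performed.
Betweenness on graphs with many tied shortest paths depends on the path
multiplicity convention; the package follows the standard all-shortest-
paths fractional count.
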
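---
title: "Models, estimators and design choices in mscognet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and design choices in mscognet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscognet)
```

`mscognet` implements a multicenter structural-connectomics analysis of
SDMT (processing-speed) impairment in adult-onset versus late-onset
multiple sclerosis. This vignette is the package's own account of the
science: the models and their assumptions, the tunable parameters, what the
synthetic-data generator emulates, the numerical choices, and the design
decisions that were genuinely open.

## 1. The synthetic world

No subject-level data are distributed with this problem, so the package
carries a first-class generator whose defaults *are* the stated conditions
of the motivating cohort:

* 7 centers; 519 HC (ages 18–77), 294 AOMS (onset 18–45 y), 80 LOMS
  (onset ≥ 45 y); disease duration ≤ 6 years, `age_at_mri = onset +
  duration`. Ages are uniform within windows — simple, and it guarantees
  the HC reference spans the whole patient age range so z-scoring never
  extrapolates by construction.
* Each z-scored metric is generated as
  `center intercept + sex + age + sex:age effects + group shift + noise`,
  with the **group shift expressed in HC-SD units of that center**
  (`shift × σ_base × center multiplier`). Because the normative z-score
  divides by the same center SD, the injected shift equals the expected
  mean z in every center — parameter recovery is exact in expectation, a
  deliberate property that makes the calibration tests sharp.
* Default shifts are the reported group means (e.g. density −0.979 AOMS /
  −1.667 LOMS; modularity +0.568 / +0.994). Center residual-SD multipliers
  default to `seq(0.8, 1.2)` across the 7 centers: heteroscedasticity large
  enough to matter, small enough to be realistic for harmonized 3T
  protocols. Center intercept offsets are ±0.25 SD steps.
* Lesion volume is log-normal (`sdlog = 0.9`, a typical right skew) with
  group mean 1.934 mL (AOMS) / 2.910 mL (LOMS); disconnection percentages
  are logit-normal around the reported group means (8.38/1.70% AOMS,
  11.18/2.41% LOMS inter/intra). HC carry zero lesion volume.
* SDMT impairment is Bernoulli from a configurable logistic model
  (intercept `qlogis(0.39)`, the observed base rate; default coefficients
  load on lesion volume, intra-hemispheric disconnection and the
  communication metrics, the AOMS-like substrate pattern, each per patient-SD
  of the predictor). The continuous `sdmt_z` is filled consistently with the
  impairment flag by a truncated-normal draw around the −1.5 cutoff — the
  pipeline consumes the flag, not the score.
* One master seed spawns named substreams (`substream_seed(master, name)`)
  per generator, so adding a generator never perturbs another's draws, and
  `simulate_cohort()` / `simulate_metric_table()` regenerate bit-identical
  tables from the same config.

Not emulated: anatomically realistic geometry, lesion–metric coupling at
the individual level (group shifts are marginal), scanner software
differences beyond location/scale, and longitudinal structure. A green test
therefore establishes estimator correctness (recovery, calibration,
coverage), not biological fidelity.

Per-center sample sizes of the original study are not published in the
available material; subjects are assigned to centers uniformly at random.

## 2. Geometry: parcellation, tractogram, lesions, disconnection

The toy parcellation lays labeled blocks on a lattice, half per hemisphere
(left = x below the midsagittal plane; an odd node count yields one midline
node), with the lower ~35% of the z-extent flagged infratentorial.
Streamlines join random points inside two distinct node regions; the bow
added for realism is vertical only, so crossing the midsagittal plane is
equivalent to having endpoints in opposite hemispheres and the commissural
fraction is exactly the configured Bernoulli rate in expectation. Lesions
are spherical foci biased toward the grid center (a crude periventricular
bias) accumulated until the volume is within one focus-volume of target.

Connectome conventions (all configurable): world mm coordinates, voxel
index `floor(coord/voxel)`, endpoint-to-node search radius 2 mm (the usual
tolerance of connectome builders for boundary effects); FA edge weight =
mean per-streamline FA (the tck2connectome-style aggregation); self-loops
and unassignable streamlines excluded. Streamline–lesion intersection
resamples polylines at half-voxel steps rather than exact segment–voxel
clipping — the error is bounded by the step and this matches common
practice.

Disconnection indices: the motivating analysis does not state whether the
denominators are class-specific or whole-tractogram. Its printed values
(inter 8.38% > intra 1.70% despite far fewer inter-hemispheric streamlines)
are consistent with class-specific denominators, which is the default here;
`denominator = "total"` is available. Midline-node streamlines count toward
the total (and the commissural-ratio denominator) but fall in class
"other", since the indices are defined for supratentorial intra- and
inter-hemispheric tracts. An empty class yields a missing index, never 0.

## 3. Graph metrics

Computed on the FA-weighted matrix with Brain-Connectivity-Toolbox
conventions: density counts nonzero pairs; strength is the mean row sum;
efficiency uses edge lengths `1/w` (the `−log w` alternative was rejected
for comparability with the toolbox); unreachable pairs contribute zero to
efficiency, which keeps it monotone under edge addition; clustering is the
Onnela geometric-mean form on max-normalized weights, with degree-<2 nodes
contributing 0.

Modularity was the one place implementation overruled the original plan.
Louvain (resolution 1, best of 100 restarts) cannot reach the exhaustive
optimum on some graphs even with vertex-permuted restarts and single-vertex
hill climbing — a known limitation of greedy agglomeration, observed here on
a fixed 7-node test graph (Q = 0.175 vs exact 0.189). `graph_modularity()`
therefore solves graphs of ≤ 12 nodes exactly (integer programming via
`igraph::cluster_optimal`) and uses vertex-permuted Louvain restarts above;
real connectomes (253 nodes) always take the Louvain path, and the
permutation restarts are what make "best of N" meaningful, since the
underlying implementation is order-deterministic.

One reported quantity is ambiguous: the z-scored "commissural ratio /
intra-hemispheric efficiency". It is implemented as the z of the raw ratio;
a ratio of z-scores can divide by values near zero and is not
location-invariant.

## 4. Normative model

Reference model per metric, HC only: `y ~ sex + age + sex:age + center`
with center-specific residual variances, estimated by iterated feasible GLS
(weighted LS ↔ per-center variance) to relative tolerance 1e−8 on the SDs,
max 50 iterations. Center variances use a residual-degrees-of-freedom
correction (`n_c` minus the center's share of model parameters) to reduce
small-center bias. Sex is coded F=0/M=1 and age is centered at the HC mean
before the interaction, which conditions the design without changing
predictions. With `heteroscedastic = FALSE` the fit collapses exactly to
OLS — the homoscedastic limit is only exact when the variance is *shared*,
because independently estimated equal variances still differ by sampling
noise.

Properties the tests rely on: per-center HC mean z is exactly zero (WLS
orthogonality to the center indicators, with weights constant within
center); HC z SD ≈ 1; z-scores are invariant to affine rescaling of the
metric. Patients may be scored outside the HC age range (warning), and an
unseen center is an error — no silent pooling. Variance heterogeneity is
center-only; center-specific age slopes are deliberately out of scope (the
reference model names covariates, not slope heterogeneity).

## 5. Group comparisons

* Chi-square without continuity correction and Fisher's exact with the
  minimum-likelihood two-sided rule: both validated by reproducing the
  printed p-values (0.751, 0.380, 0.007, 0.469, 0.039) from the published
  contingency tables.
* Mann–Whitney: exact for small untied samples, otherwise normal
  approximation with tie correction.
* "Robust linear regression" is Huber M-estimation (k = 1.345, MAD scale,
  IRLS) — the family was named without an estimator; Huber is its standard
  member. Degenerate all-constant input is answered directly (the MAD scale
  would be zero).
* Log-LV model: zeros are offset by half the smallest positive volume
  (configurable; the source is silent on zeros); group means are marginal
  over the observed sex/center distribution and mapped back to mL by the
  delta method (`mean = exp(μ̂)`, `SE = exp(μ̂)·SE(μ̂)`).
* Disconnection proportions: logit-link quasi-binomial with estimated
  dispersion, group means as marginal predicted percentages. With unit
  weights a proportion in [0,1] cannot exceed binomial variance, so
  dispersion > 1 is demonstrated via the optional `trials` weights.
* BH-FDR is applied over all p-values of one results table and never pooled
  across tables.

## 6. Associations and the balanced bootstrap

"Robust quasi-likelihood" logistic estimation is implemented as ML point
estimates with HC0 sandwich standard errors; the fully robust-deviance
estimators (Cantoni–Ronchetti) are a documented alternative, not the
default. Unit scalings follow the reporting conventions: per year, per 10%
lesion-volume increase (`exp(β_logLV · ln 1.1)` — an exact identity, tested),
per disconnection percentage point, per z-unit. Only lesion volume and the
disconnection indices are center-adjusted, mirroring the source analysis.
Separation is detected on the coefficients under inference (|β| > 15 or
non-convergence); a separated nuisance center dummy in a small resample
does not abort the analysis.

The balanced bootstrap draws n = 80 per group with replacement (5000
replicates in the original; scaled to 500 in tests purely for runtime),
reruns the analysis, and reports percentile CIs plus a two-sided bootstrap
p-value `2·min(P(stat ≤ 0), P(stat ≥ 0))` floored at 1/reps — the source
prints bootstrap p-values without defining them; this percentile-inversion
definition is documented as the package's choice, not asserted as the
authors'. Resampling is stratified by onset group only; center enters as a
covariate. Failed replicates are dropped and counted; > 20% failures is an
error, never imputation.

## 7. Elastic-net selection

Predictors are standardized; center indicators enter **unpenalized**
("center-adjusted" read as adjustment, not a selection candidate — if the
authors penalized center, selection percentages for it would have been
reported). λ is tuned by the 1-SE rule on 5-fold stratified cross-validated
binomial deviance (`glmnet`'s `lambda.1se` is exactly that rule). The
mixing parameter α is not stated in the source; the default is 0.5 and it
is exposed in every call. AUC is reported in-sample (mirroring a
"full-sample analysis" AUC) with a cross-validated AUC alongside, clearly
labeled, because in-sample AUC is optimistic. Selection frequencies rerun
the *entire* tuning on bootstrap samples of n = 80 drawn from the analysis
group's own data, reporting the percentage of replicates with a nonzero
coefficient. Lesion volume enters the multivariable model on the log scale
before standardization (consistent with its univariable treatment).

## 8. Numerical and degenerate-input conventions

FGLS tolerance 1e−8 / 50 iterations; rlm maxit 100; modularity exact below
13 nodes; empty graph efficiency 0; modularity of an all-zero matrix is an
error (m = 0); conservation ratio with zero intra-hemispheric efficiency is
missing with a warning; empty disconnection classes are missing, not zero;
bootstrap p floors at 1/reps; constant predictors are dropped with a
warning. Matrices round-trip through TSV at 9 significant digits; NIfTI-1
and TCK are implemented against their fixed published layouts
(little-endian, uncompressed) because no R reader was available in the
target environment; a JSON-lines polyline dialect serves as the text
fixture format.

## 9. Known limitations

Synthetic metrics are drawn marginally per metric, so cross-metric
correlation structure (e.g. density–strength coupling) is weaker than in
real connectomes; selection-frequency magnitudes are therefore not
comparable to published values, only their ranking behavior is tested. The
geometry path is a demonstration of the construction logic, not a
substitute for tractography. Bootstrap replicate counts in shipped tests
are scaled down from 5000; the machinery is identical. No mixed-effects
center modeling (the source adjusts by fixed center terms), no spline
normative curves, no SIFT filtering, no nodal metric export.
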
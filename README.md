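# mscognet

Structural-connectome substrates of processing-speed impairment in
multiple sclerosis (MS), comparing adult-onset (AOMS, onset 18–45 y) and
late-onset (LOMS, onset ≥ 45 y) patients.

Information processing speed — measured with the Symbol Digit Modalities
Test (SDMT, impairment = z < −1.5 against norms) — is the cognitive domain
most often affected in MS. Whether its anatomical substrate differs when the
disease starts late in life is a multicenter connectomics question: it
requires lesion masks, diffusion tractography-derived connectomes, and
statistics that survive site heterogeneity and badly unbalanced group sizes.
`mscognet` implements that full analysis pipeline as a tested, reusable R
package, exercised end-to-end on synthetic multicenter cohorts with known
injected effects.

## What it computes

**Connectome construction.** From a tractogram (3-D streamline polylines
with per-streamline mean fractional anisotropy, FA) and a node parcellation
(voxel label image, 253 nodes in the motivating design), endpoints are
assigned to nodes (2 mm search radius), yielding a streamline-count matrix
and an FA-weighted matrix `w_ij` (mean FA of connecting streamlines).

**Lesion-based disconnection.** A streamline is *disconnected* if it
intersects the T2-lesion mask (polylines resampled at half-voxel steps).
Per subject:

- intra-/inter-hemispheric disconnection index = 100 × (lesioned / total)
  streamlines of that class (intra restricted to supratentorial tracts),
- commissural ratio CR = inter-hemispheric streamlines / all streamlines,
- a node-pair disconnectivity matrix of lesioned-streamline proportions.

**Graph metrics** on the FA-weighted connectome: density, mean strength
`s̄ = (1/N) Σ_i Σ_j w_ij`, global efficiency
`E = (1/(N(N−1))) Σ_{i≠j} 1/d_ij` with edge length `1/w`, Onnela
max-normalized mean clustering, Newman–Girvan modularity Q (exact for tiny
graphs, vertex-permuted Louvain restarts otherwise), intra-hemispheric
efficiency (per-hemisphere efficiency, averaged) and the conservation index
CR / E_intra.

**Multicenter normative z-scores.** For each MRI measure a reference model
`y ~ sex + age + sex:age + center` is fitted to healthy controls (HC) by
iterated feasible GLS with center-specific residual variances; a patient's
z-score is `(y − ŷ) / σ_center`.

**Statistics.** Chi-square (no continuity correction), minimum-likelihood
two-sided Fisher, Mann–Whitney; robust (Huber M-estimation) models for mean
z-scores and log lesion volume (delta-method back-transform); sex- and
center-adjusted quasi-binomial models for disconnection proportions;
Benjamini–Hochberg FDR per results table; robust-sandwich logistic odds
ratios with the field's unit scalings (per 10% lesion-volume increase =
`exp(β_logLV · ln 1.1)`); balanced downsampled bootstrap (n = 80 per group);
center-adjusted elastic-net logistic regression tuned by the 1-SE rule on
5-fold cross-validated deviance, with bootstrap selection frequencies.

## Worked example

```r
library(mscognet)

cfg <- sim_config(n_hc = 300, n_aoms = 200, n_loms = 100, seed = 42)
cohort  <- simulate_cohort(cfg)        # demographics + SDMT impairment
metrics <- simulate_metric_table(cohort, cfg)
zres    <- zscore_table(cohort, metrics)

robust_z_comparison(zres$z$density, zres$z$group)
#>         term estimate     se        p
#> 1       AOMS   -0.891 0.0672 4.04e-40
#> 2       LOMS   -1.580 0.0950 4.27e-62
#> 3 difference   -0.689 0.1164 3.16e-09
```

The generator injects the reported group shifts (density −0.979 in AOMS,
−1.667 in LOMS, in HC-SD units); the robust comparison recovers them within
sampling error and shows the LOMS excess (difference −0.689, p ≈ 3e−9).
The reference model behind those z-scores:

```r
hc <- merge(cohort[cohort$group == "HC", ], metrics, by = "subject_id")
fit_reference(hc, "density")
#> Normative reference model for 'density' (7 centers, FGLS 10 iterations)
#> (Intercept)        male       age_c    male_age     center2  ...
#>   3.369e-01   3.182e-03  -3.104e-04   3.443e-05   4.171e-04  ...
#> per-center residual SD:
#>       1       2       3       4       5       6       7
#> 0.01896 0.01593 0.02340 0.01929 0.02210 0.02605 0.02533
```

Per-center residual SDs differ by design (heteroscedastic centers); the
z-scores absorb both the site offsets and the site noise levels. A printed
contingency check against the motivating cohort (116/294 AOMS vs 30/80 LOMS
impaired):

```r
contingency_test(rbind(AOMS = c(116, 178), LOMS = c(30, 50)), "chisq")
#> $statistic  0.1010793
#> $p          0.7505383
```

The full pipeline (Tables 1–4-shaped reports plus a reproducibility
manifest):

```r
run_all(cfg, "out/", assoc_reps = 500, select_reps = 200)
```

or from the shell via `inst/cli/mscognet`:

```sh
Rscript inst/cli/mscognet run-all --config cfg.json --out-dir out/
```

## What the synthetic data does and does not establish

The generator reproduces the *stated world* of the motivating study (7
centers, HC 18–77 y, onset windows, ≤ 6 y disease duration, reported effect
magnitudes, ~39% impairment rate) with known injected effects, so green
tests establish that the estimators recover what was injected — not that
real MS data behave this way. See `vignettes/methods.Rmd` for the model,
parameter and design discussion.
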
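# respsig

Responder-signature analysis for multi-arm dry-land training trials.

Group-average effects hide who actually responds to a training stimulus. In a
three-arm trial — maximal strength training (MSTG), plyometric training
(PTG), active control (CG) — where upper-limb power is measured by bench
press average power and medicine-ball throw, and lower-limb power by CMJ, SJ,
DJ, and SLJ at Pre/Mid/Post, `respsig` answers three questions:

1. **How much did each arm's power constructs change?** Indicators are
   standardized by baseline mean/SD; a one-component PCA fitted at baseline
   per domain gives fixed loadings `w` (‖w‖₂ = 1); composite scores
   `s_it = Σⱼ wⱼ (x_ijt − x̄_j,pre)/σ̂_j,pre` are computed at all time points
   and responsiveness is `Δ = s_post − s_pre`. Pairwise arm contrasts use
   permutation tests (100,000 relabelings, two-sided, add-one estimator, or
   exhaustive enumeration for pooled n ≤ 12), stratified-bootstrap percentile
   95% CIs (20,000 resamples), Hedges `g = J·(m₁−m₂)/s_pooled` with
   `J = 1 − 3/(4df−1)`, and Holm adjustment within endpoint.
2. **Are there stable responder signatures?** Ward clustering of the
   standardized (ΔUpper, ΔLower) vector, k = 2–4 selected by silhouette with
   a small-cluster guard, 2,000-replicate bootstrap stability
   (centroid assignment in the original standardized space, maximum-overlap
   label alignment, adjusted Rand index and cluster-wise Jaccard), and a
   100,000-permutation chi-square test of the cluster-by-arm association.
3. **What predicts responsiveness?** Leave-one-out cross-validated ridge
   (ΔUpper/ΔLower) and L2-logistic (high-responder membership) models over
   group, sex, training years, best 50 m time, and baseline composites, with
   bootstrap coefficient uncertainty.

A seeded synthetic cohort generator emulates the study conditions (3 × 9
swimmers, published change distributions, baseline correlations ≈ 0.91–0.93),
so the entire pipeline is testable without raw data. See the methods
vignette (`vignettes/responder-signatures.Rmd`) for models, assumptions, and
design choices.

## Worked example

```r
library(respsig)

panel <- generate_cohort(sim_config(seed = 42))   # 27 swimmers, 3 arms
upper <- fit_baseline_pca(panel, "upper")
upper
#> Composite model (upper-limb power), PC1 of 2 baseline indicators
#>   variance explained: 0.952
#>   loadings: bench=0.707, mbt=0.707

delta <- compute_deltas(upper, fit_baseline_pca(panel, "lower"), panel)
run_contrasts(delta, n_perm = 1e5, n_boot = 2e4, seed = 42)
#>     endpoint group_a group_b mean_diff ci_lower ci_upper p_perm p_holm hedges_g
#>  delta_upper    MSTG     PTG     0.392    0.263    0.526 <0.001 <0.001    2.480
#>  delta_upper    MSTG      CG     0.741    0.665    0.820 <0.001 <0.001    7.938
#>  delta_upper     PTG      CG     0.349    0.228    0.460 <0.001 <0.001    2.482
#>  delta_lower    MSTG     PTG     0.037   -0.132    0.204  0.689  0.689    0.184
#>  delta_lower    MSTG      CG     0.516    0.376    0.654 <0.001 <0.001    3.105
#>  delta_lower     PTG      CG     0.480    0.378    0.585 <0.001 <0.001    3.806
```

Both training arms beat the control on both constructs (Holm p < 0.001);
in this draw MSTG also exceeds PTG for upper-limb change (mean difference
0.392 composite units, g = 2.48). `hedges_g` values are pooled-SD units;
`mean_diff` and the CIs are composite (baseline-SD) units.

```r
sig <- find_signatures(delta)                    # Ward + silhouette + guard
sig
#> Ward clustering, selected k = 2 (silhouette 0.592, sizes 18; 9)

bootstrap_stability(delta, sig, n_replicates = 2000, seed = 42)
#> Bootstrap stability (2000 replicates): mean ARI 0.826 [0.477, 1.000]
#> Cluster-wise Jaccard similarity:
#>  cluster      mean         sd  ci_lower ci_upper
#>        1 0.9321389 0.05485461 0.7777778        1
#>        2 0.8880451 0.07899728 0.6923077        1

permutation_chi2(delta$group, sig$labels, n_perm = 1e5, seed = 42)
#> Permutation chi-square: chi2 = 27.000, p = <0.001 (100000 permutations)
#>        group
#> cluster CG MSTG PTG
#>       1  0    9   9
#>       2  9    0   0
```

Two signatures emerge — a high-responder cluster (here: every MSTG and PTG
swimmer) and a low-responder cluster (every CG swimmer) — reproducible
across bootstrap replicates (mean ARI 0.83, cluster Jaccard ≈ 0.89–0.93) and
strongly aligned with training allocation. `run_all(seed = 42, out_dir =
"results")` runs every stage (including the ridge/logistic predictor models)
and writes table analogues (CSV), figures (PNG), and a full-precision
`report.json`; a thin CLI wrapper lives at `inst/cli/respsig.R`.

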
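---
title: "Responder signatures: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Responder signatures: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respsig)
```

`respsig` analyzes multi-arm dry-land training trials in which neuromuscular
power is measured by several indicators per limb domain at three time points
(Pre, Mid, Post). Its running example is a three-arm swimmer trial — maximal
strength training (MSTG), plyometric training (PTG), and an active muscular
endurance control (CG), nine swimmers per arm — with two upper-limb indicators
(bench press average power, medicine-ball throw) and four lower-limb
indicators (CMJ, SJ, DJ, SLJ). This vignette documents the statistical
machinery, the assumptions behind the synthetic cohort generator, and the
choices made where the design was genuinely open.

## The composite model

Raw indicators live on incommensurate scales (watts, metres, centimetres), so
each domain is collapsed into a single construct. For domain $d$ with
indicators $x_1, \dots, x_p$:

1. standardize each indicator by its **baseline (Pre)** mean and SD;
2. fit a PCA on the baseline correlation matrix and retain the first
   component, loadings $w$ with $\lVert w \rVert_2 = 1$;
3. score every swimmer at every time point with the *fixed* baseline
   anchors: $s_{it} = \sum_j w_j (x_{ijt} - \bar{x}_{j,\text{pre}}) /
   \hat\sigma_{j,\text{pre}}$;
4. responsiveness is the change score $\Delta_d = s_{i,\text{post}} -
   s_{i,\text{pre}}$.

Fitting on the correlation matrix (not covariance) is what makes a
two-indicator domain produce the equal loadings $(0.707, 0.707)$; its PC1
variance fraction is then exactly $(1 + r)/2$ for baseline correlation $r$,
and $(1 + (p-1)\bar r)/p$ under equicorrelation — closed forms the tests
exploit. The leading eigenvector is oriented so its coefficient sum is
positive (power indicators correlate positively, so all-positive loadings are
the meaningful orientation); an exact zero sum falls back to a non-negative
first coefficient. Scores are raw projections: no division by the eigenvalue
and no rescaling to unit variance. This keeps $\Delta$ in "composite units"
(baseline-SD units aggregated over indicators) and reproduces equal-weight
behavior for two indicators. Whether the source analysis additionally
rescaled its composites is not stated; raw projection is this package's
convention and all synthetic-recovery targets are defined under it. Missing
cells are rejected rather than imputed — the pipeline is a completers
analysis.

## Between-group inference

Group contrasts on $\Delta_\text{upper}$ and $\Delta_\text{lower}$
deliberately avoid normal-theory assumptions at $n = 9$ per arm:

* **Permutation test** — statistic $T$ = mean difference; labels are permuted
  preserving group sizes. With pooled size $\le 12$ all
  $\binom{n}{n_a}$ splits are enumerated and the p value is the exact tail
  fraction; otherwise 100,000 Monte-Carlo relabelings are drawn and
  $p = (1 + \#\{|T^*| \ge |T|\})/(N + 1)$. The add-one estimator keeps
  Monte-Carlo p values strictly positive (its floor at $N = 10^5$ is
  $10^{-5}$); the uncorrected count estimator is available via
  `plus_one = FALSE` since the source procedure does not state which was
  used.
* **Bootstrap CI** — 20,000 resamples, drawn *within* each group
  (stratified), percentile 2.5/97.5 bounds. Stratification preserves the
  two-sample design; plain pooled resampling would mix the arms.
* **Effect size** — Hedges $g$: pooled-SD standardized mean difference times
  the small-sample correction $J = 1 - 3/(4\,\mathrm{df} - 1)$,
  $\mathrm{df} = n_a + n_b - 2$.
* **Multiplicity** — Holm step-down within each endpoint (family size 3).
* **Descriptives** — group mean, sample SD, and the
  $t_{0.975,\,n-1}$ interval. The t multiplier is deliberate: at $n = 9$ a
  normal multiplier gives visibly narrower intervals and does not reproduce
  published group intervals of this design, while the t form does (to the
  3-decimal precision such tables print — recomputation from rounded
  summaries can be off by one unit in the last digit).

## Responder signatures

Clustering operates on the standardized two-dimensional change vector
$(\Delta_\text{upper}, \Delta_\text{lower})$ (full-sample z-scores; the
scaler is retained).

* **Ward linkage** (`stats::hclust`, `ward.D2`) cut at $k$; candidates
  $k = 2\ldots4$ are scored by mean silhouette, and candidates whose
  smallest cluster has fewer than `min_cluster_size = 5` members are
  discarded before the silhouette maximum is taken (if all are discarded the
  guard is dropped with a warning). The threshold of 5 operationalizes
  "avoid very small clusters" at $n = 27$; at this sample size it rejects
  3-member clusters while keeping any near-balanced split, and the default is
  configurable. Note that agglomerative Ward is greedy: on well-separated
  data its $k = 2$ cut coincides with the global minimum within-cluster
  sum-of-squares partition (the property suite verifies this against a
  brute-force oracle), but on structureless point sets it can end one merge
  away from the optimum — an inherent property of the linkage, not of this
  implementation.
* **Bootstrap stability** — 2,000 replicates. Each replicate resamples the
  swimmers with replacement, refits Ward at the selected $k$, computes
  replicate centroids, assigns *every original* swimmer to the nearest
  centroid (Euclidean — Ward's own geometry), aligns replicate labels to the
  original solution by optimal maximum-overlap matching (exhaustive over the
  $k!$ assignments, ample for $k \le 4$; ties break to the lowest reference
  id), and records the adjusted Rand index plus each original cluster's
  Jaccard similarity with its matched counterpart. Replicates are placed in
  the *original* standardization space: re-standardizing per replicate would
  put centroids and original points on different scales and break the
  nearest-centroid assignment. Summaries are means, SDs, and percentile 95%
  intervals (percentile bounds, consistent with the other bootstrap
  summaries). With resampling disabled (`resample = FALSE`) the procedure
  returns ARI = Jaccard = 1 identically — a useful self-check that the
  alignment machinery is exact.
* **Association** — Pearson $\chi^2$ on the cluster-by-group table with a
  permutation null (group labels shuffled, both margins preserved), add-one
  p estimator.

## Exploratory prediction models

Features: two group indicators (CG reference — the control arm is the
natural baseline), a male indicator, and standardized years of training,
best 50 m time (seconds, so larger = slower; the sign of its coefficient
must be read against that direction), and baseline upper/lower composite
scores. Standardization happens once, at design construction; the scaler is
part of the design and is *not* recomputed inside cross-validation folds.
That choice makes the explicit leave-one-out loop coincide with the exact
linear-smoother identity $e_i / (1 - h_{ii})$, which the test suite uses as
an oracle at $10^{-8}$.

* **Ridge** — closed-form solve with the intercept unpenalized; penalty
  chosen from 25 log-spaced values in $[10^{-3}, 10^3]$ by leave-one-out
  squared error; reported as LOO RMSE and $R^2_{cv} = 1 - SS_{loo}/SS_{tot}$.
* **L2-logistic** — Newton iterations on the penalized log-likelihood
  (intercept unpenalized), penalty by LOO log-loss; reported as LOO accuracy
  (0.5 threshold) and mean log-loss in nats; predicted high-responder
  probabilities per group are evaluated at mean covariate values, with sex
  entered as its sample proportion (a fractional indicator — the standard
  "at the means" convention).
* **Uncertainty** — case-resampling bootstrap (2,000 replicates by default)
  at the selected penalty: percentile intervals and, for ridge, two-sided
  bootstrap p values $2\min(\Pr^*[\hat\beta \le 0], \Pr^*[\hat\beta \ge 0])$;
  for the logistic model, intervals for the three pairwise between-group
  log-odds contrasts. Logistic bootstrap draws that lose one outcome class
  are redrawn. The "high responder" class is the cluster with the larger
  mean $\Delta_\text{upper}$.

These models are exploratory by design: at $n = 27$ with correlated
predictors, the penalty does the work of keeping coefficients stable, and
the reference analysis reports no external numeric benchmarks for them, so
the test suite constrains them by properties (OLS limit, shrinkage limit,
LOO identity, CI/p consistency, planted-effect sign recovery) rather than by
target values.

## The synthetic cohort generator

The generator exists so that every downstream stage is exercisable without
any raw-data download. Per swimmer it draws a latent Pre score per domain
$\sim N(0,1)$, a latent *composite-unit* change per domain from the arm's
configured $N(\mu_g, \sigma_g)$ (defaults: the published group change
summaries, e.g. MSTG upper $0.962 \pm 0.129$), and interpolates Mid as
`mid_fraction` (default 0.5) of the change. Each indicator is the domain
latent plus an indicator-specific $N(0, \sigma_\text{noise})$ offset drawn
**once per swimmer and held fixed across time points** — stable individual
differences in specific tests (technique, anthropometry) rather than fresh
measurement error at every session. Two calibrations follow from this
structure:

* Baseline same-domain correlation is $1/(1 + \sigma_\text{noise}^2)$.
  Defaults $\sigma_\text{noise} = 0.309$ (upper) and $0.270$ (lower) put the
  baseline correlations at $\approx 0.913$ and $\approx 0.932$, hence PC1
  variance fractions of $\approx 0.957$ and $\approx 0.949$ — the
  published construct unidimensionality.
* The pipeline's composite change has asymptotic gain
  $c_p = \sqrt{p}/\sqrt{1 + \sigma_\text{noise}^2}$ over the latent change,
  so the generator divides the drawn composite-unit change by $c_p$ before it
  enters the latent. The full pipeline then recovers the configured
  $N(\mu_g, \sigma_g)$ in composite units (verified at $n = 2000$/arm).

Had the noise been redrawn at every time point instead, differencing would
add $\sqrt{2p}\,\sigma_\text{noise}/\sqrt{p(1+\sigma_\text{noise}^2)}
\approx 0.4$ composite units of SD to every $\Delta$ — incompatible with
change SDs as small as 0.058 alongside baseline correlations near 0.9. The
persistent-noise model is the one structure that satisfies both printed
features at once, which is why it is the package's generative assumption.

What the generator does **not** emulate: in-water outcomes; any sex effect on
the indicators (sex is generated for the design matrix but shifts nothing —
no sex-specific effects are published); cross-domain change correlation by
default (`delta_corr` exists as a knob, default 0, since no such correlation
is reported); Mid-point dynamics beyond linear interpolation (Mid is shown
only graphically in the source). Covariates (age, training years, best 50 m)
match the published per-arm summaries; sex counts per arm are deterministic
(3/9, 4/9, 3/9 women), mirroring sex-stratified allocation. Raw-scale
constants (e.g. bench press power $300 \pm 60$ W) are cosmetic; the analysis
is invariant to any consistent affine remapping of raw columns, and a test
asserts exactly that. Consequently, green tests on synthetic cohorts
demonstrate that the *machinery* is correct under the stated generative
model — they cannot certify distributional quirks of real swimmers
(skewness, outliers, indicator-specific training transfer) that the
generator does not model.

## Numerical and reproducibility choices

* One master seed; named child seeds per stage (simulation, each contrast's
  permutation and bootstrap stream, stability, association, each model)
  derived deterministically, so any stage can be rerun alone and the full
  report is byte-reproducible (`run_all` twice with the same seed gives
  identical JSON).
* Permutation and chi-square p values use the add-one estimator; tail
  comparisons use a relative $10^{-12}$ tolerance so the observed statistic
  always counts itself under floating-point noise.
* Ward merge order and the centroid-assignment tie (nearest centroid, ties
  to the lowest cluster id) are deterministic given row order.
* Degenerate inputs fail loudly and by name: zero-variance indicators at
  baseline, groups under 2 members, constant change columns, single-class
  outcomes, p values outside $(0, 1]$.
* Rendered tables round to three decimals and print p values with a
  `<0.001` floor; the JSON report keeps full precision.

## Problem sizes used in the test suite

The suite runs the full pipeline at the study's own scale ($27$ swimmers)
with procedure counts scaled to what property verification needs
(hundreds of permutations/replicates in structural tests, $10^5$
permutations where a tail probability itself is the claim); generator
calibration checks use 1,000–2,000 swimmers per arm. These sizes are the
package's choice of where each property is informative — e.g. Monte-Carlo
vs exact-enumeration agreement is only meaningful when the exact null is
enumerable, and centroid-gain calibration only stabilizes at large $n$.

## Known limitations

* Silhouette, ARI, Jaccard, and cluster sizes of the original study depend on
  its unavailable raw cohort; the package reproduces their *machinery* and
  checks ordering/limit behavior, not those exact values.
* The guard threshold (`min_cluster_size = 5`) and `mid_fraction = 0.5` are
  defaults standing in for unstated source choices; both are configurable
  and documented as assumptions.
* Repeated-measures/mixed longitudinal models are out of scope; the pipeline
  analyzes Post−Pre change scores only.
* Bootstrap percentile intervals at $n = 9$ per arm undercover slightly (a
  known small-sample property; the coverage test asserts a realistic band,
  not the nominal rate).
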
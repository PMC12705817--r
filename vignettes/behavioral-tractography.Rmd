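---
title: "Behavioral tractography of experience-sampling data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral tractography of experience-sampling data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ematract)
```

## The problem

Ecological momentary assessment (EMA) samples psychological states many times
a day on a smartphone — here 20 items (19 on a 1–7 Likert scale plus a binary
`Being-Alone` context flag), nominally 8 prompts/day over 6 days, with
roughly half the prompts completed. Two questions drive the analysis:

1. Do the *between-subject* clinical patterns measured by a structured
   interview (18 items scored 0–6) map onto the *within-subject* dynamic
   structure of momentary states?
2. Which dynamic pathways carry a state at one assessment into states at the
   next, and how do those pathways differ between clinical subgroups?

`ematract` implements the full chain: clinical dimensionality reduction,
mixed-model network estimation, network embedding, 3D multilayer assembly,
shortest-path "tractography", bundle clustering, and a permutation test for
group differences in bundle trajectories — together with a synthetic cohort
generator so every stage can be validated against known ground truth.

## Clinical dimensions

Items endorsed by at most 10% of subjects are removed
(`filter_rare_items()`; the screen that excludes rarely reported grandiosity
scores). The remaining subjects × items matrix is decomposed by
mean-centered, unscaled PCA (`fit_sips_pca()`); components whose variance
fraction strictly exceeds 10% are retained. Covariance-matrix PCA is the
default because interview items share a common 0–6 scale; a
correlation-matrix switch (`scale. = TRUE`) is provided since the choice is
a genuine free parameter.

PC signs are arbitrary, so they are fixed deterministically: component 1 is
oriented so its mean loading is positive (a severity dimension loads
positively on every item), and each later component so its largest-magnitude
loading is positive. Subgroups are formed by 1-D k-means on one component's
scores (`assign_subgroups()`, k = 2, 50 restarts, seeded); in one dimension
this is equivalent to the best single-threshold split, which the tests check
by brute force.

Group contrasts use the uncorrected Pearson chi-square for 2×2 tables and
the pooled-variance two-sample t-test, computable from summary statistics —
these reproduce published demographic tables to their printed precision,
which is how the implementation is pinned down (Yates-corrected statistics
do not reproduce them). Item-intensity contrasts across subgroups are
observation-level t-tests: all prompts pooled, which treats repeated
observations per subject as independent. That pseudo-replication is
deliberate — it mirrors how such tables are computed in practice — and the
per-item correlation with the dimension score (subject-mean intensity vs
score) is reported alongside as the subject-level quantity.

## Edge estimation

The association between items x and y is the fixed slope of a
random-intercept mixed regression fitted by REML:

$$Y_{ij} = \beta_0 + \beta_1 X_{ij} + u_j + \varepsilon_{ij},$$

with \(u_j\) a per-subject intercept absorbing stable intensity differences.
Cross-sectional edges pair items within one prompt; lagged edges pair item x
at prompt *t* with item y at prompt *t + 1*. The default pairing rule
(`same_day_consecutive`) requires both prompts completed, on the same day,
with consecutive prompt indices — a missed prompt breaks the pair and
overnight transitions are excluded, since the 9.5-hour overnight gap is not
comparable to the ~2-hour within-day gap. An `any_consecutive` rule is
available for sensitivity analysis.

Items are z-scored over pooled observations before every regression so that
slopes are on a common scale and usable directly as edge weights. When a
generative coefficient on the raw scale is the target (as in the recovery
tests), `scale = FALSE` turns this off.

Moderation by a clinical dimension adds the subject-level score and its
interaction:

$$Y_{ij} = \beta_0 + \beta_1 X_{ij} + \beta_2 S_j + \beta_3 (X_{ij} S_j)
  + u_j + \varepsilon_{ij},$$

where \(\beta_3\) measures how within-subject coupling changes with the
score; \(S_j\) is z-scored at the subject level.

Because a 20-item analysis fits 380 cross-sectional and 400 lagged models
(and the permutation test refits all of them hundreds of times), the package
uses its own profiled-REML fitter for this one model class: per-subject
sufficient statistics reduce the fit to a one-dimensional optimization over
the variance ratio \(\sigma_u^2/\sigma_e^2\). The unit tests verify it
against `lme4::lmer` to six decimals on coefficients and standard errors.
Wald p-values use a t reference with residual degrees of freedom. A
zero-variance solution falls back to ordinary least squares and is flagged
`singular`.

Edges are pruned by Benjamini–Hochberg FDR at q = 0.05, with one family per
matrix kind (all 380 ordered cross-sectional pairs; all 400 lagged pairs).
Non-significant slopes are set to zero. The cross-sectional matrix is
symmetrized as the mean of the two directional slopes, zero counting as
zero; the directional reduction is unstated in the source analyses, and
averaging is the symmetric choice that preserves magnitude when both
directions agree. The multilayer 40×40 matrix holds the symmetrized
cross-sectional block twice (TL1, TL2), the lagged block TL1→TL2, and a
structurally zero TL2→TL1 block.

One deliberate deviation: a strict "≥ 3 distinct pooled values" rule for
item inclusion would always exclude the binary `Being-Alone` flag and
silently shrink the network to 19 nodes; binary 0/1 items with both levels
present are therefore exempt from the rule.

## Network embedding (NDR)

The symmetric cross-sectional matrix is embedded by PCA of the adjacency
matrix; each node's coordinates are its loadings on the first two
components. The adjacency diagonal has no data value, so a convention is
needed: the default sets each diagonal entry to the node's mean off-diagonal
weight, which keeps component 1 from simply contrasting the diagonal; a zero
diagonal is available as a config switch. Coordinates are scaled to max
|value| = 1 per axis so in-plane distances are commensurate with the unit
inter-layer gap of the 3D assembly. Axes are oriented deterministically
(anchor item `Hallucinations` gets negative x; affective-distress items get
positive mean y), reproducing the conventional left-cognitive /
upper-distress layout; on networks without those items the lexicographically
first nodes serve as fallback anchors, which keeps the embedding equivariant
under node permutations.

Embedding fidelity is the Pearson correlation across unordered node pairs
between embedded Euclidean distance and edge weight; on structured networks
it should be negative, and the test suite requires r < 0 with p < 0.01 in at
least 95% of 20 synthetic two-community cohorts.

## 3D assembly and tractography

Nodes are duplicated at z = 0 (TL1) and z = 1 (TL2). Every retained edge
becomes a traversable segment with length 1/|weight| — the absolute value is
used so that strong negative couplings also conduct paths; the weight's sign
is kept as metadata. Within-layer edges are bidirectional; between-layer
edges run only TL1→TL2, so any TL1→TL2 path makes exactly one forward time
transition by construction.

For every ordered (TL1 item, TL2 item) pair the minimum-length path is found
by Dijkstra's algorithm with deterministic tie-breaking: shorter length,
then fewer hops, then the lexicographically smaller node-name sequence.
Label equality uses a 1e-9 relative tolerance so that floating-point
summation order cannot flip a tie. The tests verify 100% agreement with
exhaustive simple-path enumeration on hundreds of random graphs.

Each path is summarized by four anchors — Start-TL1, Exit-TL1 (last z = 0
node), Entry-TL2 (first z = 1 node), End-TL2 — giving a 12-vector that is
clustered by k-means into bundles (50 restarts, seeded). `k = "auto"`
selects k in 4..12 by mean silhouette width; a fixed k (9 is the reported
granularity on real cohorts) is recommended when comparing populations.

Behavioral diffusion analysis (BDA) assigns each node the mean displacement
toward its successor over all traversing paths (terminal TL2 nodes use the
predecessor-to-node displacement). The exact formula is not fixed by the
source analyses; the successor-displacement mean is this package's
documented choice, and dz ≥ 0 always holds because paths only move forward
in time. Longitudinal betweenness counts traversing shortest paths per node
and per edge.

## Two-population comparison

Populations A and B each get their own networks and paths, but share one
embedding (by default the pooled-sample embedding — whether the source
procedure recomputes embeddings per population is unstated, and holding the
frame fixed makes anchor coordinates directly comparable). Paths are matched
by (start, end) item pair; only pairs reachable in both populations enter.
The joint 18-vector (Start, Exit-A, Exit-B, Entry-A, Entry-B, End) is
clustered so each bundle connects a shared set of TL1→TL2 variables while
allowing population-specific trajectories.

The divergence statistic for a bundle is the mean Euclidean distance between
the A- and B-trajectory parts (exit and entry coordinates) across its
matched pairs, divided by the mean within-population pairwise distance among
the bundle's 12-vector anchors. The null distribution permutes subjects
across populations (preserving sizes), rebuilding both networks and all
paths per permutation while holding the embedding and the bundle's pair set
fixed — the test asks whether *these* trajectories differ, not whether
bundle membership would re-form. p is the proportion of permuted statistics
at least as large as the observed one (granularity 1/n_permutations;
attainable minimum 0). Permutations in which no bundle pair is reachable in
both permuted populations yield no statistic and are excluded from the
proportion; at the configured effect sizes this is rare.

## The synthetic cohort generator

Latent item intensities follow a first-order vector autoregression with
subject random intercepts: within each day,
\(L_t = u_j + B(L_{t-1} - u_j) + e_t\), with innovations whose precision
matrix is \(I - C\) (so `cross_coupling` entries are contemporaneous partial
associations; they must satisfy positive definiteness, roughly
c × (block size − 1) < 1), and `lag_coupling` B constrained to spectral
radius < 1. The latent state re-initializes each morning at the subject mean
plus one innovation, so the same-day pairing rule matches the generative
process — within- vs between-day autocorrelation is not characterized in
the source data, and the day-reset is one defensible choice. Latent values
are discretized by six fixed thresholds (default ±0.5, ±1.5, ±2.5);
`Being-Alone` is an independent Bernoulli flag (p = 0.36, the observed
endorsement level); prompts are completed independently with probability
`compliance` (default 0.52 ≈ 25/48, the observed completion level). Defaults
mirror the study conditions: 68 subjects, 20 items, 8×6 design.

This linear-Gaussian model is exactly the class the estimation equations
assume — which is the point: recovery tests then have unambiguous ground
truth. Real EMA data are not Gaussian, are not missing completely at random,
and have skewed, floor-heavy Likert distributions; passing recovery tests
demonstrates the estimator implements its model correctly, not that the
model is right for any particular dataset. Likert discretization attenuates
raw-scale slopes by roughly 5–10%, which the ±0.1 recovery tolerances absorb.

The clinical table is generated from two latent traits (severity, tied to
the subject's mean intensity; and a signed contrast) through an 18×2 loading
matrix with round-and-clip to 0–6.

## Validation suite and problem sizes

The acceptance checks (also recomputed by `scripts/acceptance.R`) are:

* worked 2×2 chi-square and pooled-t examples reproduced to printed
  precision (< 1 s);
* slope recovery: 50 cohorts of 60 subjects × 20 observations, true slope
  0.5 — seed-averaged estimate within 0.03; interaction recovery within 0.1
  of 0.3;
* FDR null calibration: 20 null cohorts at the full study design — at most
  8% of edges retained at q = 0.05;
* shortest-path oracle: 200 random graphs of 3–8 items, 100% agreement with
  exhaustive enumeration;
* bundle recovery: adjusted Rand index 1.0 on two well-separated synthetic
  path families;
* permutation-test calibration: 100 null simulations × 19 permutations
  (scaled down from the production default of 500) on 6-item, 14+14-subject,
  6×4-prompt cohorts — rejection rate at α = 0.05 inside [0.01, 0.10], and a
  Kolmogorov–Smirnov check of p-value uniformity;
* NDR faithfulness: 20 two-community cohorts at the study design, embedding
  accuracy r < 0 with p < 0.01 in ≥ 95%.

These sizes were chosen once, as the smallest configurations at which each
property is informative; none is tuned to any particular observed outcome.

### Calibration of the divergence test: what holds and what does not

Two structural properties of the divergence statistic limit how uniform its
null p-values can be:

* **Exact ties.** Anchor coordinates are node positions, so the statistic
  depends on the data only through *which routes* the shortest paths take.
  When networks are dense and stable, many permutations reproduce exactly
  the observed routes, the permuted statistic equals the observed one, and —
  since ties count toward `p` under the `>=` convention — p-values
  accumulate at 1. This is conservative (it never inflates rejections) but
  visibly non-uniform.
* **Bundle selection.** Bundles are clustered on the observed populations'
  paths, so the observed within-bundle spread is smaller than that of a
  random pair set; permuted statistics are computed on recomputed paths
  without that selection. In high-noise regimes this inflates the observed
  ratio relative to the null.

A third pathology is handled explicitly: when a permuted split yields
networks in which the bundle's pairs are unreachable, that permutation has
no statistic. A p-value over a handful of surviving permutations is not
interpretable, so `bundle_divergence_test()` returns `NA` (with a warning)
whenever fewer than half the permutations are valid — the analogue of its
requirement that a testable bundle have at least two matched pairs.

Under the calibration conditions above, the rejection *rate* at α = 0.05 is
well controlled, which is what matters for the substantive use of the test
(flagging bundles whose trajectories differ between populations). Full
distributional uniformity is not attained: the tie mass at p = 1 makes a
strict KS uniformity test reject. Users should read small p-values at face
value and large ones as "no evidence", not as calibrated quantiles.

## Known limitations

* The estimator is massed pairwise regression, not a joint (e.g.
  graphical-lasso) model; edges are marginal-style associations, and no
  regularized alternative is provided by design.
* The divergence statistic is route-based and therefore discrete; its null
  p-values are conservative (mass at p = 1) when networks are dense and
  stable (see above).
* Observation-level subgroup t-tests pseudo-replicate; use the subject-level
  correlations when inference at the subject level is needed.
* The permutation test holds the bundle definition fixed; it does not test
  bundle membership stability.
* With ~16 subjects per population at realistic compliance, FDR-pruned
  networks can be sparse enough that some item pairs are unreachable; the
  path census reports (rather than imputes) unreachable pairs.
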
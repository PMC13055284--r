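---
title: "Methods: ordination geometry of microcosm time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ordination geometry of microcosm time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what the synthetic data can and cannot
tell you about real amplicon studies.

## The analysis model

The package treats a longitudinal inoculation experiment as a set of
per-replicate *trajectories* through a community state space. The state
space is never observed directly: it is induced by (a) a dissimilarity
measure over samples and (b) an embedding of that dissimilarity at a
chosen dimensionality `d`. Every downstream quantity — direction cosines
between control and inoculated displacement vectors, smoothness,
linearity, treatment SNR, kNN statistics, the Hopkins statistic, and
PERMANOVA on embedding-reconstructed distances — is a function of that
`(dissimilarity, method, d)` triple. The package's central design
decision is to make `d` an explicit swept parameter (default
`{2, 3, 4, 7, 10, 15, 20, 30, 70}`) rather than a fixed preprocessing
choice, because treatment effects that are invisible at `d = 2` can be
both visible and statistically significant at intermediate `d` (the
dimension-swept PERMANOVA in `run_pipeline()` demonstrates this on the
default synthetic study).

## Dissimilarities

*Bray–Curtis* is computed on raw counts, not relative abundances and with
no rarefaction, matching the default behaviour of the classical community
ecology implementations. This means unequal library sizes contribute to
dissimilarity; the synthetic generator draws library sizes from a Poisson
around a common mean, so this contribution is small but present.

*Weighted UniFrac* places relative abundances on the leaves of a rooted
tree and accumulates branch-length-weighted mass differences. The
normalised variant (divide by `Σ ℓ_b (p_b + q_b)`, range [0, 1]) is the
default because it is what the widely used implementations return for
"weighted UniFrac"; the raw form is available through
`normalized = FALSE`. Whether to normalise was an open choice; both are
exposed and the pipeline records which was used.

*rCLR* log-transforms observed counts and centres each sample over its
observed features only; zeros become missing values rather than being
imputed. The minimum-feature-count pre-filter (default 8) removes
ultra-rare features whose single observations would otherwise dominate
the completion step. The separate low-count table filter used by the
pipeline (default 10) mirrors the common practice of discarding sequences
with fewer than ten molecule counts across the whole study.

## Embeddings

*PCoA* is classical scaling: double-centre `−½ J D² J`, eigendecompose,
scale eigenvectors by the square roots of the positive eigenvalues. No
Cailliez/Lingoes correction is applied. Requesting more axes than there
are positive eigenvalues is an explicit error, and the sweep records such
dimensions as skips: with 90 samples a semi-metric dissimilarity
typically supports far fewer than 70 positive axes (the default seed-1
pipeline run has 42), and we prefer reporting that feasibility boundary
over fabricating axes.

*Sammon mapping* minimises
`E = (Σ d_ij)⁻¹ Σ (d_ij − δ_ij)² / d_ij` by gradient descent with step
halving. The step-halving line search only ever accepts a configuration
with lower stress, so the stress trace is non-increasing by construction —
this is asserted in the tests rather than assumed. Initialisation is the
PCoA configuration at the same `d`; zero off-diagonal dissimilarities
(duplicate samples) are an error with advice, because the `1/d_ij`
weights are undefined there and silent jitter would change the objective.
Convergence: absolute stress change below `tol` (default 1e-9) or
`max_iter` (default 500).

*NMDS* minimises Kruskal stress-1 with isotonic regression of embedded
distances on the rank order of the input dissimilarities, refit at every
line-search evaluation so the accepted stress is always the true
stress-1. Community-table standardisations (autotransform, Wisconsin)
are deliberately omitted: the input here is an already-computed distance
matrix, not a community table. Local minima are handled by multi-start
(one PCoA start plus seeded random starts, default 20 total); the
lowest-stress solution is returned and the winning start recorded. The
start count and iteration cap were open choices; the defaults (20 / 300)
follow common practice for this family of optimisers.

*Robust Aitchison PCA* completes the masked rCLR matrix at rank `d` by
iterative SVD imputation: missing entries start at zero (the row-centred
neutral value), the matrix is decomposed, missing entries are refilled
from the current rank-`d` reconstruction, and the loop stops when the
reconstruction's relative Frobenius change drops below `tol` (default
1e-7). Sample scores are left singular vectors scaled by singular
values. The completion engine is oracle-tested on planted low-rank
matrices with known masked entries.

All embeddings are column-centred and sign-fixed (largest-magnitude
coordinate of each axis positive), so repeated runs and cross-method
comparisons are deterministic given the seed. External embedding methods
(e.g. UMAP or phylogeny-aware RPCA variants) are not re-implemented; any
externally computed coordinate matrix can be wrapped with
`new_embedding()` and fed to every downstream stage, which is the
intended adapter route.

## Trajectory geometry

Displacement vectors are coordinate differences between two sampling
days. Control-vs-inoculated comparison pairs every control replicate
with every inoculated replicate of the same soil (all-vs-all, 9 pairs for
a 3 × 3 design) and reports the plain arithmetic mean and SD of the
cosines — no Fisher transform, because the averaged quantity of interest
is the cosine itself. Cosines are clamped into [−1, 1] after
floating-point rounding. Smoothness averages cosines of successive
segments; zero-length segments are an error rather than silently skipped,
since skipping would bias the average upward. Replicates missing an
endpoint day are excluded from pairwise comparison with a warning;
trajectories missing an interior day simply use their surviving
consecutive segments.

## Dimension diagnostics

SNR pools all same-soil/same-day pairs into a single between-treatment
and a single within-treatment mean (a per-stratum option exists). The
kNN statistic averages each point's mean distance to its `k = 5` nearest
neighbours; a `kth`-neighbour variant is exposed because "mean kNN
distance" is ambiguous between the two readings. The CV uses the
population SD, treating the point cloud as the full population of
interest. The Hopkins statistic follows the classical nearest-neighbour
scheme: `m = 50` real points sampled without replacement, `m` uniform
probes in the data's axis-aligned bounding box, `H = Σu/(Σu + Σw)` with
plain (unexponentiated) distances. Calibration is verified by
simulation: uniform clouds give `H ≈ 0.5`, well-separated tight clusters
give `H > 0.9`.

## PERMANOVA

Sums of squares are sequential (Type-I) on the Gower-centred matrix in
the stated term order (`soil`, `day`, `treatment` for the global model),
computed through projection hat matrices; `day` is categorical.
Permutations are free (unrestricted) label permutations; p-values use the
+1 correction and a small relative tolerance when comparing permuted to
observed F so that permutations reproducing the observed grouping count
as ties rather than falling below the cutoff through floating-point
jitter. The implementation is verified three ways: against an
exhaustive-enumeration oracle at n = 6, against `vegan::adonis2` on a
larger synthetic table, and by a 500-run type-I-error calibration on
exchangeable synthetic data. Per-soil models pool time points and test
treatment only; the permutation count default is 999.

## The synthetic generator

The generator emulates the design of a three-soil inoculation microcosm
study: 3 soils × 2 treatments × 3 replicates × 5 sampling days
(0, 14, 28, 57, 249), 500 features, expected library size 1e5. Its
pieces:

- **Baselines.** Per-soil Dirichlet concentration profiles; by default a
  shared heavy-tailed log-normal core (sd 2) plus a per-soil deviation
  (sd 1.2), so soils are clearly distinct but share dominant taxa. This
  produces the soil ≫ time > treatment variance ordering in global
  PERMANOVA that such studies report (seed-1 default run: R² ≈ 0.66 /
  0.03 / 0.025 on Bray–Curtis).
- **Drift.** A fixed per-soil direction in log-composition space with
  magnitude `drift_scale · sqrt(day / max(day))` (default scale 16),
  shared by both treatments.
- **Divergence.** For inoculated microcosms the drift direction is
  rotated by a per-soil angle (defaults 0.20, 0.28, 1.25 rad, i.e.
  cosines 0.98, 0.96, 0.31 — nearly parallel in two soils, divergent in
  the third). The angle is imposed on the *realised* composition
  displacement rather than the raw log-space direction: the soft-max map
  from log perturbations to relative abundances re-correlates directions
  that are orthogonal in log space (their images' cosine can reach
  0.8–0.9), so the mixing angle is solved numerically (`uniroot` on the
  displacement cosine) such that the expected first-to-last-day
  displacements of the two treatments meet at the requested angle.
- **Treatment shift.** A constant per-soil log-space offset (default
  norm 0.8) applied to inoculated samples only; it cancels in
  displacement vectors but separates the treatment clouds.
- **Inoculant.** One designated feature is imposed at a Day-0 fraction
  (default 0.05) in inoculated samples and decays log-linearly in time to
  per-soil residual fractions (defaults 0.05%, 0.17%, 0.33% — the
  soil-ordering reported for long-term inoculant persistence). Controls
  carry exactly zero. The Day-0 fraction is a free parameter of the
  emulation, not a reported value; 5% was chosen as a plausible
  post-inoculation spike that is large against the residuals yet far from
  dominating the community.
- **Noise.** Counts are Dirichlet-multinomial: gamma perturbation of the
  expected composition at precision `overdispersion` (default 200),
  multinomial at a Poisson library size. Replicate spread at this
  precision is what makes the treatment effect small-but-significant
  rather than trivial.

All draws flow from one master seed through named substreams
(`substream_seed`), so any stage can be re-run in isolation with the
draws it saw inside the pipeline.

**What the generator does not emulate.** Real amplicon data have
phylogenetically structured effects: related taxa respond similarly, so
directional changes survive branch-aggregation in UniFrac. The synthetic
tree is an independent random coalescent, so weighted UniFrac *smooths*
the control/inoculated divergence (branch aggregation re-correlates the
two displacement directions), and the per-soil divergence pattern is
therefore clearest in Bray–Curtis-based geometry and attenuated in
UniFrac-based geometry. Passing tests on synthetic data demonstrate that
the machinery is correct and calibrated — not that any particular real
study's effect sizes will reproduce. Taxonomic identity, chimeras, UMI
errors and compositional mean-variance relationships beyond the
Dirichlet-multinomial are likewise out of scope.

## Numerical choices and degenerate inputs

- Distance matrices must be symmetric within 1e-12 with an exactly zero
  diagonal; Bray–Curtis of an all-zero sample is an error naming the
  sample (not 0), since its composition is undefined.
- PCoA positive-eigenvalue threshold: `max(|λ|) · 1e-9`.
- Sammon/NMDS step halving: up to 30 (Sammon) / 20 (NMDS) halvings per
  iteration; failure to improve terminates the optimisation at the
  current (best-so-far) configuration.
- Embedded distances are clamped at 1e-12 inside gradients to avoid
  division by zero for near-coincident points.
- Hopkins errors on a degenerate (all-coincident) bounding box; kNN CV is
  defined as 0 with a warning when all neighbour distances are zero.
- Chao1 uses the bias-corrected substitute `F1(F1−1)/2` when there are no
  doubletons, so the estimator is always finite and ≥ observed richness.

## Problem sizes used by the test suite

Tests run the full default study (90 samples × 500 features, nine
dimensionalities, 999 permutations) end-to-end twice to verify
determinism, a 500-run permutation-test calibration at n = 12 per run, a
100-restart Sammon oracle on 10-point instances, and a 720-permutation
exhaustive PERMANOVA enumeration at n = 6. These sizes keep the whole
suite in the low minutes on a single CPU while still exercising every
code path at the scale of the default study design.

## Known limitations

- Sammon and NMDS find local optima; the multi-start and
  oracle-comparison tests bound, but do not eliminate, this risk.
- PERMANOVA permutations are free; designs needing restricted permutation
  strata (e.g. repeated measures within replicate) are not modelled.
- The d = 70 entry of the default sweep is infeasible for eigenvalue-
  bounded methods on 90-sample semi-metric inputs and is reported as a
  skip; only RPCA (bounded by `min(n, p)`) reaches it.
- `cos θ` between high-dimensional noisy displacement vectors is biased
  toward 0 by noise; the package reports plain means and SDs and leaves
  attenuation corrections to the analyst.
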
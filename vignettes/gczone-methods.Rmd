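---
title: "Models and methods behind gczone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gczone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gczone` quantifies the spatial organisation of one germinal center (GC):
which cells belong to the dark zone (DZ) or light zone (LZ), where the
boundary between the two regions runs, and how T-cell subtypes distribute
across that boundary. This vignette explains the models, the parameters
that matter, the numerical conventions, and the design decisions that were
genuinely open — in enough detail that a maintainer could re-derive every
choice.

## Scoring and classification model

Scores are computed on a QC-filtered, normalized matrix. QC keeps cells
with strictly fewer than 3,000 detected genes and strictly more than 400
total counts; both inequalities are strict, so cells exactly at a threshold
are excluded. Normalization is median-library-size scaling, `log1p`, then
per-gene z-scaling; a gene constant across cells is mapped to z = 0 rather
than NaN, a convention that makes scores of degenerate panels well defined.
No highly-variable-gene restriction is applied before scoring: HVG
selection serves embedding pipelines, and restricting the scoring universe
would silently drop signature genes.

The default signature score is the mean z-scaled expression over the
signature genes present in the matrix (`mean_z`). Signature-to-panel
matching is case-sensitive exact symbol matching; unmatched genes are
skipped and their fraction reported, because signature and panel
vocabularies routinely differ. A second method (`ctrl_bins`) subtracts, per
signature gene, the mean of 50 control genes drawn (seeded) from the same
average-expression bin of 25 bins — the expression-matched control practice
common in single-cell module scoring. `mean_z` is the default because it is
parameter-free and deterministic without a seed; on the synthetic tissues
the two methods correlate above 0.9, and both are exposed so the choice is
recorded rather than hidden.

Classification uses the combined score `s = score_DZ − score_LZ` with
thresholds `s > 0.3` → DZ, `s < −0.3` → LZ, and intermediate (INT)
otherwise. The thresholds are parameters (`upper`, `lower`) because the
score scale depends on signature size and scoring method; ±0.3 are the
defaults used throughout.

Bulk samples are stratified with the same score logic, with genes z-scaled
across samples. The grouping rule was an open choice; the default ranks
samples by the combined score and takes the top and bottom thirds
(`floor(n/3)` samples each) as DZ-like and LZ-like — deterministic, scale
free, and it yields three comparably sized groups. A k-means (k = 3)
alternative on the combined score is provided for cohorts where the group
sizes should be data driven.

## Region formation on the spatial graph

The cell graph connects every pair of cells within `neighbor_radius`
(default 30 µm, roughly two to three lymphocyte diameters: small enough
that neighborhoods are local, large enough that the graph stays connected
at typical GC cell densities). Construction uses grid bucketing, so only
nearby candidate pairs are examined; the test suite checks the edge set
against brute-force thresholding of the full distance matrix.

Region formation runs synchronous (Jacobi-style) sweeps until a fixpoint:

* an INT cell takes the majority phenotype among its neighbors' *current*
  DZ/LZ labels, so assignments propagate inward across sweeps; exact ties
  (including no labeled neighbor) keep INT;
* a DZ or LZ cell flips when the fraction of its neighbors holding the
  opposite phenotype *among the original calls* strictly exceeds
  `dissimilar_fraction` (default 0.5).

Two schedule decisions deserve justification. Synchronous updates with
ties keeping the current label make the result independent of cell order —
an asynchronous sweep would make the segmentation depend on an arbitrary
cell indexing. Evaluating the flip rule against the original calls, not
the evolving labels, makes it a one-shot cleanup of isolated misclassified
cells; a flip rule on current labels lets a majority region erode a
genuine minority region front cell by cell (and, under synchronous
updates, admits two-cycles in which a frontier oscillates forever). With
the static rule the INT-propagation dynamics still iterate, but flips
cannot cascade. Oscillation remains possible in adversarial configurations
(a cell whose original neighborhood is exactly half-and-half at a low
threshold), so the sweep loop is guarded by `max_iter = 100` and raises an
error rather than returning a non-converged labeling. Convergence is
defined as a sweep with zero changes, and that confirming sweep is counted
in `n_iterations`.

Residual INT cells (no labeled neighbors at convergence) stay
`unassigned`; they are excluded from both regions and count against
neither purity. Purity is the fraction of cells in each final region whose
*original* phenotype matches the region (DZ region vs original DZ calls,
and likewise LZ); measuring purity against the smoothed labels would be
circular — it approaches 1 by construction — whereas against the original
calls the ≥ 70% requirement actually constrains how much relabeling the
smoothing performed. Boundary extraction refuses to run when either purity
is below `min_purity` (default 0.70).

The boundary itself is deliberately simple: the midpoints of all edges
joining a DZ-region cell to an LZ-region cell, ordered by projection onto
the first principal axis of the midpoint cloud (principal-axis sign fixed
to the first non-zero positive component, so the ordering is
deterministic). This is invented plumbing — many curves separate two
labeled regions — chosen because it is local, parameter free, and testable:
on synthetic tissue the vertices track the true chord to well within one
neighbor radius. Signed distance uses the nearest boundary *vertex* rather
than polyline-segment distance; with cross-edge midpoints the vertex cloud
is dense along the interface, the two quantities differ by less than the
inter-vertex spacing, and the nearest-vertex form has a trivial
brute-force oracle. The sign comes from the region of the nearest
region-labeled cell (negative = DZ side); cells exactly on a vertex get 0.

## Enrichment profile and the Monte-Carlo envelope

Cells are binned by signed boundary distance into 10-µm bins over
−100…100 µm (20 bins). Bins are half-open `[lo, hi)` with the last bin
closed at +100 so the range endpoint is not silently dropped. The per-bin
mean of a per-cell value is the enrichment level; the default value is the
0/1 subtype indicator, making the bin mean the subtype fraction — the
"enrichment" notion is ambiguous in general, so a continuous per-cell
score column is accepted as an alternative. The slope comes from
unweighted OLS of bin means on bin centers; empty bins are excluded from
the fit rather than imputed (bin occupancy is reported, so emptiness is
visible).

The null model for the slope is label permutation over the observed cell
positions with the subtype count fixed — not uniform re-placement in the
plane — so the null conditions on the tissue geometry: a cell-density
gradient across the window widens the envelope instead of being mistaken
for subtype structure. Each of `n_sim` replicates (default 10,000) assigns
the subtype to a uniformly random subset of in-range positions and refits
the slope; the 2.5/97.5 percentiles form the 95% envelope, and the trend
call is `increasing` above it, `decreasing` below it, `random` inside.
Under complete spatial randomness the call is `random` for ≈ 95% of
simulated datasets, which the test suite verifies over 200 replicates.

Power guidance, computed by the same simulations: with a 150-cell subtype
among 3,000 cells, a logistic gradient that doubles the enrichment from
the DZ edge to the LZ edge of the ±100 µm window places the expected
observed slope only about two null standard deviations above zero, so the
three-way call detects it in roughly half of replicates; reliable
detection (≥ 80%) needs an edge-to-edge enrichment ratio around 2.5–3, or
proportionally more subtype cells. The envelope is a calibrated test, not
a powerful one, at small subtype counts.

The nearest-neighbor exclusion test compares observed A→B nearest-neighbor
distances against `n_rand` label permutations over the pooled positions
(group sizes fixed), pooled into one null sample, with a two-sided
Wilcoxon rank-sum test (exact for small samples, normal approximation with
continuity correction otherwise; a zero-variance tie-only comparison
returns p = 1). The randomized control is again a positional permutation
rather than uniform placement, for the same geometry-conditioning reason.
Direction is `excluded` when the observed median exceeds the null median
at p < α.

## The synthetic generator

`generate_gc()` emulates exactly the tissue structure the pipeline
assumes: cells uniform in a disc (default radius 150 µm, a typical tonsil
GC scale), a straight chord boundary whose offset is solved from the
requested DZ area fraction, negative-binomial counts (default dispersion
1, matching the overdispersion of real single-cell counts; Poisson is the
dispersion → ∞ limit), and signature genes whose zone mean is multiplied
by `exp(signature_effect)`. With the default dispersion the per-gene
log-expression SD is close to 1, so `signature_effect` reads approximately
in SD units; the default 1.5 produces the clear but imperfect zone
polarization seen in real GCs (combined scores separate by ≈ ±0.8 around
the ±0.3 thresholds). `label_noise` re-draws a fraction of cells from the
opposite zone's expression profile while the truth table keeps their
geometric zone — emulating mixed phenotypes near the interface without
moving cells.

Subtypes are subsets of the generated cells, so they inherit the tissue
geometry. A logistic subtype includes each cell independently with
probability `plogis(alpha + beta * d)` in the signed distance `d`, with
`alpha` calibrated by root finding so the expected size hits the target;
the realized size is then binomial around it. A fixed-size weighted draw
without replacement was considered and rejected: sequential weighted
sampling does not follow the logistic model it is meant to plant, and the
independent-Bernoulli scheme is the one under which logistic regression of
membership on distance provably recovers `beta` (the test suite recovers
it within a few percent at n = 10,000). CSR subtypes, whose size is a
hard condition of the envelope analyses, are exact-size simple random
samples. Everything is reproducible from the single config seed.

What the generator does *not* emulate: segmentation errors and doublets,
platform-specific noise (probe efficiency, background), curved or diffuse
zone interfaces, 3D structure, and multiple GCs per field. Passing tests
on synthetic tissue therefore validate the algorithms under their stated
assumptions — a polarized disc with a straight interface — not robustness
to every artifact of real spatial data.

## Problem sizes and numerical conventions

The test suite exercises: 2,000-cell GCs (50 replicates) for the purity
contract; 200 datasets × 1,000 permutations for envelope calibration and
power; 10,000 cells for gradient recovery; and 200-cell instances against
brute-force oracles for graph construction and signed distances. These
sizes were chosen so the full suite runs in about a minute while keeping
Monte-Carlo standard errors small relative to the tolerances tested
(e.g. coverage SE ≈ 1.5 percentage points at 200 datasets).

Numerical conventions worth knowing: QC inequalities are strict; score
thresholds are strict (a combined score of exactly ±0.3 is INT); the
purity requirement is inclusive (exactly 70% passes); smoothing ties keep
the current label; the OLS slope is fitted by least squares with no
weighting; envelope percentiles use R's default quantile definition; and
every stochastic operation (control-gene draws, Monte-Carlo replicates,
permutation nulls, the generator) takes an explicit seed, with the
pipeline deriving per-stage seeds from one master seed.

## Known limitations

One GC per run: multi-GC fields must be cropped upstream (a batch loop
over crops reproduces the multi-GC setting). The boundary is a vertex
cloud ordered along one principal axis; strongly curved interfaces would
need a curve-fitting step. The envelope test treats cells as exchangeable
under the null; spatial autocorrelation of subtype labels beyond what
position permutation captures is not modeled. And the packaged DZ/LZ gene
lists are a synthetic stand-in with the published sizes and a canonical
marker core — analyses of real tissue should supply the published
signature via `read_signatures()`.
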
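---
title: "Individualized tau-PET networks: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized tau-PET networks: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taunet)
```

## The model

Tau pathology in the Alzheimer's continuum spreads along a fairly
stereotyped anatomical route — entorhinal and limbic structures first,
isocortex later — and the amount *and* spatial heterogeneity of tracer
uptake both carry information. taunet encodes a single subject's tau
topography as a weighted, undirected graph. Nodes are small, equal-sized
samples of each atlas region: a 3×3×3 block of 2-mm voxels (a 6-mm cube)
centered on the region, which keeps every node's estimate equally precise
and avoids region-size confounds. Writing x̄ᵢ for the mean SUVR over node
i's cube, the edge weight is the absolute contrast

w<sub>ij</sub> = |x̄ᵢ − x̄ⱼ|.

A subject with uniformly low (or uniformly high) tau has near-zero weights
everywhere; focal accumulation creates strong edges between affected and
spared territory. Network distance is the reciprocal weight 1/w<sub>ij</sub>,
so strongly contrasting pairs are "close", and the shortest path length
d<sub>ij</sub> minimizes total distance over direct and indirect routes.
Three summary measures are used:

* **nodal strength** sᵢ = Σⱼ w<sub>ij</sub>;
* **global strength**, the mean of sᵢ over all nodes, and **limbic
  strength**, its mean over the bilateral amygdala and parahippocampal
  nodes — the territory earliest and most reliably affected;
* **global efficiency** E<sup>w</sup>, the mean inverse shortest path
  length over ordered pairs, with unreachable pairs (zero weight and no
  finite indirect route) contributing zero — the standard
  weighted-efficiency convention; the degenerate all-equal profile thus has
  E<sup>w</sup> = 0.

Useful structural facts, all enforced by tests: the weight matrix is
symmetric, nonnegative, zero-diagonal; every measure is invariant to adding
a constant to the profile and scales linearly under positive rescaling;
Σᵢ sᵢ equals twice the total edge weight; and because a shortest path never
exceeds the direct distance, E<sup>w</sup> ≥ global strength/(n−1).

### Assumptions

The image is already in template space on (nominally) a 2-mm isotropic
grid; the atlas and gray-matter map share that grid exactly. No resampling
is ever done implicitly — any shape mismatch is an error, because silent
interpolation would corrupt the cube geometry. A non-2-mm grid is accepted
with a warning stating the physical cube size. SUVR normalization, when
requested, is a plain division by the mean uptake of a reference-region
mask (classically cerebellar crus).

## Node selection

Each region contributes one candidate cube at the voxel nearest its center
of mass (Euclidean distance in voxel units; lexicographic tie-break, so the
choice is deterministic and storage-order independent). The region
"center" is not pinned down further by the method's description; nearest
voxel to the center of mass is the natural reading and is validated against
brute-force enumeration in the tests. A node survives only if

1. all 27 voxels fall inside the image and inside the gray-matter mask
   (probability ≥ 0.3; the inclusive `≥` is our choice — the published rule
   states the threshold but not strictness — and the threshold is a
   parameter);
2. its cube shares no voxel with any other region's cube.

Rule 1 is recorded first when both fail. Overlap excludes *both* regions
involved: the method requires cubes to be mutually independent without
saying which of an overlapping pair to keep, and symmetric exclusion is the
only order-independent, non-arbitrary resolution — selection is provably
invariant to region enumeration order. Cohorts processed with a published
final node list can bypass the rules with an explicit include-list.

## Staging

Two routes map (limbic strength, global efficiency) to ordinal stages 1–4.
The **fixed-threshold** route applies the published cutpoints — limbic
strength 14.463 (stages 1–2 vs 3–4) and 9.867 (1 vs 2), efficiency 0.901
(3 vs 4) — with values at a threshold going to the lower branch, the
convention of recursive-partitioning software. Where the source material
prints both 14.46 and 14.463, the three-decimal figure is used.

The **learned** route, `fit_stage_tree()`, is a simplified
conditional-inference tree: at each node every feature's association with
the response is scored by |Spearman ρ|; its p-value comes from a joint
permutation null (one set of response permutations shared across features,
p = (1+#{T\*≥T})/(B+1), default B = 9999) with Bonferroni correction over
the non-degenerate features. If the smallest corrected p exceeds α
(default 0.05) or the node is smaller than 2·`min_node` (default 20 per
child), growth stops; otherwise the winning feature is split at the
cutpoint maximizing the standardized two-sample rank-sum statistic, never
between tied values, ties in the statistic resolved toward the smaller
threshold. Leaves are numbered into stages by ascending mean of the *first*
feature, so ordering features as (limbic strength, efficiency) yields
severity-ordered stages. This follows the conditional-inference recipe but
is deliberately not bit-identical to partykit, which uses asymptotic
influence-function statistics; the published fixed thresholds are therefore
implemented exactly rather than claimed as a refit. The method's
description also leaves open which response variable produced the published
four stages, so the learner takes the response as an explicit argument and
no default pretends to reproduce that figure. All randomness flows from an
explicit seed and the global RNG state is restored afterwards.

## Statistics

* **ANCOVA Cohen's f.** The group effect adjusted for covariates uses
  type-II sums of squares (main-effects model, so SS(group | covariates));
  partial η² converts to f = √(η²/(1−η²)). The 95% interval inverts the
  noncentral-F distribution on the noncentrality parameter and maps back
  through η² = λ/(λ+df₁+df₂+1) — the convention of the effect-size
  literature; the exact CI recipe behind the published intervals is not
  stated, so this choice is documented and tested by coverage simulation.
  Sex enters as a 0/1 covariate. Complete-case deletion per analysis.
* **Spearman correlation** with the asymptotic t p-value; constant input is
  an explicit error rather than NA.
* **Steiger's test** for two dependent correlations sharing a variable,
  using Fisher z transforms with the covariance term evaluated at the
  back-transformed mean of the two z values (Steiger's Z₁\*).
* **Chi-square** independence tests without continuity correction; zero
  expected counts are errors.
* **ROC/AUC** by the Mann–Whitney identity with DeLong intervals and the
  Youden-J operating point (first row on ties), delegated to pROC and
  cross-checked against explicit pair counting in the tests.

No multiplicity correction is applied across analyses by default, matching
the reporting style the battery reproduces.

## The synthetic cohort generator

The generator exists to exercise every stage of the pipeline with known
ground truth; it is not a model of PET physics. A phantom atlas packs `k`
disjoint 7³-voxel cuboids (margin ≥ 1 voxel) onto a slot lattice, assigns
tiers — four limbic regions, the remainder split temporal/isocortical,
optionally off-target — and sets gray matter to 1 inside regions. Each
subject has a latent severity s ~ U(0,1), and a region in tier t gets mean
SUVR

baseline + amplitude_t · max(0, s − onset_t) + ε,

with onsets 0 < 0.35 < 0.7 enforcing the limbic → temporal → isocortical
order, amplitudes 2.5/2.0/1.5 SUVR, baseline 1.0 (between-subject sd
0.05), regional noise sd 0.05, and optional voxel-level noise at render
time. The hinge-plus-noise form is an invention: it produces monotone,
tier-ordered accumulation — the property the staging and recovery tests
need — with SUVR in the realistic 1–3.5 range. With the 20-region staging
phantom these defaults put limbic strength in ≈0–26 and efficiency in
≈0–1.1, straddling all three published cutpoints so that all four stages
are populated.

What the generator does *not* emulate: point-spread blur and partial-volume
effects, off-target binding patterns, scanner harmonization, anatomically
shaped regions, and registration error. Passing tests therefore demonstrate
the correctness of the geometry, graph computations, staging logic and
statistics — not clinical performance on real images.

## Numerical choices and problem sizes

Shortest paths use dense Dijkstra per source (O(n³) total; trivial at
n ≤ 90), with Floyd–Warshall retained as an independent route and
exhaustive simple-path enumeration as the test oracle at n ≤ 7. Zero
weights become infinite direct distances; ties between equal-length paths
are irrelevant since only lengths are used. Images are written as float64
so round trips are bit-exact. Positivity comparisons are strict (`>`), per
the published wording "greater than 1.23".

Validation sizes, chosen to make every property decisive while keeping the
full suite around half a minute: 200 random profiles for route-agreement
checks; a 40³/8-region phantom with 50 graded subjects for end-to-end
severity recovery (rank correlation 1 without noise, ≥ 0.9 at voxel sd
0.05); n = 500 for planted-threshold recovery (within 2% of the feature
range); 200 pure-noise replicates for the tree's type-I behavior; 500
replicates for f-interval coverage and 1000 for Steiger calibration. On the
pure-noise check, Bonferroni over two features makes the true no-split
probability ≈ 0.95 by construction; the observed fraction over 200
replicates fluctuates around that value across seeds, which is the expected
behavior of a calibrated test rather than a defect.

## Limitations

Node placement assumes template-space images; subject-space analysis and
surface parcellations are out of scope, as are other graph metrics
(clustering, modularity, betweenness) and group-covariance networks, which
answer a different question. Efficiency is reported on the raw
SUVR-difference scale with no normalization. The tree learner's permutation
framework is exchangeable-response only (no covariate stratification).
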
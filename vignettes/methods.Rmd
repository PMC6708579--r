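---
title: "Phylogenetic inference from shell landmarks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic inference from shell landmarks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphotree)
```

## The problem

morphotree estimates phylogenies from 3D landmark configurations digitised
on turtle shells (carapace and plastron), and evaluates how well such
estimates recover a molecular reference phylogeny. The pipeline covers three
stages that are usually scattered across separate tools:

1. **Landmark processing** — from raw digitisations in TPS format to the
   superposed species-level datasets that all analyses consume.
2. **Tree inference** — five optimality criteria native to continuous
   landmark data, each with a heuristic search and bootstrap support.
3. **Evaluation** — quartet- and split-based dissimilarities to a reference
   tree, a topological-accuracy statistic with an explicit random-tree null,
   and leave-one-out placement of single species on a molecular scaffold
   (the "fossil placement" protocol).

A fully synthetic Brownian-motion study generator with known truth backs
every stage, so the whole pipeline is testable end to end without any
collection data.

## Landmark processing

Raw data are one TPS record per digitisation; replicates of the same
specimen carry a `$a`/`$b` suffix on the ID line. The pipeline is:

* **Replicate consensus.** The replicates of each specimen are superposed by
  generalised Procrustes analysis (GPA) and averaged.
* **Abnormality repair.** Landmarks flagged as developmentally abnormal are
  replaced by the mirror image of their bilateral counterpart across the
  estimated midsagittal plane.
* **Symmetrisation.** The midsagittal plane is estimated by least squares:
  it passes through the mean of the medial landmarks and bilateral-pair
  midpoints, with its normal taken as the principal direction of the
  right-minus-left difference vectors (exact for a symmetric shape). Every
  retained bilateral landmark is the average of the right landmark and the
  reflected left counterpart; medial landmarks are projected onto the plane;
  only right + medial landmarks are kept. With the built-in definition
  tables this yields 77 effective carapace and 25 effective plastron
  landmarks.
* **Lobe splitting.** Plastra are divided into anterior (14 landmarks) and
  posterior (11) lobes, because hinged taxa cannot be superposed whole.
* **Species consensus and dataset assembly.** Specimens are averaged per
  species after GPA; the carapace, anterior-lobe and posterior-lobe blocks
  are each superposed independently across species; the composite plastron
  (25) and shell (77 + 25 = 102) datasets concatenate those blocks on the
  species intersection, deliberately without a joint re-superposition.

GPA here is the standard iterative scheme: centre, scale to unit centroid
size, rotate (proper rotations only) onto the running consensus until the
consensus moves by less than 1e-10. No tangent-space projection is applied;
"Procrustes distance" throughout the package is the Euclidean distance
between the already superposed, flattened configurations (the partial
Procrustes convention).

Two choices were genuinely open and are fixed as follows. The symmetrisation
could either average the right side with the reflected left, or merely fill
missing landmarks by reflection; averaging is used, since the stated goal is
to remove side variation. The between-species `total_variance()` uses the
sample variance (divisor N - 1); the alternative divisor N changes the value
by a factor (N-1)/N, well inside the tolerance used anywhere the quantity is
compared.

## Optimality criteria

All criteria consume a `landmark_dataset` (species x landmarks x dims array)
and a fixed unrooted topology.

**Squared-change parsimony (SCP).** Minimises the sum of squared coordinate
changes over edges with unit branch lengths. The minimiser solves the
quadratic problem exactly through the graph-Laplacian normal equations,
jointly for all coordinates; tests verify it against a free-ancestor
numerical optimisation.

**Linear (Farris) parsimony.** Each coordinate is an independent continuous
character; the minimal total absolute change is computed per coordinate with
the exact interval down-pass on binary trees (intersection of child
intervals, else the gap is added). Multifurcating trees fall back to an
exact dynamic programme over the per-coordinate tip-value state set, valid
because an L1-optimal labelling always exists on tip values.

**Landmark analysis under parsimony (LAUP).** The optimisation unit is the
whole landmark: candidate ancestral positions form a lattice with `g`
subdivisions per axis over the landmark's bounding box across the terminals,
and the minimal summed *Euclidean* displacement (not squared) is found
exactly on that lattice by Sankoff-style dynamic programming (implemented in
C++). Grid nesting re-runs the programme on a finer lattice of
`±window_cells` previous cells around each incumbent position; the incumbent
itself stays in the candidate set, so an extra nesting level can never
increase the score. Defaults are `g = 6` with two nesting levels and a
window of one cell, the settings that balanced score quality against run
time in the original study design. Terminal positions are used exactly (not
snapped to the grid), and the bounding box is global across terminals rather
than subtree-local — a conservative superset that keeps the programme a
clean tree DP. Degenerate axes (zero extent) collapse to a single
coordinate.

**Dynamic alignment.** Rather than fixing the GPA superposition, the LAUP
score can be minimised over per-terminal rigid rotations: reconstruct
ancestral positions, rotate each terminal (about its centroid, no rescaling)
towards its reconstructed ancestor by iteratively reweighted Kabsch steps
(Weiszfeld weights, matching the summed-distance objective), accept only
improving updates, repeat. The score trace is non-increasing by
construction.

**Brownian-motion maximum likelihood.** Coordinates are independent
characters evolving by Brownian motion with common rate 1; the rate scale is
absorbed into the branch lengths, which are free parameters. The package
maximises the restricted (contrast) log-likelihood computed by pruning, with
L-BFGS-B on log branch lengths. Absolute log-likelihood values follow the
contrast-density convention and are therefore not comparable with programs
that use other normalisations; only differences between topologies matter
here. Zero-variance characters are dropped with a warning; only binary trees
are accepted.

**Neighbour joining.** Standard agglomeration on the pairwise Procrustes
distance matrix, with negative branch lengths clamped to zero.

## Searches and support

All criterion searches share the same machinery: random addition sequences
(each species inserted, in seeded random order, on the edge currently
minimising the criterion), followed by first-improvement hill climbing over
NNI, SPR or TBR neighbourhoods generated by surgery on an adjacency
representation of the unrooted tree. Ties break to the first candidate in a
seeded shuffled order. The SCP search adds a stochastic-NNI-perturbation
stage seeded from the best trees of the first stage. The dynamic-alignment
LAUP search alternates tree search and re-alignment until the same topology
appears in two successive iterations, across several restarts from randomly
rotated configurations, optionally plus one run from a user-supplied
starting tree.

Branch support is estimated by resampling whole landmarks (their coordinates
move together) — ordinary bootstrap or symmetric reweighting (each landmark
independently dropped or doubled with probability p/2 each; default
p = 0.33, the conventional default for symmetric resampling, since no value
is dictated by the study design). The superposition is not recomputed on
replicates. Support is summarised by the majority-rule consensus at a 70%
threshold (frequency >= threshold retains a split).

## Tree comparison and topological accuracy

Quartet comparison classifies every tip quartet through the four-point
condition on unit-branch-length path distances; dQ counts the quartets
resolved *differently* in the two trees, so polytomies are soft and a star
conflicts with nothing. The contradiction difference (CD) counts the
nontrivial splits of each tree incompatible with the other. For tree-space
distance matrices, where a true metric is needed on polytomous trees, the
scaled quartet distance optionally adds the one-sided resolutions; the
conflict-only count remains the default for accuracy.

Topological accuracy is
TA = (d0 - d) / d0,
where d is the dissimilarity between the estimate and the reference and d0
is the median dissimilarity between the reference and random binary
topologies on the same tips (10,000 by default). TA is 1 for perfect
agreement, about 0 for random-tree-level conflict, and invariant to any
positive rescaling of the dissimilarity — which is why no normalisation
convention for CD needs to be pinned down. The random-topology null uses
uniform sequential edge addition; this generator is a documented
approximation of the cited null model, and the TA denominator (a median
over thousands of draws) is insensitive to the fine structure of the
distribution.

Tree spaces are visualised by classical metric MDS (double centering +
eigendecomposition) with the Pearson correlation between original and
projected distances as a quality index, and clustered by PAM with the elbow
rule (largest second difference of the cost-versus-k curve).

## Placement on a molecular scaffold

`place_species()` prunes one species from the reference tree, scores its
attachment on every edge of the pruned scaffold under a chosen criterion
(re-optimising ancestral states or branch lengths per candidate, never
rearranging the scaffold), and reports the set of optimal edges. The error
is the number of nodes separating the chosen from the original attachment
edge — 0 for the same edge, m + 1 where m is the smallest topological
distance between edge endpoints otherwise, a convention that makes both the
"correct = 0" case and the farthest-edge maximum well defined — scaled by
that maximum. Ties are summarised by the median scaled error. The AUC of the
empirical CDF of scaled errors equals 1 - mean(error) exactly, and the
pooled distribution of all possible placements (`placement_null()`) provides
the random-placement baseline. The reference tree is used fully resolved.

## The synthetic study generator

`simulation_spec()` fixes the study conditions: a tree with branch lengths
in Brownian time units, a root configuration drawn once, every coordinate
evolving independently with variance rate x branch length, optional
convergence shifts added to designated clades (emulating the confound of a
plastral hinge shared by distant clades), two digitisation replicates per
specimen with isotropic noise, and — in bilateral mode — mirrored left-side
landmarks, medial landmarks pinned to the midplane, optional fluctuating
asymmetry, injected abnormalities, and a random similarity transform per
digitisation so that superposition has real work to do. Defaults follow the
empirical design: 3D, bilateral, two replicates, digitisation noise 0.02 on
configurations of centroid size sqrt(p).

What the generator deliberately does *not* emulate: covariance between
landmarks (integration), ontogenetic or sexual variation, and digitisation
error that varies by landmark. Tests passing on these data therefore
demonstrate correctness of the algorithms and recoverability under the
model's own assumptions, not performance on real shells — where the original
study found all methods to perform poorly.

### The recovery experiment

The end-to-end check simulates on a symmetric 12-taxon tree (three
4-taxon subclades, unit branch lengths throughout), 30 landmarks, rate 1,
zero replicate noise, and asks every criterion's search to reach TA(dQ)
>= 0.9 against the truth. Two properties of this design matter:

* At 12 taxa a single misplaced cherry costs about 0.19 TA, so the check
  effectively demands near-perfect recovery.
* Even with no measurement noise, the Brownian process itself is the noise:
  with 90 characters, roughly one realisation in ten yields a dataset whose
  *global optimum* under a given criterion differs from the true tree by one
  rearrangement (verified by exhaustively comparing criterion scores of the
  found tree and the truth). This is a property of the estimators, not of
  the searches — linear parsimony and ML both genuinely prefer the wrong
  tree on such draws.

The test suite therefore runs the recovery check on one fixed realisation,
while the acceptance script reports the *median* TA over three independent
simulation replicates per method, which is robust to single unlucky draws.
Search effort in these checks (6 TBR addition sequences for the fast
criteria, 3 NNI sequences for ML and spatial parsimony with a 4-division
single-level grid) was sized so that searches, not data, are never the
limiting factor — verified against exhaustive enumeration at 6 taxa and
against heavier searches at 12.

## Numerical choices

* GPA convergence 1e-10 on the consensus; rotations are proper
  (determinant +1) throughout, including the Kabsch steps of dynamic
  alignment.
* Criterion ties in searches and placement use a 1e-9 score tolerance.
* The Brownian ML optimiser runs L-BFGS-B on log branch lengths bounded in
  [1e-10, 1e6]; its terminal digits can depend on the internal node
  numbering of the tree, so topology identity — not raw likelihood
  equality — is the right test of search success.
* All randomness flows through explicit seeds; `random_topology()`,
  searches, resampling and the simulator restore the caller's RNG state.

## Problem sizes used by the tests and the acceptance script

Oracle agreement uses 8-taxon, 5-landmark instances (squared-change
parsimony against numerical optimisation), 6-taxon 1-D instances (linear
parsimony against exhaustive enumeration), and 3-leaf stars (spatial
parsimony against the Weiszfeld geometric median). Search reliability is
measured on 6-taxon instances where all 105 topologies can be scored
directly. The end-to-end recovery and placement checks use the 12-taxon
design above. These sizes keep the whole suite in the minutes range while
still exercising every code path that the full 42-46 species analyses
would use.

## Known limitations

* Landmark independence is assumed everywhere; genetic or functional
  covariance between landmarks is not modelled.
* Brownian ML log-likelihood values are on the contrast-density scale and
  not comparable across software conventions.
* The LAUP grid search is exact only on its lattice; the reported score is
  an upper bound on the continuous optimum that tightens with more
  subdivisions and nesting (tested as a monotone envelope).
* Dynamic-alignment placement is not offered; scoring every candidate edge
  under re-alignment is prohibitively slow, matching the original
  protocol's restriction to GPA-aligned placement.
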
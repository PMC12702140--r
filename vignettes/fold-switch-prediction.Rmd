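---
title: "Fragment-based scoring and classification of fold-switching proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based scoring and classification of fold-switching proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldswitchr)
```

## The model

Fold-switching proteins adopt two distinct stable folds, usually with a
large change in secondary structure over a contiguous stretch of residues.
The working hypothesis of this package is that such a stretch betrays
itself in a structural database: short fragments from the fold-switching
region occur in deposited structures in *different* secondary-structure
states, whereas fragments from a monomorphic protein occur predominantly in
one state. The pipeline therefore measures, residue by residue, how
structurally degenerate the query's local fragments are.

### Fragment picking

Each 7-residue window of the query is looked up exactly (no mismatches, no
ambiguity-code expansion) in an index over all 7-mers of the database. The
window starting at residue $s$ is assigned to query position
$s + \mathrm{offset} - 1$ where the scoring offset is 3 by default — the
third residue of the fragment, the position found to classify best, with
local backbone interactions within the 7-mer largely determining its state.
A length-$L$ query thus has $L-6$ scored positions, $3 \ldots L-4$;
the two first and four last residues of the query are never scored and
carry no values in the output track.

Hits are then filtered in a fixed order:

1. **Confidence filter.** A hit from a predicted structure is dropped when
   the scoring residue's pLDDT is below 70 (exactly 70 is kept); a hit from
   an experimental structure is dropped when the scoring residue is
   unobserved in the deposited model. Encoding observed/unobserved as
   100/0 lets one numeric rule serve both sources. The filter is applied at
   the same residue whose secondary structure is scored — filtering a
   different residue would admit unreliable state assignments for the
   residue that actually enters the score.
2. **Cluster deduplication.** Databases of deposited structures are highly
   redundant (the same sequence solved many times), which would bias the
   propensities toward well-studied proteins. Hits are collapsed to one per
   100%-sequence-identity cluster; the representative is the hit with the
   lexicographically smallest (protein id, offset), an arbitrary but
   deterministic choice.

The order matters — deduplicating first could keep a representative that
the confidence filter then removes — so the contract pins it.

### Scores

The scoring residues of the $n$ surviving unique-cluster hits are mapped to
three states (H/G/I helix, E/B strand, T/S/`-` loop; the bend state S and
coil `-` join the loop class by the standard 3-state convention), giving
propensities $(h, e, l)$. Four per-position scores follow:

- **Diversity index** $DI = (h^2+e^2+l^2)^{-1}$, the inverse Simpson
  concentration: 1 when all hits agree, 3 at the uniform mixture.
- **Entropy** $-h\ln h - e\ln e - l\ln l$ with $0\ln 0 = 0$, in
  $[0, \ln 3]$. The natural logarithm is used; with base-e the observed
  per-protein entropies of known metamorphic proteins stay below
  $\ln 3 \approx 1.10$, consistent with the scale on which the score was
  designed.
- **Substitution score**: every unordered pair of hits is scored with the
  symmetric class-dissimilarity matrix (helix–strand 0.7, helix–loop 0.3,
  strand–loop 1, diagonal 0) and the pair scores averaged. A single hit
  has no pairs and scores 0.
- **Uncertainty** $\exp(-0.5\,n)$, a Hoeffding-style penalty for sparsely
  sampled fragments: 1 with no evidence, $e^{-1} \approx 0.37$ at two
  unique hits, effectively 0 beyond a dozen.

A window with **no hits at all** is assigned (diversity 1, entropy 0,
substitution 0, uncertainty 1.0): the minimum of every diversity metric and
maximal uncertainty, so absence of data can never masquerade as evidence of
fold-switching.

### Feature reduction

Fold-switching needs *consecutive* ambiguous fragments, not isolated ones,
so the diversity, entropy and substitution tracks are smoothed with a
rolling mean before taking the maximum. The window width is a step
function of protein length — 8 positions for sequences of up to 251
residues, 18 above — so that the high-score plateau must be sustained
proportionally longer in larger proteins. Both widths and the threshold are
exposed as configuration (`window_width()`, `default_config()`). Tracks
shorter than the rolling width (proteins shorter than width + 6) use a
single window spanning the whole track, so short designed proteins are
scored without a special case.

The classifier input is the 4-vector

$$\left(\max_i \tfrac1{WW}\sum_j DI_{i+j},\;
  \max_i \tfrac1{WW}\sum_j H_{i+j},\;
  \max_i \tfrac1{WW}\sum_j S_{i+j},\;
  \operatorname{mean}_i U_i\right).$$

The uncertainty feature is the plain mean over positions, not a rolled
maximum: it summarizes how well-sampled the whole protein is, not where a
peak lies.

### Classifier

A support vector machine with a polynomial kernel of degree 2 separates
fold-switching from monomorphic feature vectors. Features are standardized
to zero mean and unit variance before the kernel; the standardization
parameters are estimated from the training data only and stored with the
model, so cross-validation estimates are leakage-free (each fold's
parameters come from its own training split, and the per-fold centers are
asserted to differ in the tests). The kernel's independent term defaults
to 1: the inhomogeneous quadratic kernel
$(\gamma\,u^\top v + 1)^2$ spans all quadratic *and linear* functions of
the features, whereas the homogeneous form ($c_0 = 0$) is an even function
that cannot represent any boundary separating classes lying on opposite
sides of the standardized origin. Positive decision values mean
fold-switching; the signed distance to the boundary is reported as the
confidence.

Validation uses stratified six-fold cross-validation. Stratification is
used (rather than a fully unconstrained random split) because with classes
of roughly 190 examples each an unlucky split can starve a fold of one
class; the partition is controlled by a seed and reproducible.
Hyperparameters (cost log-uniform $10^{-2}..10^3$, kernel coefficient
log-uniform $10^{-3}..10$, independent term $0..5$) can be tuned with
`tune_hyperparameters()`, a sequential model-based search: a seeded random
design that always contains the default point, refined by a Gaussian-process
surrogate (squared-exponential kernel on the unit cube, fixed length-scale
0.3) with the expected-improvement acquisition maximized over a random
candidate pool. Folds are held fixed across all evaluations, so the tuned
model's cross-validated accuracy can never fall below the default's, and
ties are broken toward smaller cost (lower model complexity).

### Region calling and filters

For a positive prediction the *fold-switch region* is localized on the
entropy track: the rolled entropy is thresholded at a fraction (default
0.8) of its maximum and the maximal contiguous run of above-threshold
windows containing the arg-max window is reported in residue coordinates.
The fraction is a design choice — the region is defined qualitatively as
"the contiguous stretch of consistently high entropy" — and is exposed as
configuration; at 0.8 with rolling width 8 a rectangular plateau longer
than the window is recovered to within one residue at each end (windows
need $\lceil 0.8 \cdot 8\rceil = 7$ of their 8 positions on the plateau to
pass, extending the call by exactly one position on either side).

Two proteome-scale filters then act on positive calls:

- **Disorder consensus.** Intrinsically disordered regions sample many
  secondary structures across deposited models and light up the entropy
  track without being fold switches in the two-stable-folds sense. A
  region with more than 50% of its residues inside the consensus of two
  disorder predictors is dropped; exactly 50% is kept. "Consensus" is read
  as the residue-wise *intersection* (a residue must be called disordered
  by both predictors) — the natural reading of agreement, and the
  conservative one for rejection; a union mode is available. Annotations
  are consumed as interval tables; the package never runs a disorder
  predictor itself.
- **Domain annotation.** Calls whose region overlaps an annotated domain
  (any nonempty intersection) are retained; calls with domain annotation
  that never touches the region are excluded from the final set; proteins
  with no domain annotation at all are retained as their own category
  rather than excluded, since absence of annotation is not evidence of
  absence.

`shortlist_candidates()` implements the final candidate criterion: among
domain-overlapping positives, proteins with a contiguous run (at least one
rolling-window long) of positions where helix and strand propensity are
*simultaneously* at least 0.05 — direct fragment evidence for both
conformations in the same stretch.

## The synthetic-data generator

`make_database()` builds databases with *planted ground truth*: each plan
row places one segment into a chosen number of distinct-cluster records
with an all-helix, all-strand or all-loop annotation, separated by random
filler that is rejection-sampled until it (including the junctions) contains
no copy of any planted 7-mer. `make_query()` embeds a planted segment in
filler that likewise avoids every 7-mer present in the database. Two exact
consequences follow, and the tests assert them without tolerance: every
query window fully inside the segment finds exactly the planned records
(so its propensities equal the planned class mixture exactly), and every
other window finds nothing (so it carries exactly the default scores).
Plans whose segments share a 7-mer are rejected as infeasible rather than
silently merged.

`make_classifier_set()` generates labelled feature vectors directly in
feature space rather than through 387 full pipeline runs: each class draws
uniformly from a box (monomorphic centered at diversity 1.25, entropy 0.25,
substitution 0.12, uncertainty 0.75), with the fold-switching box displaced
by `separation` times a fixed effect vector (+0.90, +0.60, +0.45, −0.60)
and all values clipped to the scores' valid ranges. The default class sizes
(189 fold-switching, 198 monomorphic) mirror the labelled training
set's shape. At `separation = 1` the two boxes are disjoint in every
feature with a clear margin, so the data are linearly separable and
six-fold cross-validation must be perfect — the separable-limit sanity
check. At `separation = 0` the classes are identically distributed, the
permutation null under which the mean cross-validated MCC is asserted to
lie within three standard errors of zero.

What the generator does *not* emulate: real fragment databases have
heavy-tailed hit counts, correlated neighbouring windows, partial mixtures
contaminated by loop states, and feature distributions that overlap
substantially between classes. Passing tests therefore demonstrate the
correctness of the machinery (exact propensity arithmetic, filter order,
fold hygiene, threshold behaviour), not field accuracy on real proteomes —
that depends on the database one builds.

## Numerical choices and degenerate inputs

- Entropy uses natural logarithms and the $0\ln 0 = 0$ convention.
- Confusion-matrix ratios with a zero denominator (e.g. precision when
  nothing is called positive) are reported as `NaN` with a warning rather
  than silently coerced to 0; aggregations over permutation replicates
  average the finite values.
- Queries shorter than 7 residues are skipped with a warning in batch
  scoring and are an error in direct calls.
- Query fragments containing non-canonical letters (X, B, Z, U) return no
  hits, with a warning: exact-match semantics, no silent substitution.
  Database sequences may contain such letters; they are indexed literally.
- An all-default track (no hits anywhere) has no entropy signal and
  `call_region()` refuses to call a region for it.
- Internally all offsets are 0-based half-open; every user-facing table and
  region is 1-based inclusive, matching residue numbering in structure
  viewers.
- All stochastic components (fixtures, fold assignment, the tuning design)
  are driven by explicit seeds and regenerate byte-identically.

## Problem sizes in the tests

The shipped tests and the acceptance script run at desk scale: databases of
tens of records, queries of 50–100 residues, oracle comparisons over 100
random databases, 1000 random confusion matrices, and 50 permutation
replicates of the 387-example cross-validation. These sizes give exact or
tightly-bounded expectations while keeping the whole suite fast; the same
code paths scale to proteome-sized inputs since the index lookup is O(1)
per window and scoring is linear in query length.

## Known limitations

- Exact 7-mer matching cannot see fold switches triggered by point
  mutations in otherwise similar sequences, and proteins whose secondary
  structure is preserved while tertiary contacts rearrange score low by
  construction.
- The propensity estimate inherits whatever conformational biases the
  database carries; regions well-sampled only in one fold will look
  monomorphic.
- The hit-count uncertainty treats unique clusters as independent
  observations, which overstates independence for homologous (but
  non-identical) sequences since clustering is at 100% identity only.
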
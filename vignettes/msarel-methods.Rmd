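---
title: "Methods: ensemble perturbation and reliability scoring in msarel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble perturbation and reliability scoring in msarel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A progressive protein aligner makes three classes of arbitrary choices:
the guide tree that fixes the merge order, the affine gap penalties, and
— whenever several alignments attain the same optimal score — which
co-optimum the traceback happens to return. `msarel` treats a reference
MSA as one draw from this space and estimates, for each of its columns,
residue pairs, residues and sequences, the probability that the feature
would be reproduced under resampling of those choices.

The ensemble recipe (defaults in parentheses):

* **TREE** — resample the reference MSA's columns with replacement,
  recompute pairwise p-distances (pairwise deletion of gap sites), and
  build a midpoint-rooted neighbor-joining guide tree (100 trees).
* **GAP** — per tree, draw one gap-opening penalty from a continuous
  Uniform(1, 3). Continuity is the weaker assumption; a ClustalW-like
  preset Uniform(4, 16) is available. One draw is shared by all of a
  tree's members, mirroring the per-tree sampling of the protocol this
  package implements. The gap-extension penalty is never perturbed: its
  contribution to ensemble variability is known to be negligible.
* **HOT** — per tree, sample `n_cooptimal` (4) head/tail orientation
  vectors, one bit per internal node in deterministic post-order; the
  first member of every tree is all-HEAD and later draws are kept
  distinct while the 2^(n−1) orientation space allows. A TAIL merge
  aligns both profiles character-reversed and un-reverses the result;
  because the traceback tie-break is a fixed state preference
  (align > gap-in-B > gap-in-A), HEAD and TAIL are the two deterministic
  extremes of the co-optimal set and always score equally (this is
  asserted on every tested input).

The default ensemble is 100 × 4 = 400 alternatives. The reference itself
is never counted as a member; it is only the object being scored.
Reproducibility contract: each member is keyed by
(seed, tree index, member index) through a small deterministic hash, so
identical (seed, config, input) yields a byte-identical ensemble
regardless of execution order.

## Scores

Columns are identified coordinate-free by their *column key*: the vector
of 1-based residue ordinals (0 for gap) over the fixed sequence order.
Two columns of any two alignments over the same sequences are equal iff
their keys are equal — the column-wise form of the C-matrix device used
for alignment comparison, verified in the tests against a residue-pair
oracle.

* `CS(j)` — fraction of alternatives containing column `j`'s key.
* pair score — fraction of alternatives in which the two residues share
  a column (a strictly weaker event, hence `CS ≤ SPC` per column).
* `SPC(j)` — mean pair score over column `j`'s pairs; columns with < 2
  residues fall back to `CS` and are flagged.
* residue score — mean pair score over the residue's pairs; a residue
  alone in its column falls back to that column's `CS`, flagged.
* sequence score — mean of the sequence's residue scores (so the
  length-weighted mean of sequence scores equals the mean residue score,
  an identity the tests check).

The CLI's reporting cutoffs (column 0.93, sequence 0.6) are conventional
defaults inherited from the web-tool lineage of this method family, not
model quantities; they are fully configurable and logged.

## The internal aligner

Profile–profile global alignment uses the 3-state affine DP (Gotoh).
Column–column score is the mean substitution score over all cross pairs
of rows; gaps and `X` contribute 0 to the numerator but stay in the
denominator, so gappy profile columns are down-weighted. Gap penalties
are charged once per inserted gap column — `open` for the first column
of a run, `extend` thereafter — scaled by the occupancy of the profile
receiving the gap. Occupancy is a per-profile scalar (fraction of
non-gap cells); the per-column alternative was considered and rejected
because a newly inserted gap column has no own occupancy, and the scalar
choice reduces exactly to the textbook pairwise DP when profiles are
single sequences, which is what the enumeration oracle certifies.
Penalty units are "matrix scale" (mean diagonal of the substitution
matrix, 5.8 for BLOSUM62), so the perturbation range [1, 3] reads as
MAFFT-like absolute units; defaults are gap-open 1.53 and gap-extend
0.123 in those units. Terminal gaps are penalized by default (global
ends); a free-ends mode exists for divergent termini. There is no
iterative refinement: refinement would blur the attribution of ensemble
variability to the three perturbation sources.

The reference MSA uses NJ on p-distances taken from global pairwise
alignments of all sequence pairs — the simplest self-contained analogue
of an external aligner's internal first pass; the O(n²) cost is
acceptable at desk scale.

Numerical/determinism choices: NJ breaks Q-criterion ties by lowest index
pair and clamps negative branch estimates to 0; the unrooted NJ tree is
midpoint-rooted (no rooting is prescribed by the protocol; midpoint is
deterministic and standard for guide trees); children are ordered by
smallest contained leaf id so orientation bits address stable nodes.

## The simulator and what a green benchmark establishes

The benchmark generator evolves a root sequence (drawn from the model's
equilibrium frequencies) along a tree: LG substitutions (Poisson model
available for closed-form oracles) with per-site rates that are 0 with
probability `pinv` and Gamma(alpha, alpha) otherwise (continuous, not
discretized — simulation has no likelihood to discretize for); indels as
a per-branch Poisson process at (ins+del) × branch length × length, with
positions uniform and lengths Zipf(1.7) truncated at
min(ceil(10 % of the current length), 25). Defaults ins = del = 0.03
events per substitution per site give alignments with realistic gap
structure at depth ≈ 1. Within a branch, indels are applied first (event
count from the branch-start length), then substitutions act on the full
branch — inserted residues start at equilibrium, so the process remains
stationary. Insertions create new true-MSA columns; columns deleted from
every descendant leaf are dropped and counted (`n_extinct`), keeping the
column accounting exact.

The root length is a direct parameter (the published 66 %-of-alignment
convention is database-relative and documented, not hard-coded), and
benchmark trees are coalescent topologies rescaled to a chosen
root-to-tip depth.

What the generator does *not* emulate: compositional heterogeneity
across lineages, rate shifts, domain shuffling, alignment-length-anchored
indel caps, and real benchmark curation (core blocks are accepted as an
input mask but never inferred). A green benchmark therefore establishes
that the scores discriminate wrongly aligned columns under a well-behaved
stationary indel model — not performance on curated structural
benchmarks, whose headline numbers depend on external corpora and
aligners and are out of scope here.

## Evaluation conventions

A reference column is labeled correct iff its key occurs in the true
MSA. Columns with < 2 residues are excluded from ROC/PR (no pair
evidence) and reported. ROC/PR sweep the distinct score values with ties
grouped; AUC-ROC is the trapezoid area and equals the scaled
Mann–Whitney U statistic with midpoint tie handling (asserted against a
rank oracle), which removes a known source of AUC drift. AUC is
undefined for single-class labels and raised as an explicit error, never
silently 0.5. Pearson correlation with the per-column fraction of
correctly aligned pairs is reported both per replicate and pooled, since
the aggregation level is a genuine free choice.

## Known limitations

* The head/tail device samples one co-optimum per orientation vector; it
  does not enumerate the full combinatorial co-optimal propagation, and
  near-optimal (sub-optimal) alignments are not sampled at all.
* p-distances are uncorrected; for deeply diverged sets a corrected
  distance can be swapped in at the `nj_tree()` boundary.
* The scalar occupancy weighting is one of several defensible profile
  gap conventions; it was chosen for determinism and pairwise
  reducibility, not fitted.
* Reliability of a 2-sequence "MSA" is near-trivial and only warned
  about, not refused.
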
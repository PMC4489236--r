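# msarel — ensemble-based reliability scores for multiple sequence alignments

Multiple sequence alignments (MSAs) are inferred objects: from the same
protein sequences, different aligner settings routinely produce different
alignments, and downstream analyses (phylogenetics, selection inference)
are sensitive to the wrongly aligned regions. `msarel` quantifies that
uncertainty directly. It re-aligns the sequences hundreds of times under
joint perturbations of the three main sources of alignment arbitrariness:

1. **Guide tree** — the reference MSA's columns are bootstrapped, pairwise
   p-distances re-estimated, and a new neighbor-joining guide tree built
   for each replicate;
2. **Gap-opening penalty** — one draw per tree from Uniform(1, 3)
   (MAFFT-like units; the gap-extension penalty is deliberately never
   perturbed, its contribution being negligible);
3. **Co-optimal solutions** — each progressive merge is run either
   "head" (as given) or "tail" (character-reversed, then un-reversed);
   with a fixed traceback tie-break these are the two deterministic
   extremes of the co-optimal alignment set.

With the defaults (100 trees × 4 co-optimal samples = 400 alternatives),
every column *j* of the reference MSA gets a **column score**

    CS(j) = #{alternatives containing column j exactly} / #alternatives

where column identity is alignment-coordinate-free: a column is the vector
of residue ordinals (or gap) it aligns, one entry per sequence. Analogous
frequencies over residue pairs give the **SPC** (mean pair score per
column), per-residue and per-sequence scores, all in [0, 1]. Low-scoring
regions can be masked (`X`) or removed.

The package is self-contained: an internal affine-gap (Gotoh) profile
aligner written in C++ stands in for an external alignment program, an
indel-aware sequence evolution simulator (LG substitution, gamma + pinv
rate heterogeneity, Zipf indel lengths capped at min(10 % of length, 25))
generates benchmarks with known true alignments, and an evaluation module
computes ROC / precision-recall / Pearson summaries of how well the scores
detect wrongly aligned columns.

## Worked example

Simulate a 12-taxon benchmark with a known truth, score a fresh reference
alignment against a 100-member perturbed ensemble, and check how well CS
flags the wrongly aligned columns:

```r
library(msarel)
set.seed(42)
tree <- random_tree(12, depth = 1)                   # substitutions/site
sim  <- simulate_msa(tree, evol_model(root_length = 120))
ref  <- build_reference(sim$sequences)
alts <- generate_alternatives(sim$sequences, ref,
                              perturb_config(n_trees = 25, n_cooptimal = 4,
                                             seed = 7))
report <- score_msa(ref, alts)
report
#> score_report over 100 alternatives
#>   mean CS  0.9601 | mean SPC 0.9899
#>   columns with CS < 0.93: 13 of 131

lab <- label_columns(ref, sim$true_msa)
roc_curve(report$cs, lab$label)$auc                  # 0.868
pearson_to_pair_fraction(report$cs, lab$fraction)    # 0.234
```

Reading the output: 13 of 131 reference columns fall below the
conventional 0.93 CS reporting cutoff; ranked by CS, wrongly aligned
columns are separated from correct ones with AUC-ROC 0.87 on this
replicate. `mask_msa(ref, report, column_cutoff = 0.93)` would drop the
suspect columns before downstream use.

## Command line

A dispatcher (`inst/exec/msarel`, or `msarel_main()` from R) exposes the
pipeline:

```sh
msarel score    --n-trees 100 --n-cooptimal 4 --seed 1 input.fasta outdir/
msarel simulate --n-taxa 20 --depth 1 --root-length 200 --seed 1 simdir/
msarel benchmark --seed 1 simdir/true_msa.fasta benchdir/
msarel mask     --column-cutoff 0.93 outdir/reference.fasta outdir/column_scores.tsv filtered.fasta
```

Every run writes a `manifest.json` (parameters, seed, input checksums)
sufficient to reproduce its outputs bit for bit; data go to files,
logging to stderr.

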
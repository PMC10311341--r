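---
title: "Measuring structural similarity between RNA motif families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring structural similarity between RNA motif families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

RNA 3D structural motifs — recurrent arrangements of nucleotides in the
loop regions of folded RNAs — are conventionally grouped into named
families (Kink-turn, Sarcin-ricin, E-loop, Tandem-shear, ...). The
families are not cleanly separated: some pairs of families share a set of
non-canonical base interactions while folding into different shapes, and
others are close in 3D shape while differing in their interaction
patterns. `rnamotifsim` quantifies both kinds of relatedness over a set
of motif instances and summarizes them as a labeled family similarity
graph, together with per-pair lists of the instances that drive each
edge.

Two complementary viewpoints are implemented:

* **Interaction-based (local).** Each motif is represented as a
  base-interaction graph: nodes are nucleotides in strand order, edges
  are Leontis–Westhof classified base pairs (interacting edge of each
  base — Watson-Crick, Hoogsteen or Sugar — plus cis/trans orientation)
  and base stackings. Two motifs are aligned by maximum-weight clique
  search over a match-compatibility graph: vertices are candidate
  nucleotide matches, cliques are exactly the order-consistent one-to-one
  matchings, vertex weights carry sequence bonuses and auxiliary edge
  weights carry interaction-match scores.
* **Coordinate-based (global).** Each motif is reduced to one
  representative backbone atom per nucleotide (C3′, falling back to P
  then C1′) and aligned by the usual iterative scheme for TM-score-type
  objectives: seed matchings (gapless threadings at every offset plus
  4-nt fragment seeds), then alternation of Kabsch superposition on the
  current matched set, computation of the affinity matrix
  $1/(1+(d_{ij}/d_0)^2)$, and a dynamic-programming pass with gap
  penalty, until the matched set stabilizes (at most 30 iterations per
  seed). The reported score is
  $\mathrm{TM} = \frac{1}{L}\sum_i \frac{1}{1+(d_i/d_0)^2}$ with $L$ the
  length of the shorter motif.

Both viewpoints are converted to a common currency: the RMSD over the
aligned nucleotides, computed on per-nucleotide centroids of the backbone
and ribose heavy atoms (P, OP1, OP2, O5′, C5′, C4′, C3′, O3′, C1′, C2′,
O2′, O4′) after optimal superposition of the matched centroid sets.

## From pair records to a similarity graph

For every unordered pair of motifs the pipeline records the aligned
length, the RMSD and the alignment score (or TM-score). The family-level
statistics then follow a fixed sequence:

1. **Outlier filtering.** Within each family, every instance is
   summarized by its mean alignment score (interaction mode) or mean
   TM-score (coordinate mode) against its same-family partners; instances
   whose z-score falls below a cutoff (default −2) are removed. The
   default is deliberately conservative: in a family of clones a single
   structurally unrelated instance sits near $z = -\sqrt{n-1}$, while the
   minority partners of a genuine cross-family similarity at
   participation $p$ sit near $z = -\sqrt{(1-p)/p}$ (≈ −1.5 at $p=0.3$),
   safely above the cutoff.
2. **Family length thresholds.** The threshold of a family is the mean
   aligned length over all its intra-family pairs. An inter-family pair
   qualifies only if its aligned length reaches the thresholds of *both*
   families — this is what stops short accidental alignments between
   unrelated families from counting as similarity.
3. **Best-pair selection.** Qualifying pairs must additionally have RMSD
   at or below the cutoff: 1.0 Å in interaction mode and 1.5 Å in
   coordinate mode by default. The coordinate cutoff is looser because a
   global alignment necessarily includes weakly superposable positions
   that a local alignment would simply leave out.
4. **Participation.** For each family pair, the participation of a family
   is the percentage of its (post-filter) instances appearing in at least
   one selected pair. An edge is drawn solid when the minimum of the two
   percentages reaches the threshold (default 20%), dotted when it is
   positive but below it. Edges carry the unweighted mean RMSD, the mean
   aligned length and that minimum percentage.

All cutoffs are arguments of `compare_motif_families()` and of the
command-line front end.

## Interaction-alignment scoring

The published description of the interaction aligner does not fix a
scoring scheme, so the defaults here are chosen for structural soundness
and exposed via `interaction_params()`:

| parameter | default | meaning |
|---|---|---|
| `pair_full` | 3.0 | base-pair match with identical LW class (edge×edge×orientation, symmetric flip allowed) |
| `pair_partial` | 1.0 | base-pair match agreeing in orientation or one edge |
| `stack` | 0.5 | stacking matched to stacking |
| `seq_match` | 0.3 | identical bases at a matched position |
| `seq_mismatch` | −0.6 | differing bases at a matched position |

Two constraints pin the mismatch score, and this is the one place where
the package deviates from the most permissive choice (a mismatch score of
0): with a non-negative mismatch score the optimal clique always matches
*every* nucleotide, every alignment becomes full-length, and the
family-specific length thresholds lose all discriminating power. The
magnitude must furthermore be at least the stacking score: a run of $k$
stacked nucleotides carries $k-1$ stacking matches, so any penalty
smaller than `stack` lets consecutive stacking chains — present in every
motif — drag arbitrarily unrelated nucleotides into the alignment
($(k-1)\cdot 0.5 - k\cdot p > 0$ for all large $k$ whenever $p < 0.5$).
A matched base pair (3.0 against two mismatch penalties of −0.6) remains
decisively profitable, which is the behaviour a local interaction
alignment should have.

The clique search is exact branch-and-bound (C++): vertices are ordered
by potential, a greedy solution seeds the incumbent, and the bound
exploits that a matching uses at most one candidate per nucleotide
position on either side. Equal-score ties prefer the larger aligned
length, then the lexicographically smallest match set, so results are
deterministic. A `greedy = TRUE` flag switches to the seeding heuristic
alone for motifs well beyond the ~40-nt scale; it is labeled heuristic
and not used anywhere in the default pipeline.

## Coordinate-alignment choices

* $d_0$ follows the length-dependent convention
  $0.6\sqrt{L-0.5} - 2.5$, floored at 3.0 Å. The floor is what matters at
  motif scale: the formula only exceeds 3.0 beyond ~85 nt, far above the
  4–30 nt motifs in scope.
* $L$ (the normalization length) is the shorter motif's length, which
  makes the score symmetric in its arguments; it is configurable.
* The DP gap penalty is −0.6 with free end gaps. Because affinities are
  strictly positive, the DP matches every position it can; unmatched
  positions are penalized only through the $L$ normalization, which is
  the intended "global" behaviour.
* There is no randomness: seeds and iteration order are fixed.

## The synthetic corpus

Real motif corpora require structure downloads and third-party
annotation tools, so the package ships a generator
(`synthetic_family_spec()`, `planted_similarity()`, `generate_corpus()`)
that emulates all three inputs — coordinate files, two annotation
dialects, and a motif-location list — with controlled ground truth.

A family is a two-strand internal-loop template: nucleotide centers on a
helical curve plus a family-specific smooth random displacement field
(`wiggle_sd`, default 2.5 Å) that makes families geometrically distinct;
a fixed template sequence; cross-strand signature base pairs covering the
core; stackings between consecutive nucleotides. Instances add
per-position mutations (rate 0.05), isotropic Gaussian coordinate noise
(0.15 Å per axis), and a random rigid motion, and are written as PDB
files rounded to the format's 3-decimal precision. Only backbone and
ribose atoms are generated — exactly the RMSD atom scope — so the
fixtures are deliberately not physically realistic RNA; they exist to
give every pipeline stage a checkable ground truth.

Planted similarities come in three flavours matching what the pipeline
must distinguish:

* **interaction-only**: participating instances of both families gain a
  shared block (extra nucleotides on both strands) with identical pairs,
  sequence and internal geometry, but each family places the block
  rigidly in its own way — the interaction viewpoint and the local
  geometry of the block are shared, the global shape is not;
* **coordinate-only**: participating instances keep their family's
  pairs and sequence but take their whole-motif geometry from a shared
  donor shape;
* **both**: participating instances are full copies of a donor.

Base alphabets are part of the design: the two families of a
coordinate-only pair draw their sequences from disjoint alphabets
({A,G} vs {C,U}) and use fully incompatible pair classes, so the
interaction aligner genuinely finds nothing — the planted distinction,
not luck, separates the modes. The reference design
(`reference_corpus_design()`) uses seven families of ten instances with
participations 0.3 (interaction-only), 0.3 (coordinate-only), 0.5
(both) and one family with nothing planted; the acceptance suite checks
that exactly the planted solid edges are recovered in each mode at the
default cutoffs, across seeds.

What passing these tests shows — and does not show: the pipeline
correctly separates interaction-level from shape-level similarity and
recovers planted participation fractions under realistic noise,
mutation, rigid motion, annotation-merging conflicts and outlier
contamination. It does not certify behaviour on real crystallographic
data, where modified residues, missing atoms, annotation errors and
family heterogeneity are richer than the generator emulates.

## Annotation merging

Two annotation dialects (one with explicit record types, one with bare
triples and `s35`-style stacking codes) are parsed to a canonical form
and merged. Interactions asserted identically by both sources are kept
with a joint source label. Conflicts — a different pair class at the same
residue pair, or one base edge claimed by two partners — are resolved in
favour of the class most frequent among the chain's agreeing
interactions. Frequency is counted over interaction *classes* per input
corpus (precomputed counts can be supplied), because class-level counting
is the only unit that generalizes to pairs not seen elsewhere in the
corpus. Ties prefer jointly asserted pairs, then the lexicographically
smaller class label, making the merge deterministic. The same rule
resolves stacking-kind mismatches.

## Evaluation harness

The classifier harness quantifies how inter-family similarity degrades
family identification. Features are alignments against family
representatives (the instance with the highest mean intra-family score,
ties broken by lower mean RMSD then id): five features per representative
in interaction mode (score, length, RMSD, matched pairs, matched stacks),
three in coordinate mode (length, RMSD, TM-score). Binary classifiers use
one-vs-rest labels with the negative class undersampled once per report
to the positive class size; evaluation is stratified 3-fold
cross-validation repeated 5 times (15 runs) with a Gaussian naive Bayes
classifier using variance smoothing 1e-9 (the per-class variances are
inflated by that fraction of the largest feature variance). Sensitivity
is the positive-class recall, specificity the negative-class recall.
Features are standardized for the PCA projection utility only; the naive
Bayes model is per-feature scale-equivariant through its variances, so no
scaling is applied there.

## Numerical and degenerate-input conventions

* `kabsch()` requires ≥3 points of rank ≥2 (collinear sets are rejected
  as degenerate); the reflection case is corrected to a proper rotation.
* `aligned_rmsd()` defines the degenerate match counts explicitly: one
  matched pair has RMSD 0 (a point superposes exactly), two matched
  pairs have the two-segment residual $|d_A - d_B|/2$.
* Nucleotides missing all in-scope atoms are skipped pairwise with a
  warning; an alignment with zero usable atoms is an error, not a 0.
* Residue ranges in location files are 1-based closed intervals in
  author numbering; insertion codes sort after the un-coded residue of
  the same number, alphabetically.
* Modified nucleotides with a known parent keep the parent base code and
  a `modified` flag; any HETATM record inside a motif region excludes
  the whole instance (the conservative reading of the curation rule —
  exclusion is triggered by HETATM content as such, not only by
  non-nucleotide ligands).
* Multi-chain motifs are re-homed to a single chain on export because
  coordinate aligners consume first-chain-only files; the residue
  renumbering map is returned and embedded in the file header.
* Z-scores use the sample standard deviation; zero-variance families
  produce no removals (with a warning) rather than undefined scores.

## Problem sizes

The shipped test and acceptance runs use the reference corpus at ten
instances per family (70 motifs, 2415 pairwise alignments per mode),
oracle suites of 100 random point sets (superposition) and 50 motif
pairs of up to 8 nt (clique alignment vs exhaustive enumeration), and
classifier fixtures of 24–36 feature rows. These sizes were chosen so a
complete from-scratch run of every check stays comfortably on a single
CPU while keeping all participation fractions at round numbers of
instances.

## Known limitations

* The interaction scoring scheme is a structural stand-in, not a
  reproduction of any published isostericity matrix; conclusions should
  be parameter-relative.
* "Aligned length" counts matched nucleotide positions (one per motif
  per match). Published tools are not explicit about this unit; the
  package uses it consistently on both sides of every threshold
  comparison, which is what the thresholds actually require.
* Whether RMSD should be superposed for interaction-mode alignments is
  not specified by the original description; this package always
  superposes, since unsuperposed RMSD would depend on the arbitrary
  crystal frame.
* The per-nucleotide-centroid reading of "centroid to centroid" RMSD is
  a documented choice; a whole-motif centroid would reduce every
  alignment to a single point pair and make the averaging vacuous.
* PCA and plotting utilities are conveniences, not analysis results.
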
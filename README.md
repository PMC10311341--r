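# rnamotifsim

Structural similarity analysis of RNA 3D motif families.

RNA structural motifs — recurrent 3D arrangements of nucleotides in the
loop regions of folded RNAs — are grouped into named families (Kink-turn,
Sarcin-ricin, E-loop, Tandem-shear, ...). Families overlap in two distinct
ways: some share non-canonical base interactions while folding into
different shapes, others are close in 3D shape with different interaction
patterns. `rnamotifsim` measures both kinds of relatedness over a corpus
of motif instances and reports them as a labeled family similarity graph,
plus per-pair lists of the similar instances. It is aimed at structural
bioinformaticians curating motif families, benchmarking motif-search
tools, or deciding whether a borderline instance is annotated in the
right family.

## The method

For every unordered pair of motif instances, two alignments are computed:

* **Interaction-based (local):** motifs as base-interaction graphs
  (nodes = nucleotides in strand order; edges = Leontis–Westhof base
  pairs, edge × edge × cis/trans, and stackings), aligned by exact
  maximum-weight clique search over a match-compatibility graph whose
  cliques are the order-consistent one-to-one matchings.
* **Coordinate-based (global):** one representative backbone atom per
  nucleotide (C3′, fallback P then C1′), aligned by iterative Kabsch
  superposition + dynamic programming under a TM-score objective,
  TM = (1/L) Σᵢ 1/(1 + (dᵢ/d₀)²), with L the shorter motif's length and
  d₀ = max(3.0, 0.6·√(L−0.5) − 2.5) Å.

Each alignment yields an aligned length and an RMSD
√((1/N) Σ δᵢ²) over per-nucleotide centroids of backbone + ribose heavy
atoms after optimal superposition. Family-level statistics follow:
z-score outlier filtering within families (cutoff −2); family-specific
alignment-length thresholds (mean intra-family aligned length; an
inter-family pair must reach both families' thresholds); RMSD cutoffs
(1.0 Å interaction mode, 1.5 Å coordinate mode); participation
percentages (share of a family's instances in at least one qualifying
pair). An edge between two families is solid when the minimum of the two
participation percentages is ≥ 20%, dotted below that; edges are labeled
with average RMSD, average aligned length, and the minimum participation
percentage. All cutoffs are user-adjustable.

Because real corpora need structure downloads and third-party annotation
tools, the package includes a seeded synthetic corpus generator
(parameterized helical backbones, family-specific base-pair signatures,
planted cross-family similarities, injected annotation disagreements)
so the whole pipeline builds and tests offline, and a Gaussian naive
Bayes evaluation harness (balanced binary classifiers, repeated
stratified 3-fold cross-validation) quantifying how inter-family
similarity degrades family identification.

## Worked example

```r
library(rnamotifsim)

# a synthetic corpus with known ground truth: 7 internal-loop families,
# 10 instances each; famA-famB share interactions only, famC-famD share
# shape only, famE-famF share both, famG shares nothing
dir <- tempfile()
design <- reference_corpus_design(n_instances = 10)
generate_corpus(design$specs, design$planted, seed = 42, dir = dir)
corpus <- read_motif_corpus(file.path(dir, "motifs.in"))

ci <- compare_motif_families(corpus, "interaction")
print(ci$graph)
#> <similarity_graph> interaction mode: 7 families, 2 edge(s) (2 solid)
#>   famA -- famB  [solid]  0.11 A / 10.0 nt / 30.0%
#>   famE -- famF  [solid]  0.11 A / 12.0 nt / 50.0%

cc <- compare_motif_families(corpus, "coordinate")
print(cc$graph)
#> <similarity_graph> coordinate mode: 7 families, 2 edge(s) (2 solid)
#>   famC -- famD  [solid]  0.11 A / 12.0 nt / 30.0%
#>   famE -- famF  [solid]  0.11 A / 12.0 nt / 50.0%
```

Each printed edge reads *average RMSD / average aligned length / minimum
participation percentage*: the interaction-mode famA–famB edge says the
qualifying famA–famB pairs align over 10 nucleotides on average at
0.11 Å RMSD, and 30% of each family's instances take part — exactly the
planted interaction-only similarity, which is correctly absent from the
coordinate-mode graph. `tidy(ci)` returns the edge table as a tibble,
`autoplot(ci)` draws the graph, and `write_comparison(ci, out_dir)`
writes DOT/GraphML/JSON graphs, per-family-pair similar-instance TSVs,
and a JSON run report.

Residue ranges in motif-location files are 1-based closed intervals in
author numbering (`family pdb_id chain 10-14,30-33`, one range per loop
strand, optional leading motif id).

A command-line front end lives at `inst/cli/rnamotifsim`
(subcommands `compare`, `synth`, `evaluate`).

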
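# barcodegap

Evaluation of short DNA barcode markers (e.g. the nuclear ribosomal ITS2
spacer) for species discrimination within a genus.

Distance-based barcoding rests on the *barcoding gap*: within-species
divergence must be clearly smaller than between-species divergence for a
marker to identify species reliably. `barcodegap` implements the complete
evaluation workflow a barcoding study runs on a set of labeled marker
sequences — and a controlled simulator to validate it — for systematists,
pharmacognosists and anyone assessing a candidate marker:

- **Kimura 2-parameter distances** with pairwise deletion. Over the sites
  where both sequences carry a plain nucleotide, with transition proportion
  *P* (A↔G, C↔T) and transversion proportion *Q*,

  *d* = −½ ln((1 − 2P − Q) √(1 − 2Q)).

- **Six divergence metrics**: all inter-specific distance, theta prime
  (per-species mean heterospecific distance), minimum inter-specific
  distance (per-species minimum, averaged over species), all intra-specific
  distance, theta (per-species mean conspecific distance) and coalescent
  depth (per-species maximum conspecific distance), each reported as
  mean ± SD.
- **Barcoding-gap profile**: intra/inter distance histograms on a 0.008
  grid, zero- and below-threshold overlap percentages, and a Wilcoxon
  rank-sum comparison of the two distributions.
- **Species identification** by leave-one-out: every sequence is queried
  against all others by (a) nearest K2P distance and (b) best
  Smith–Waterman local-alignment hit (BLAST-style best-hit logic without
  the network), with *correct / ambiguous / incorrect* verdicts — a query
  is *ambiguous* when several species tie at the optimum including the true
  one, *incorrect* when the true species is not among the top hits.
- **Per-species separability table** (TaxonGap-style): within-species
  heterogeneity (max intra) vs between-species separability (min inter)
  per species, closest relatives, and the species pairs sharing identical
  sequences.
- **Neighbor-joining phylogeny** (Saitou–Nei, deterministic tie-breaks,
  negative branch lengths clamped) with nonparametric bootstrap supports
  and outgroup rooting; Newick output via `ape`.
- **Synthetic genus simulator**: star phylogenies with exact expected
  intra/inter K2P divergences, GC-matched roots, optional planted
  identical-sequence species pairs — ground truth for every stage.

## Worked example

Simulate a 16-species genus (4 samples each, one planted pair of species
with identical sequences) and run the full evaluation:

```r
library(barcodegap)

sim <- simulate_genus(n_species = 16, samples_per_species = 4,
                      n_identical_pairs = 1, seed = 42)
ev <- barcode_eval(sim$alignment, bootstrap_replicates = 100, seed = 42)
ev
```

```
Barcode marker evaluation
=========================
64 sequences; length 248-248 bp (mean 248.0); GC 50.4%-54.0% (mean 52.1%)
Inter-specific divergence / intra-specific variation (K2P):
  All inter-specific distance       0.180 ± 0.035
  Theta prime                       0.180 ± 0.021
  Minimum inter-specific distance   0.113 ± 0.047
  All intra-specific distance       0.007 ± 0.005
  Theta                             0.007 ± 0.003
  Coalescent depth                  0.011 ± 0.005
  (16 species, 16 with >= 2 samples)
Barcoding-gap profile (bin width 0.008):
  intra: n=96, range 0.000-0.020
  inter: n=1920, range 0.000-0.271
  % inter-specific distances = 0:        0.83%
  % inter-specific distances < 0.020:    0.83%
  Wilcoxon rank-sum inter vs intra: W = 182952, p < 0.001
Identification (leave-one-out):
nearest        64 samples,  16 species: correct 87.5%, incorrect 0.0%, ambiguous 12.5%
best_hit       64 samples,  16 species: correct 87.5%, incorrect 0.0%, ambiguous 12.5%
TaxonGap-style separability: 87.5% of 16 species separable; 2 species in inseparable pairs
NJ tree: 64 tips, bootstrap supports from 100 replicates
```

Reading the output: the intra- and inter-specific distance distributions
barely overlap (the gap), so identification is never *incorrect*; the one
planted identical-sequence species pair (`ev$inseparable` lists `sp01` /
`sp02`) makes exactly its 8 queries *ambiguous* — ties across a species
boundary can be flagged but not resolved by the marker. Real data enter
through `read_labeled_fasta("seqs.fasta", "labels.tsv")`, and
`run_pipeline()` (or `inst/scripts/barcodegap.R`) drives the same analysis
from a YAML config and writes all tables, the distance matrix and the
Newick tree to a run directory.

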
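---
title: "Evaluating a DNA barcode marker: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a DNA barcode marker: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

`barcodegap` evaluates how well a short marker sequence — typically the
nuclear ribosomal ITS2 spacer, a few hundred base pairs long — separates
the species of a genus. This vignette explains the models behind each
stage, the tunable parameters, what the synthetic data generator does and
does not emulate, and the design decisions taken where conventions in the
field are ambiguous.

## The distance model

All divergence statistics rest on the Kimura 2-parameter (K2P) model,
which distinguishes transitions (A↔G, C↔T, rate α) from transversions
(rate β per alternative). For an aligned sequence pair, let *P* and *Q* be
the observed proportions of sites differing by a transition and a
transversion respectively, computed over the *comparable* sites — those
where both sequences carry a plain `A/C/G/T`. The distance in expected
substitutions per site is

$$d = -\tfrac{1}{2}\,\ln\!\big((1-2P-Q)\sqrt{1-2Q}\,\big).$$

Columns containing a gap, `N` or any other ambiguity code in either
sequence of a pair are excluded for that pair only (*pairwise deletion*).
This is the default gap treatment of the standard distance software in
this field and preserves per-pair information when marker lengths vary; the
alternative (complete deletion) would discard whole columns genus-wide.
The estimator is undefined when $1-2P-Q \le 0$ or $1-2Q \le 0$
(saturation); because genus-level barcode distances sit far from that
singularity (maxima around 0.3–0.4), the default policy is a hard error,
with an opt-in `on_saturation = "na"` mode that records missing entries
for exploratory use. Distances are written to 6 decimal places in output
files; all internal comparisons use full double precision.

## The six divergence metrics

Barcoding studies conventionally summarize a genus with three
inter-specific and three intra-specific metrics. They are named but rarely
defined in papers; `divergence_summary()` follows the convention of the
ITS2-barcoding literature, in which "all" metrics pool sequence pairs and
the remaining metrics average a per-species statistic:

| metric | definition |
|---|---|
| all inter-specific distance | mean over every heterospecific pair |
| theta prime | per-species mean distance to all heterospecific sequences, averaged across species |
| minimum inter-specific distance | per-species minimum distance to any heterospecific sequence, averaged across species |
| all intra-specific distance | mean over every conspecific pair |
| theta | per-species mean conspecific distance, averaged across multi-sample species |
| coalescent depth | per-species maximum conspecific distance, averaged across multi-sample species |

Only the per-species averaging convention can make the reported "minimum
inter-specific distance" *exceed* the "all inter-specific distance" in
published tables — a pooled minimum never could — which is the strongest
internal evidence for these definitions. Three further choices are
documented rather than universal: dispersion is the *population* standard
deviation over the pooled items (papers print "mean ± x" without defining
x); species averaging is unweighted by sample count; and species with a
single sample contribute to the inter-specific metrics but are excluded
from all three intra-specific ones (flagged as absent, never coerced to
zero). Outgroup sequences are excluded from all summaries.

## Barcoding gap

`gap_profile()` bins both distance distributions on a common half-open
grid $[kw, (k+1)w)$ with $w = 0.008$ distance units by default — fine
enough to resolve intra-specific structure near zero while keeping
genus-scale histograms readable. Overlap is summarized by the percentage
of heterospecific pairs at exactly zero distance and the percentage
strictly below a threshold, which defaults to the observed intra-specific
maximum: that value is the natural data-driven boundary of the gap, and a
fixed threshold can be supplied where comparability across datasets
matters. The inter/intra comparison uses the Wilcoxon rank-sum test
(`stats::wilcox.test`: exact enumeration when both samples are ≤ 20 and
untied, tie-corrected normal approximation otherwise). Pairwise distances
are not independent observations, so the p-value is descriptive — reported
because it is the field's convention, with this caveat.

The "unique sequence" species percentage is defined here as: a species
with ≥ 2 samples counts as unique when its haplotype set (ungapped residue
strings) is disjoint from every other species' haplotype set. Published
phrasings of this statistic are ambiguous; the disjoint-set reading
matches the identification context (a shared haplotype is precisely what
makes a query ambiguous) and is stated explicitly so results are
interpretable.

## Species identification

`evaluate_loo()` scores identification success by leave-one-out: each
sequence in turn is the query, the reference set is everything else
(conspecific sequences retained, the query's own record excluded — a
query matching itself would make success trivial). Two search criteria are
provided:

- **nearest distance** — hits are the references at the minimum K2P
  distance (ties within 1e−9, guarding against float noise);
- **best hit** — hits are the references with the maximal Smith–Waterman
  local-alignment score under affine gaps (integer scheme, exact tie
  equality), the in-package equivalent of best-BLAST-hit identification.
  The search is exhaustive rather than heuristic: seeding and E-values
  only accelerate the search, they do not change who the best hit is, and
  an exhaustive scan removes the external database dependency. Default
  scoring is BLASTN-like (match +2, mismatch −3, gap open 5, extend 2);
  residues outside `A/C/G/T` score 0 against everything.

Verdicts follow the best-hit convention: *correct* when the hit species
set is exactly the true species; *ambiguous* when several species tie at
the optimum and the true species is among them; *incorrect* when it is
not. Singleton species stay in the query set — their queries can never be
*correct* under leave-one-out — and their count is flagged in the rates so
that reported percentages can be interpreted.

When every species' minimum heterospecific distance exceeds its maximum
conspecific distance (a strictly positive gap) and every species has ≥ 2
samples, incorrect verdicts are impossible for the nearest-distance
method; the test suite asserts this on simulated genera. Identical
sequences shared across a species boundary produce ambiguity, never error
— which is why published tables of this design report 0% incorrect.

## Per-species separability

`species_gap_table()` gives the per-taxon view: *heterogeneity* (max
conspecific distance; 0 with a `singleton` flag for single-sample species,
since a maximum over an empty set is undefined) against *separability*
(min heterospecific distance), plus the closest relative(s), with ties
listed lexicographically. The table is computed on K2P distance for
consistency with every other stage (the original per-taxon tool works on a
similarity matrix; the ordering information is the same).
`inseparable_pairs()` reports species whose separability is *exactly* zero
— i.e. identical sequences across the boundary. Near-zero but positive
separability is deliberately not folded in: zero is the only threshold
that needs no justification, and near-ties are already visible in the
table.

## Phylogeny

`nj_tree()` implements Saitou–Nei neighbor joining with the standard
Q-criterion. Two reproducibility choices: ties in Q are broken by the
lowest (row, column) index pair in the current ordering, and negative
branch-length estimates are clamped to zero by default (the common
behavior of mainstream tree software; `clamp_negative = FALSE` restores
the raw estimates). On an additive matrix the algorithm recovers the
generating topology and branch lengths exactly, which the tests verify
against a path-length oracle on random trees. `bootstrap_nj()` resamples
alignment columns with replacement, rebuilds the tree per replicate, and
annotates each internal edge of the *full-data* tree with the percentage
of replicates containing the same bipartition (supports on the original
tree, not a consensus — matching how mainstream software annotates NJ
trees; replicates with undefined distances are dropped and the denominator
adjusted, both counts retained). `root_tree()` verifies the outgroup is
one side of a bipartition before rooting on that edge.

## The synthetic genus generator

`simulate_genus()` provides ground truth with the structure the analysis
assumes: a root sequence with exact GC composition (`gc_target`, positions
shuffled — avoiding the ~3% single-draw GC variance of i.i.d. sampling at
barcode lengths), a star phylogeny of species ancestors, and individuals
evolved independently from their ancestor under the K2P process
(`evolve_sequence()`, with site-substitution probabilities derived in
closed form from the requested branch length and κ = α/β, default 2, a
typical nuclear value).

Because K2P distances are additive in expectation, placing species
ancestors at depth (inter − intra)/2 and individuals at depth intra/2
makes the *expected pairwise* divergence exactly `intra_divergence` within
species and `inter_divergence` between species — so the divergence module
recovers the configured values without offset. The defaults encode a
genus-scale ITS2 survey: 64 species, ~6 samples/species, 248 bp, GC 0.52,
intra 0.007, inter 0.18.

`n_identical_pairs = k` plants k species pairs with no barcode
separation: both species of a pair receive their shared ancestor haplotype
for *all* samples, so cross-boundary distances are exactly zero. This is
the configuration that reproduces the identical-sister-species phenomenon:
all queries of the 2k affected species become ambiguous and none become
incorrect, and the pairs are exactly what `inseparable_pairs()` flags.

What the generator does *not* emulate — and therefore what passing tests
do not demonstrate about real data: no within-genus tree structure (a star
phylogeny matches the pooled intra/inter summaries but not clade
structure, so simulated bootstrap supports for deep edges are
uninformative); no rate heterogeneity across sites; no indel process by
default (`indel_rate` exists purely to exercise the pairwise-deletion
path); no alignment error, paralogy, or mislabeled vouchers — the factors
that dominate real identification failure. Conclusions about a real marker
require real data through `read_labeled_fasta()`.

## Problem sizes and numerical checks

The test suite validates the estimator against the closed form to 1e−9 on
constructed (P, Q) cases and against an independent K80 implementation on
simulated alignments; NJ against a path-length oracle on 200 random 5–8
leaf additive trees; the local-alignment scorer against an independent
Gotoh dynamic program; and parameter recovery on a 64 species × 6 sample
genus (the survey-scale configuration), with Monte-Carlo standard errors
estimated from the between-species spread of the per-species statistics.
Bootstrap demonstrations use 100 replicates on a 16 × 4 genus; the
`n_replicates = 1000` default matches standard practice for publication
trees.

```{r example}
sim <- simulate_genus(n_species = 8, samples_per_species = 3, seed = 1)
ev <- barcode_eval(sim$alignment, bootstrap_replicates = 50,
                   methods = "nearest", seed = 1)
ev
```

## Known limitations

- K2P only; no gamma rate correction or alternative substitution models
  (the evaluation conventions this package implements are defined on K2P).
- The rank-sum p-value ignores the dependence among pairwise distances;
  no permutation-aware alternative is provided.
- Best-hit identification scores full pairwise alignments; for reference
  databases orders of magnitude larger than a genus survey a seeded
  search would be preferable.
- The simulator's star phylogeny makes deep-edge bootstrap supports
  structurally meaningless (there is no deep structure to recover).
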
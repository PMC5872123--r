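---
title: "Methods: pan-SMGC clustering and gain/loss inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-SMGC clustering and gain/loss inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smgcpan)
```

## The problem

Closely related bacterial genomes — the motivating case is a set of 24
*Streptomyces* genomes split into two recently diverged sister clades
plus a few intermediate taxa — each carry dozens of secondary metabolite
biosynthetic gene clusters (SMGCs). Most of these clusters have no
close match in reference databases, so comparing repertoires across
genomes by annotation is hopeless. The alternative implemented here is
annotation-independent: treat each cluster as a bag of genes, identify
orthologous genes by sequence, and compare clusters by shared gene
content. On top of that representation the package computes pan-genome
structure (which cluster families are core, clade-specific, accessory or
strain-specific) and reconstructs gain and loss events on the genome
phylogeny.

## Model and procedure

### Orthology: alignment, maxbit, Markov clustering

Every gene from every cluster region is compared by exact local
alignment (Smith–Waterman with affine gaps). The scoring scheme is
pinned for reproducibility — BLOSUM62, gap open 10, gap extend 1, with a
gap of length $L$ costing $\mathrm{open} + (L-1)\,\mathrm{extend}$ —
because "aligner defaults" pin nothing; all three parts are
configurable via `scoring_scheme()`. Raw scores are normalized to the
**maxbit score**
$$ \mathrm{maxbit}(a,b) \;=\; \frac{S(a,b)}{\max\{S(a,a),\,S(b,b)\}} \in [0,1], $$
a bit-score analogue that is symmetric and equals 1 only for identical
sequences. Raw Smith–Waterman scores stand in for Karlin–Altschul bit
scores (none are derivable from the pinned scheme); the substitution is
monotone-equivalent for thresholding.

Genes with maxbit ≥ 0.04 are connected in a weighted graph, which is
partitioned by the Markov Cluster algorithm with inflation 2.0. The
0.04/2.0/maxbit triple follows the upstream orthology convention of the
study system. The cutoff is deliberately permissive — unrelated proteins
of typical length can exceed maxbit 0.04 — and MCL, not the cutoff, does
the actual separation; the orthology tests confirm that planted
ortholog groups are recovered exactly even though the similarity graph
contains many weak spurious edges.

MCL details the literature leaves open are pinned and configurable:
self-loops of weight 1, column-stochastic normalization, expansion by
squaring, inflation by entrywise power, per-entry pruning at $10^{-5}$,
convergence at max entrywise change $<10^{-6}$, iteration cap 100 (a cap
hit emits the current clustering with a warning). Each connected
component is processed independently (MCL can only split components,
never merge them), and clusters are read off the support of the limit
matrix. Group identifiers are the lexicographically smallest member
gene id, so output is independent of input order.

An optional k-mer prefilter (`prefilter_kmer = 5`, 0 disables) skips
gene pairs sharing no 5-mer before aligning, in the spirit of seeded
aligners. Near-identical orthologs always share 5-mers; only extremely
diverged pairs hovering at the cutoff could be missed, and exact mode is
one switch away.

### Family clustering

Each cluster is reduced to its set of ortholog groups, and pairs of
clusters are compared by binary Jaccard dissimilarity
$d(A,B) = 1 - |A \cap B|/|A \cup B|$. Pairs with $d \le 0.4$ are linked,
and **families are the connected components** of this network. The
source procedure names a graph library and "cluster membership" without
fixing a method; components are the minimal assumption, they match the
published network presentation, and they make membership transitive (two
clusters more distant than the threshold belong to one family if a chain
connects them). The 0.4 default reflects the observation that looser
thresholds yield no appreciable gain in family counts — reproducible
here with `threshold_sweep()`, whose family count is provably
non-increasing in the threshold. The printed threshold in the source
("≤4.0") is read as 0.4, since binary Jaccard lives in $[0,1]$.

Family ids are the smallest member cluster id; each family carries a
consensus class (majority member class, ties lexicographic).

### Pan-SMGC partition

From the family-by-genome presence/absence matrix (multi-copy families
count once for presence; copy counts are retained):

* **conserved core**: present in ≥ `core_fraction` (default 0.8) of
  *all* genomes, intermediates included in the denominator;
* **clade core (C)**: ≥ the same fraction of clade C's genomes, not
  conserved core — so clade core totals decompose as conserved +
  clade-specific (9 + 2 and 9 + 6 on the fixture);
* **strain-specific**: occupancy exactly 1;
* **accessory**: the rest.

Fractional cutoffs use the ceiling rule (80 % of 10 genomes means ≥ 8;
80 % of 24 means ≥ 20). A family reaching the core fraction in both
clades without being conserved core is assigned to the alphabetically
first clade's core for the partition (the per-clade `core_total` counts
both regardless); this corner case cannot occur at the defaults.

Sharing between two clades is reported twice, because the obvious
tabulations disagree: *overlapping* (shared-within-A means ≥ 2 A
genomes, regardless of B; *across* means ≥ 1 genome of each clade) and
*exclusive* (each non-singleton family in exactly one bin). The
fixture's printed 78/55/37 structure corresponds to the overlapping
reading.

Statistics: per-class enrichment between clades uses two-sided Welch
t-tests on per-genome class counts with Bonferroni correction (default
$\alpha/n = 0.05/22 \approx 0.0023$); "t-test" in the source is
unspecified, and Welch is the robust default (a pooled option is not
provided — the epsilon rule below covers the degenerate cases instead).
When both groups are constant, equal means give $p = 1$ and unequal
means substitute variance $\varepsilon = 10^{-8}$ (the "epsilon rule"),
keeping the statistic finite and the call significant, as it should be
for a class present in every genome of one clade and absent from the
other. Clade count comparisons (SMGC counts, ORF counts, genome sizes,
SMGC:ORF ratio) use the same Welch machinery; the genome-size/SMGC-count
association is Pearson's r (reported as NA when either variable is
constant). Frequency spectra are compared with the two-sample KS test on
occupancy observations; exact p-values where sample sizes allow, tie
warnings suppressed (occupancies are discrete by nature).

Known-cluster coverage: a query cluster is "well characterized" when ≥
70 % of its genes have a maxbit hit (at the orthology cutoff) in the
single best reference cluster. With no references the fraction is
missing and the flag is FALSE.

### Gain/loss on the phylogeny

Trees are consumed (newick), never inferred. Unrooted input is rooted
for event polarity on the branch separating the NDR clade from the rest
(midpoint rooting as fallback and option; explicit outgroup supported).

Two reconstruction criteria are provided, as complementary readings of
a verbal parsimony argument:

* **Fitch**: minimum-change reconstruction of the binary
  presence/absence character (implemented as Hartigan's generalization,
  so polytomies are handled exactly); ambiguous ancestral states are
  resolved by preferring absence, consistent with a
  horizontal-acquisition-biased prior, and the ambiguity set is
  reported. Branch events are gains (0→1) and losses (1→0); the labeled
  event count equals the parsimony minimum.
* **Dollo**: families arise once — the gain sits above the MRCA of the
  present leaves (at the root when the MRCA is the root), and one loss
  is placed on the stem of each maximal present-free subtree below it.
  Fitch's event count never exceeds Dollo's.

The frequency heuristic translates occupancy directly: within a clade,
families in 1–3 genomes (`low_freq_max`) are recent-acquisition
candidates; families missing from at most 3 genomes
(`near_core_missing_max`) but not complete are recent-deletion
candidates. The near-core bound is not numerically defined in the
source; 3 mirrors the low-frequency bound symmetrically and is
configurable. When a tiny clade satisfies both bands, the acquisition
reading wins (low frequency is the stronger signal).

## The synthetic generator: what it emulates, what it does not

`simulate_tree()` builds a Yule (unit-rate pure-birth) tree for each
ten-genome clade, grafts them at a root with the four intermediate taxa
attached along the path to the second clade (so both named clades are
monophyletic, intermediates paraphyletic between them).
`simulate_evolution()` places 30 ancestral families at the root; along
each branch of length $\ell$, families are lost with probability
$1-e^{-0.15\ell}$ and gained as Poisson($5\ell$) fresh families;
surviving families substitute residues at $0.01$ per residue per unit
length and turn over genes (loss $0.02$ per gene, gain $0.05$ per family
per unit length). Defaults were calibrated once so leaves carry on the
order of 28–47 clusters (a default-seed run gives 27–38), matching the
empirical per-genome range; gain/loss rates have no empirical estimate
to anchor them (the source provides none), so they are chosen for test
power, not biological inference.

Two construction guarantees matter for interpreting green tests:

* **Turnover budget.** Cumulative gene losses and gains per family copy
  are each capped at $\lfloor n_0/11 \rfloor$ of the birth gene count
  $n_0$, which bounds the Jaccard dissimilarity between any two copies
  by $1-(n_0-2t)/(n_0+4t) \le 0.4$. Planted families therefore cannot
  split at the default threshold *by construction* — the premise the
  recovery criterion states. Small families (under 11 genes) get no
  turnover at all; turnover realism lives in the larger families.
* **Disjoint gene universes.** New families draw fresh random genes, so
  the truth partition is unambiguous and cross-family Jaccard is exactly
  1 (a `shared_gene_frac` knob exists to stress-test family clustering
  with cross-family gene sharing).

Consequently, a green recovery test establishes that the pipeline's
inference machinery is correct on data satisfying its assumptions; it
does *not* establish robustness to real-world violations — fragmented
assemblies, mispredicted region boundaries, paralog expansions within
clusters, domain shuffling between families, or empirical substitution
processes (substitutions are uniform random replacements, chosen because
recoverability, not realism, is what the tests need). Protein lengths
(uniform 100–400) and the 22-class label distribution (NRPS and terpene
dominant) are scenery, not signal.

`paper_fixture()` is not simulated at all: it deterministically
constructs a 310 × 24 presence/absence matrix reproducing the printed
pan-genome counts of the study system — 177 singletons (57 %), nine
conserved-core families (two universal), 11/15 clade core totals,
78/55/37 sharing structure, core-loss asymmetry between the clades —
with the seed shuffling only which genomes carry the flexible families.
It exists so the downstream arithmetic has a worked example with known
answers; it says nothing about upstream sequence-level stages.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout (GenBank convention);
  strand is provenance only.
* Class labels are normalized into a closed 22-class vocabulary plus
  `"other"`; multi-product labels become `"hybrid"`.
* Alignment rejects any character outside the 20 amino acids + X, naming
  the position; empty sequences and empty Jaccard sets are errors
  (undefined), while an empty input *file* degrades to an empty result
  with a warning.
* Self-alignment scores are computed by the same DP (not a diagonal-sum
  shortcut): with X in the alphabet (BLOSUM62 X/X = −1) the full
  diagonal need not be the optimal self-alignment.
* Jaccard ties at the threshold are inclusive (`d <= t` connects), so
  `threshold = 0` still merges identical profiles.
* All randomized code paths take explicit integer seeds, restore the
  caller's RNG state, and derive sub-seeds by fixed offsets; reruns are
  byte-identical (verified in tests on every emitted file).

## Runtime scaling in the test suite

The acceptance suite must run in minutes on one CPU, so its simulations
use 24 genomes at the default substitution/turnover *rates* but fewer
ancestral families (10), 4–8 genes per family, and 60–120-residue
proteins. The full-scale defaults are exercised once (per-genome count
band) in the synthetic-data tests. Nothing is gated on environment
variables; everything runs everywhere.

## Known limitations

* No synteny or domain-order awareness: families are pure gene-content
  equivalence classes, so rearranged clusters with identical content are
  one family by design.
* Orthology operates on genes within cluster regions, not whole
  genomes; the genome-wide mode exists but is quadratic and documented
  as slow.
* Parsimony only — no likelihood gain/loss rate models; no HGT donor
  identification.
* The GenBank reader covers the region-record subset the pipeline needs
  (LOCUS length, source/region features, CDS with translations), not the
  full flat-file grammar.
* Whether the source's clustering step used components or a community
  detection routine is unknowable from the text; components are a
  documented interpretation (see the decisions discussion above), and
  alternative linkages are out of scope.
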
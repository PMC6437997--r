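---
title: "dropquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dropquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropquant)
```

# The quantification problem

Droplet scRNA-seq protocols (Drop-seq, inDrop, 10x Chromium) tag every
captured cell with a cellular barcode (CB) and every captured mRNA molecule
with a unique molecular identifier (UMI) before many rounds of PCR. Read 1
carries CB+UMI, read 2 the cDNA. Recovering a cells-by-genes molecule count
matrix therefore requires (i) deciding which observed CBs are real cells
("whitelisting"), (ii) correcting CB and UMI sequencing/PCR errors, and
(iii) collapsing PCR duplicates per cell while resolving reads that map to
more than one gene. Because tagged-end protocols produce effectively
single-end, strongly 3'-biased reads, gene-ambiguous reads are common;
pipelines that simply discard them systematically under-count genes that
share sequence with other genes. dropquant keeps those reads and resolves
them through a transcript-level parsimony model followed by an EM step.

# Pipeline model

## Initial whitelisting

All observed barcodes are tallied. A Gaussian kernel density (Scott's-rule
bandwidth) is fit to the log10 read counts of the distinct barcodes; the
threshold is the count at the largest local minimum of the density below the
rightmost density mode, i.e. the valley between the ambient mode and the
real-cell mode. We fit on the log10 scale because barcode counts span
several orders of magnitude and the two modes are only comparable there.
When no interior minimum exists (unimodal or degenerate tallies) the
threshold falls back to `max(10, 0.01 * max(count))`, capped at
`max(count)` so the whitelist is never empty; the cap matters for the
degenerate all-counts-equal case, where the whole tally is admitted. The
initial whitelist is deliberately liberal; the final decision is made by a
classifier after quantification.

Each non-whitelisted barcode is corrected to a whitelisted barcode from
which it can be obtained by one substitution, one insertion followed by
clipping of the terminal base, or one deletion followed by appending a
base. Substitution labels are preferred over indel labels; remaining ties
are broken uniformly at random under a named, recorded seed; barcodes with
no candidate are noise and their reads are dropped. Because barcodes are
short, candidates are found by enumerating the one-edit neighborhoods of
the whitelisted barcodes rather than by all-versus-all edit distance.

## Pseudo-mapping to equivalence classes

Reads are assigned to transcript *equivalence classes* by a stranded k-mer
index (default k = 31, forward strand only — the protocols are stranded, so
a shared reverse complement cannot cause multimapping). A read's class is
the intersection of the transcript sets of its indexed k-mers, accepted
when at least a fraction τ = 0.8 of its k-mers hit the index. This
intersection-with-coverage rule is the module's central approximation: it
stands in for a full selective aligner and is adequate for synthetic data,
but it is position-free — within-transcript fragment coordinates are never
used downstream, only class identity. k-mers containing N are skipped on
both sides; with `keep_duplicates = TRUE` (default) sequence-identical
transcripts are retained rather than collapsed.

The per-gene *sequence uniqueness* statistic — the fraction of a gene's
distinct forward k-mers found in no other gene — uses the same
non-canonical k-mer convention and stratifies all multimapping analyses.

## Parsimonious UMI graph deduplication

Within a cell, every distinct (UMI, equivalence class) pair becomes a
vertex with its read count. Two vertices whose classes share a transcript
are connected when their UMIs are within Hamming distance 1: by a
*directed* edge i→j when `c_i > 2 c_j − 1` and the distance is exactly 1
(an error with a clear direction of duplication), otherwise by a
*bi-directed* edge (same molecule sampled at a different fragmentation
position — this includes Hamming-0 pairs, the same UMI split across
classes — or an error without clear direction). After edge formation the
counts play no further role.

A *monochromatic arborescence* is a rooted tree (directed edges forward,
bi-directed either way) whose vertices' transcript sets have a non-empty
intersection; it represents one pre-PCR molecule. Deduplication seeks a
minimum-cardinality covering of the graph by vertex-disjoint monochromatic
arborescences. The decision version of this covering problem is
NP-complete (by reduction from dominating set: make every edge bi-directed
and label each node with its closed neighborhood), so a greedy algorithm
is used: per weakly connected component, grow from every remaining
(vertex, transcript) pair the largest arborescence reachable under that
color, emit the largest, delete its vertices, repeat. An exact
subset-DP solver (`brute_force_cover()`, guarded to ≤ 12 vertices) exists
purely as a test oracle; on random 8-vertex graphs the greedy covering
matches the exact minimum in ≈ 98% of instances and can never beat it.

Numerical/tie-break choices: arborescence size is vertex cardinality; ties
are broken by smallest vertex insertion index, then lexicographically
smallest transcript, so the covering is deterministic without a seed;
components are processed in order of their smallest vertex index; when
directed edges exist in both orientations both are kept (unreachable for
integer counts, but stated for completeness).

A note on thresholds: the classic directional UMI-collapsing rule is
usually quoted as `c_m > 2 c_n + 1`, while the PUG's directed edges use
`c_i > 2 c_j − 1`. The graph rule governs construction here; near-tie
pairs that the directed rule leaves unordered are still connected by a
bi-directed edge, so the covering — not the edge rule alone — decides
whether they collapse.

## EM over gene-ambiguous molecules and tiers

Each arborescence's feasible transcript set is mapped to genes. A single
gene increments that gene's count by one; several genes yield one
*ambiguous molecule* carrying a gene set. Ambiguous molecules are then
distributed by EM: the E-step assigns each molecule fractionally to its
genes in proportion to current abundances (uniformly while all are zero),
the M-step resets abundances to unique counts plus assigned fractions.
There is no effective-length term: in tagged-end protocols fragment
generation is taken proportional to abundance alone. Convergence is
declared when the largest absolute count change drops below `tol = 1e-3`
(counts are on the molecule scale, so this is far below half a molecule);
`max_iter = 1000` bounds runtime. Each ambiguous arborescence carries
weight one — it is one molecule — regardless of its read count. Totals are
conserved: the output sums to unique molecules plus ambiguous molecules.

Per cell, genes receive an evidence *tier*: 0, no reads; 1, only
single-gene classes (class "size" is counted in genes, so a
multi-transcript class of one gene is still unique evidence); 2, genes in
a transcript-graph component (built over multi-gene classes) that touches
tier-1 evidence — these are the genes the EM can actually resolve; 3,
components with no unique anchor, whose counts are split essentially
uniformly and should be treated as family-level signal only. Optional
per-cell bootstraps resample reads (multinomial over the cell's
(UMI, class) records) and rerun the whole deduplication, so error-edge
structure can change across replicates; the per-gene variance is reported.

## Final whitelisting

Barcodes above the knee are ranked by count and split into a high-quality
upper half H and an ambiguous lower half L; `n_l = max(0.2 |H|, 1000)`
barcodes immediately below the knee form the low-quality training set. A
Gaussian naive Bayes classifier is trained on H versus the low set over
quantification-derived features: mapped-read fraction, duplication rate
`(mapped − molecules) / mapped`, mean gene count `molecules / genes
expressed`, optional mitochondrial and rRNA read fractions, and optionally
the maximum Spearman correlation of log1p gene counts against the H cells
(Spearman, because the count distribution is heavy-tailed; computed over
all of H at desk scale). Ambiguous barcodes with posterior ≥ 0.5 join the
final whitelist; H always survives. Class-conditional variances get
`1e-9 × max feature variance` added so constant features stay
well-defined. The duplication-rate and mean-gene-count formulas are our
definitions — the features are conventionally named but not conventionally
formalized. When a user supplies an external whitelist it is used as the
fixed final whitelist and both the knee and the classifier are skipped.

Because the classifier needs features for its negative class, the `n_l`
training barcodes below the knee keep their own reads and are quantified
as cells; they are exempted from one-edit correction into the whitelist.
All other sub-knee barcodes are corrected or discarded as usual.

# The simulator

`simulate_transcriptome()` + `simulate_reads()` emulate, per molecule: a
Gamma-weighted gene choice, a uniform random UMI (collisions possible), a
per-copy PCR branching process (`pcr_cycles` rounds, duplication
probability `pcr_dup_prob`, per-base per-cycle substitutions on the CB+UMI
tag of new copies), per-copy capture (`capture_prob`), a 3'-biased
fragment (exponential end offset with mean `100 / bias` bases), and
per-base sequencing errors on both reads. Ambient barcodes emit low-count
molecules from the pooled abundance profile. Gene pairs can share a
3'-terminal block sized so the shared fraction of distinct 31-mers equals
the requested sharing; extra isoforms share a 3' suffix of their gene.
Everything is seeded and a JSON manifest records the configuration; the
same seed gives byte-identical FASTQ.

Defaults (50 cells, 100 single-isoform 500-bp genes, 16-base CB, 12-base
UMI, ~100 molecules per cell, 4 PCR cycles at 90% efficiency, 60% capture,
~1% per-read UMI error, 400 ambient barcodes) describe a desk-scale
10x-v3-like library. The 12-base UMI is the current 10x chemistry and, at
these molecule counts, keeps within-gene UMI collisions negligible (the
birthday bound at ≤ 10^3 molecules per gene gives ≪ 0.001 expected
Hamming-0 collisions per gene), which is what makes exact closed-loop
recovery a fair expectation. Real-cell barcodes are drawn with pairwise
Hamming distance ≥ 3 so one-edit correction is well posed — real curated
whitelists are not guaranteed to satisfy this.

What the simulator does *not* model: quality-score-conditioned error
profiles, doublets, intronic/intergenic sequence, positional coverage
structure beyond the single 3'-bias knob, and library-size heterogeneity
between cells beyond Poisson molecule counts. Passing closed-loop tests
therefore demonstrates algorithmic correctness under the stated generative
model, not performance on real libraries.

# Problem sizes used by the test suite

The suite and `scripts/acceptance.R` run entirely from simulation: the
closed-loop experiments use 50 cells × 100 genes (≈ 5,000 molecules; the
noisy arm amplifies to ≈ 55,000 reads); the multimapping experiment uses
10 cells × 300 genes with 50 gene pairs at each sharing level 0/0.5/0.9
and fragment = read placed uniformly, so read ambiguity tracks sequence
sharing rather than fragment-length geometry; solver comparisons use 500
random PUGs of ≤ 8 vertices against the exact subset-DP solver, 50
dominating-set reductions, and 100 single-transcript gene instances
against an independently coded directional clusterer. These sizes were
chosen as the smallest at which the statistical checks are stable.

For the multimapping comparison the summary statistic is the aggregate
relative error `Σ|est − truth| / Σ truth` over the 50 replicate genes:
per-gene ratios are undefined at zero true counts and unstable near zero,
while the aggregate form preserves the per-gene comparison direction.

# Known limitations

- The k-mer pseudo-mapper is not a selective aligner; on real data its
  class assignments would be noisier, and range-factorized (position-aware)
  classes are not produced. Fragmentation-position splitting is healed in
  the PUG instead (Hamming-0 bi-directed edges).
- The greedy covering is not optimal (the problem is NP-complete); its
  measured optimality gap on small random graphs is ~2%.
- EM runs per cell with no pooling across cells, so genes with no unique
  anchor in a cell are split uninformatively there (tier 3 flags exactly
  this).
- The exact solver is exponential and guarded to 12 vertices; it exists
  for verification, not production.
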
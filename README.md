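# dropquant

Gene-level quantification of droplet single-cell RNA-seq (dscRNA-seq)
experiments, from demultiplexed FASTQ to a cells × genes molecule count
matrix — with the UMI deduplication done on a **parsimonious UMI graph
(PUG)** instead of per-gene or per-equivalence-class collapsing, so reads
that map to several transcripts or genes are resolved rather than thrown
away. A built-in droplet-protocol simulator with full ground truth makes
every stage testable in a closed loop.

## Who this is for

Anyone who wants a compact, fully inspectable implementation of the
end-to-end dscRNA-seq quantification stack — cell-barcode whitelisting,
barcode correction, equivalence-class mapping, graph-based UMI
deduplication, EM resolution of gene-ambiguous molecules, evidence tiers,
and classifier-based final whitelisting — in pure R, at desk scale.

## The method in brief

For each cell, every distinct (UMI `u`, transcript equivalence class `T`)
pair becomes a vertex `v = (u, T)` with read count `c(v)`. Edges connect
vertices that can share a pre-PCR molecule of origin:

- **directed** `v_i → v_j` when `c_i > 2 c_j − 1`, `|T_i ∩ T_j| > 0` and
  the UMIs are at Hamming distance 1 (a PCR/sequencing error whose
  direction of duplication is clear);
- **bi-directed** when `d(u_i, u_j) ≤ 1` and `|T_i ∩ T_j| > 0` otherwise
  (the same molecule sampled at different fragmentation positions, or an
  error without clear direction).

A *monochromatic arborescence* is a rooted tree in this graph whose
vertices' transcript sets intersect; it represents a single pre-PCR
molecule. Deduplication = **minimum-cardinality covering by vertex-disjoint
monochromatic arborescences**. The decision problem is NP-complete
(reduction from dominating set), so a greedy largest-arborescence-first
covering is used, with an exact subset-DP solver (≤ 12 vertices) kept as a
test oracle. Arborescences whose feasible transcript set spans several
genes become *ambiguous molecules* and are distributed by an EM with no
effective-length term; each gene's count additionally carries an evidence
tier (0 none, 1 unique-only, 2 ambiguous-but-anchored, 3 fully ambiguous).
Whitelisting is two-step: a liberal KDE-knee threshold on log10 barcode
counts up front, and a Gaussian naive Bayes classifier over
quantification-derived features at the end.

## Worked example

```r
library(dropquant)

cfg <- sim_config(seed = 42, n_cells = 20, n_genes = 50,
                  molecules_per_cell = 80)
sim <- run_simulate(cfg, "sim42")          # writes FASTQ + truth tables
#> sim_experiment: 20 cells (+400 ambient), 50 genes, 3618 molecules, 28195 reads

res <- run_quant("sim42/reads_1.fastq", "sim42/reads_2.fastq",
                 "sim42/transcriptome.fa", "sim42/t2g.tsv",
                 out_dir = "quant42",
                 geometry = barcode_geometry(cb_length = 16, umi_length = 12))
res$manifest$stage_counts
#> $reads_in: 28195        $reads_mapped: 26349
#> $barcodes_observed: 823 $barcodes_whitelisted: 20
#> $barcodes_final: 20     $molecules_out: 4004

truth <- sim$truth$counts
est <- as.matrix(res$quant$counts)[rownames(truth), colnames(truth)]
sum(truth); sum(est)
#> [1] 1615
#> [1] 1614.04
cor(colSums(truth), colSums(est), method = "spearman")
#> [1] 1
est[1:3, 1:5]
#>                  g0001 g0002 g0003 g0004 g0005
#> TTTACACTTAGGCGCG     2     1     0     1     1
#> CATGAATGACTCTAGC     5     1     0     4     2
#> GAAACTTCTTTGGAAC     9     2     0     3     1
```

Reading the numbers: 28,195 reads (cells + ambient + PCR duplicates +
errors) collapse to 4,004 molecules across all quantified barcodes; the
knee finds exactly the 20 real cells; on those cells the 1,615 true
pre-PCR molecules are recovered to within one molecule and per-gene totals
are rank-identical to the truth. `res$quant$tiers` holds the matching
evidence-tier matrix, and `quant42/` contains the MTX count matrix, tier
TSV, final whitelist and a JSON run manifest.

A thin command-line front end with `quant`, `simulate`, `uniqueness` and
`dump-pug` subcommands lives at `inst/cli/dropquant.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/dropquant.R", package="dropquant"))') quant --help`).

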
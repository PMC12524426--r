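# crhub

Cis-regulatory hub analysis from chromatin activity and 3D genome contacts.

Distal enhancers choose their target genes through 3D proximity, and groups
of enhancers and promoters that contact each other assemble into
*cis-regulatory hubs* (CRHs). Architectural proteins such as CTCF insulate
topologically associating domains (TADs) and thereby constrain which
elements can meet; when CTCF is lost, boundaries weaken, ectopic
enhancer–promoter contacts appear, and hubs reorganize. `crhub` implements
the full analysis chain needed to study this at the level of processed
genomics files, for anyone working with paired ATAC-seq / H3K27ac /
HiChIP-style data in one or two conditions (e.g. control vs. a CTCF
depletion).

## What it computes

**Activity-by-contact (ABC) scoring.** A candidate element *E* (merged
ATAC/H3K27ac peaks) is linked to gene *G* by

```
ABC(E, G) = A_E * C_EG / sum over e in window(G) of (A_e * C_eG)
```

where `A = sqrt(ATAC * H3K27ac)` is the element's activity, `C` is the
binned contact count between the element and the TSS (with a
distance-decay pseudocount), and the window spans 5 Mb around the gene.
Scores per gene sum to 1; pairs with `ABC >= 0.01` form the enhancer–gene
pair set.

**CRH construction.** Thresholded pairs are edges of a bipartite
promoter/element graph; each connected component (igraph) is one hub.
Summary statistics include connections per gene / per enhancer and the
elements-per-hub distribution, plus two-condition comparisons: shared
pairs, score redistribution, hub merging/splitting, and CTCF site
enrichment by an exact test.

**TAD calling.** Per-bin directionality index
`DI = sign(B - A) * ((A - E)^2/E + (B - E)^2/E)` with upstream/downstream
contact sums `A`, `B` within a 2 Mb window and `E = (A + B)/2`; boundaries
sit where strong negative runs flip to strong positive runs. Hubs are then
classified as within one TAD, spanning several, or outside.

**APA.** Aggregate peak analysis over a loop list: mean submatrix around
loop anchors, scored as center over the lower-left corner mean, with a
z-score, optionally observed-over-expected normalized.

**Differential co-regulation.** Pearson correlation of gene-expression
log2 fold changes against linked-enhancer signal changes, per pair and per
hub (all co-resident combinations), with an effect-size filter.

**Synthetic data.** `simulate_dataset()` generates the complete paired
input set (peaks, gene table, contact matrices, loops, CTCF sites,
differential tables) with planted TADs, hubs, dominant enhancers and
co-regulation, and returns the ground truth so every stage can be checked
against what was planted.

## Worked example

```r
library(crhub)

cfg <- simulation_config(seed = 42)   # 20 Mb, 10 TADs, 60 genes, 300 enhancers
d <- simulate_dataset(cfg)

el <- define_candidates(d$atac, d$h3k27ac, promoter_windows(d$genes))
el <- compute_activity(el, d$atac, d$h3k27ac)
pairs <- threshold_pairs(compute_abc_scores(el, d$genes, d$contacts_control))
crhs <- build_crhs(pairs)
crhs
#> crh_set: 9 hubs, 311 members, 776 edges

st <- hub_stats(crhs)
c(st$mean_connections_per_gene, st$mean_connections_per_enhancer)
#> [1] 12.93 3.09

tads <- call_tads(directionality_index(d$contacts_control))
classify_crh_tads(crhs, tads)$fractions
#>     within_one spans_multiple        outside
#>          0.889          0.111          0.000

aggregate_loops(d$contacts_control, d$loops_control, normalize = "expected")
#> apa_result: score 5.050, z 87.185, 60 loops used (0 skipped)

hub_coregulation(crhs, d$gene_lfc, d$enh_lfc)$r
#> [1] 0.367
```

776 element–gene pairs pass the 0.01 cutoff and collapse into 9 hubs — one
per planted TAD (one planted hub merges across a weak boundary at this
seed). 88.9% of hubs stay within a single called TAD. The planted 5x loops
return an APA score of 5.05, and the hub-level co-regulation recovers a
correlation of 0.37 against the planted mixture (base rho 0.3 plus a
strong-effect subset). Running the same scoring on `d$contacts_ko` (the
weakened-insulation condition) yields more pairs, fewer and larger hubs,
lower mean ABC scores, and a larger fraction of hubs spanning multiple
control TADs — the qualitative signature of CTCF loss.

`run_pipeline()` wires the same steps end to end from file paths and writes
TSV/JSON outputs plus a run manifest; `inst/scripts/crhub.R` exposes
`simulate`, `run`, `tads` and `apa` subcommands for shell use.

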
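---
title: "crhub: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crhub: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented by `crhub`: the models and
statistics, the assumptions behind them, the tunable parameters, what the
synthetic generator does and does not emulate, and the design choices that
were genuinely open.

## The activity-by-contact model

An element's regulatory effect on a gene is taken to be proportional to the
product of its chromatin *activity* and its 3D *contact* with the gene's
promoter, normalized against all candidate elements competing in the same
window:

$$\mathrm{ABC}(E,G) = \frac{A_E \, C_{EG}}{\sum_{e \in W(G)} A_e \, C_{eG}}$$

- **Candidates** are the union of ATAC and H3K27ac peaks ("and/or": either
  mark qualifies), merged where they overlap, padded/clipped to widths in
  `[min_width, max_width]` (defaults 500 bp / 10 kb) around the merged
  midpoint. Candidates overlapping a promoter window (TSS ± 500 bp) are
  flagged promoter-proximal and excluded from distal pairing by default;
  they are flagged rather than deleted so a user can audit them.
- **Activity** is the geometric mean `sqrt((ATAC + eps)(H3K27ac + eps))`
  with `eps = 0.1`. The geometric mean is the reference ABC combiner and is
  symmetric in the two assays; the pseudocount keeps single-assay elements
  at a nonzero floor. Peak signal is treated as uniform over the peak, so a
  peak contributes `signal * overlap / peak_width` to an element
  (equivalent to per-base integration of the signal density).
- **Contact** is the count at the (element-midpoint bin, TSS bin) of a
  binned matrix (default 10 kb resolution), plus a pseudocount equal to 1%
  of the matrix's own fitted power-law expectation at that distance. The
  pseudocount prevents exact zeros from annihilating scores while scaling
  with the library like every other count; fitting the matrix's own decay
  (log-log regression of per-offset mean counts) keeps it calibrated to
  whatever normalization the matrix arrived with. Same-bin pairs use the
  diagonal entry, with the pseudocount distance floored at one bin.
- **Window and normalization.** The window is 5 Mb total, centered on the
  gene TSS. Normalizing per gene is the only reading under which a gene's
  scores sum to 1 and a fixed cutoff (0.01) is meaningful across genes, so
  per-gene is the default; `per_element_norm = TRUE` provides the
  element-centered denominator for comparison. Scores are computed only for
  expressed genes (`expression > 0.5`, configurable) — the floor controls
  how many genes enter, and 0.5 FPKM is a conventional expressed/silent
  split.
- **Threshold.** Pairs with score ≥ 0.01 form the enhancer–gene pair set.
  The cutoff must lie strictly inside (0, 1).

Invariants worth knowing: pre-threshold scores per gene sum to 1; scores
are invariant to rescaling all activities or all contacts; raising one
element's activity strictly raises its own score and weakly lowers every
competitor's for the same gene.

## Cis-regulatory hubs

Thresholded pairs are edges of a bipartite graph whose node classes are
promoters and distal elements. A CRH is a connected component with at least
one edge. Hub ids are assigned deterministically (descending member count,
ties by leftmost coordinate) so outputs are diffable. Both promoters and
enhancers count as hub "elements" when sizes are reported — consistent
with the smallest possible hub having 2 members.

For two-condition comparisons, element identity is not stable across runs,
so hubs are matched by *locus*: genes by id, elements by ≥ 1 bp overlap.
Each reference hub is labeled:

- `dissolved` — no condition-B hub shares a member;
- `split` — members land in ≥ 2 B hubs;
- `merged` — its B hub also contains members of other reference hubs;
- `conserved` — one-to-one mapping with member Jaccard ≥ `jmin` (0.5).

The label set must partition all hubs; the one case the definitions above
leave open — a one-to-one mapping whose Jaccard falls below `jmin` — is
assigned `merged` (the hub was absorbed into a substantially different
hub). `jmin` is a strictness knob with no canonical value; 0.5 means "most
members retained".

CTCF enrichment between the two hub populations uses a 2×2 table over hub
member elements (rows: condition; columns: overlaps ≥ 1 site or not). The
two-sided exact p sums all hypergeometric tables with fixed margins whose
probability does not exceed the observed one — implemented directly so the
convention is explicit, and cross-checked against both full enumeration
and `fisher.test` in the test suite. Zero margins get a Haldane 0.5
correction and a flag.

## TAD calling with the directionality index

For bin *i*, with `A` / `B` the summed contacts to bins up to `window`
(default 2 Mb) upstream / downstream and `E = (A+B)/2`:

$$\mathrm{DI}(i) = \mathrm{sign}(B-A)\left(\frac{(A-E)^2}{E} + \frac{(B-E)^2}{E}\right)$$

DI is 0 when `A = B` or `E = 0`, and is masked at bins without full window
coverage. Classic DI pipelines post-process this statistic with an HMM;
`crhub` instead uses a deterministic run-based rule: a boundary is placed
where a negative run (domain end) is followed by a positive run (domain
start) and both runs reach the `magnitude_quantile` (default 0.8) of |DI|.
This keeps the caller reproducible and directly testable; the quantile and
`min_tad_size` (100 kb) are exposed. The deterministic rule is a deliberate
simplification — it calls sharp boundaries well but has no smoothing, so
very noisy tracks produce conservative boundary sets. A consequence of
masking is that boundaries closer than one window to a chromosome end are
not observable.

DI sums are accumulated offset-by-offset, adding identical stored values to
the upstream sum of one bin and the downstream sum of another, so on a
translation-invariant matrix `A == B` holds *exactly* in floating point and
the DI is identically zero.

Hub/TAD classification counts the distinct TADs overlapped by hub members
(elements by interval, genes by TSS): one → `within_one`, several →
`spans_multiple`, none → `outside`. Judging by member positions rather than
the hub's convex hull means an unrelated TAD lying between two member
clusters is not counted.

## Aggregate peak analysis

The `(2f+1)`-square submatrices centered on loop anchor bin pairs
(anchor1 upstream) are averaged; the APA score is the center cell over the
mean of the `c × c` lower-left corner (max row, min column — the
short-distance background), `f = 10`, `c = 3` by default. The z-score
standardizes the center by the corner cells' mean and standard deviation; a
zero-variance corner yields a flagged undefined z (0 only in the fully
flat case where the center equals the corner). Loops whose flanks leave
the matrix or whose anchors are closer than `2f+1` bins are skipped and
counted — closer loops would let the center or corner touch the diagonal.
`normalize = "expected"` divides each cell by the matrix's mean count at
that bin offset (observed-over-expected; offsets without data fall back to
the fitted power law), which removes the distance-decay gradient across
the aggregate.

## Differential co-regulation

Gene log2 fold changes are joined by id; enhancer fold changes are joined
to elements by maximal locus overlap with the differential peak table
(unmatched records are counted and dropped). The pair-level correlation
uses one observation per thresholded pair; `min_abs_lfc = 0.5` reproduces
the effect-size-filtered variant. Hub-level co-regulation correlates *all*
gene × enhancer combinations co-resident in a hub — the hub concept
implies shared regulation beyond direct edges — with `direct_only = TRUE`
as the restrictive alternative. Correlations are Pearson with the
two-sided t-transform p; no multiple-testing correction is applied or
claimed (single-test module). The top-genes analysis ranks genes by
expression (ties broken lexicographically for determinism) and compares
member counts of hubs containing vs. lacking those genes with a two-sided
Wilcoxon rank-sum test (normal approximation with tie correction, no
continuity correction).

## The synthetic generator

The generator plants a fully known truth at desk scale — defaults: one
20 Mb chromosome at 10 kb (2,000 bins), 10 equal TADs, 60 genes, 300
enhancers, one hub per TAD — and emits every file the pipeline reads. Key
conditions, chosen once as a coherent benchmark:

- **Geometry.** Boundary margins of 500 kb keep a ≥ 1 Mb element-free dead
  zone across each boundary, mirroring the depleted regulatory density at
  real boundaries and making "one hub per TAD" a well-posed truth.
  Enhancers cluster around their hub's gene TSSs (Gaussian sd 100 kb, the
  typical enhancer–promoter range) but stay ≥ 25 kb from every TSS: the
  planted elements are *distal* elements by construction.
- **Activities.** Log-normal with `sdlog = 0.3`: planted members are
  uniformly genuine regulators. No inactive background peaks are planted —
  real peak lists would add noise candidates that the ABC threshold
  filters; passing tests therefore demonstrate recovery of true structure,
  not robustness to a background peak load.
- **Dominant enhancers.** Each gene's nearest unassigned enhancer at
  ≥ 250 kb becomes its dominant enhancer: 10× activity plus a planted loop
  (5× contact). The distance floor keeps loop anchors many bins apart —
  resolvable at 10 kb and usable by APA flanks. In the full landscape a
  gene's top-scoring element can still legitimately be *another* gene's
  nearby dominant (hubs share enhancers); the isolated property "the
  planted dominant tops its own gene" is exercised with one gene per hub.
- **Contacts.** Expected counts `scale * d^(-alpha)` (`scale = 1000`,
  `alpha = 1`), multiplied by `insulation` (control 0.1) across boundaries
  and by `loop_strength` (5) at planted loop pixels; realized counts are
  negative-binomial (dispersion 0.1). The depth is that of a deeply
  sequenced library: at shallow depth, single stray ligation counts at
  cross-TAD range can clear the 0.01 cutoff for high-activity elements and
  corrupt the planted hub structure.
- **Paired conditions.** The KO condition must *weaken* insulation
  (`ko_insulation = 0.6 > 0.1`; values closer to 1 mean weaker boundaries)
  and removes boundary-anchored loops. Both conditions consume one shared
  uniform noise stream through the negative-binomial inverse CDF, so the
  KO matrix differs from the control only through the planted mechanism —
  as a paired perturbation of the same cells would, and without
  resampling churn contaminating condition contrasts.
- **Differential effects.** Each hub draws a shared factor; member log2
  fold changes load on it with `sqrt(rho)` (`rho = 0.3`), so hub-mates
  correlate at `rho`. A 20% subset of hubs gets `rho = 0.7` and doubled
  scale, planting the strong-effect population that an |lfc| ≥ 0.5 filter
  enriches.

What the generator does **not** emulate: background (non-regulatory)
peaks, replicate-level variability, trans contacts, nested or hierarchical
TADs, unequal TAD sizes, mapping artifacts, and matrix-balancing effects.
Results on synthetic data therefore validate the machinery and its
qualitative behavior under boundary loss, not performance on the full
noise spectrum of real data.

## Numerical and scale choices

- All coordinates are 0-based half-open internally (BED convention);
  GRanges conversions happen only inside overlap queries.
- Chromosome names are matched by exact string equality; a disjoint
  vocabulary raises a warning naming the union rather than silently
  renaming.
- Contact matrices are stored sparse and symmetric; readers sum duplicate
  COO entries and treat absent cells as zero. Contacts are materialized to
  a 3 Mb offset by default in the generator — beyond the 2.5 Mb scoring
  radius, expected counts are negligible.
- Test and acceptance runs use the default desk-scale configuration
  (2,000-bin chromosome; 10–20 seeds per stochastic property), sized so
  the full suite completes in a couple of minutes while leaving clear
  margins on every planted effect.
- Deterministic tie-breaks throughout (hub ordering, gene ranking, band
  selection) so repeated runs are byte-identical; `run_pipeline()` writes
  a manifest with resolved parameters and input digests.

## Known limitations

- The DI boundary caller has no HMM smoothing; closely spaced or very weak
  boundaries merge into single domains, and boundaries within one DI
  window of a chromosome end are unobservable by construction.
- Per-gene ABC normalization makes scores comparable within a gene but not
  a measure of absolute regulatory strength across genes.
- Locus-overlap hub matching treats any ≥ 1 bp overlap as identity; at
  coarse peak widths this can over-join dense element clusters.
- The exact test is computed on element counts pooled over hubs, treating
  elements as independent; spatial autocorrelation within hubs is ignored.
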
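---
title: "Methods: chromosome-scale homology testing for WGD ohnolog inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome-scale homology testing for WGD ohnolog inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogon)
```

## The model

Early vertebrate evolution includes two rounds of whole-genome
duplication: WGD1 before the split between agnathans (lampreys,
hagfishes) and gnathostomes (jawed vertebrates), and WGD2 after it, on
the gnathostome side; agnathan lineages additionally underwent their own
polyploidization, commonly modeled as a triplication. A gene family
created by these events — ohnologs — leaves a chromosome-scale
footprint: the chromosomes carrying the duplicates descend from one
ancestral chromosome, so *all* genes on them, not just the family of
interest, should show a skewed pattern of cross-genome similarity.
`paralogon` turns that footprint into statistics.

The procedure has four stages.

**1. Best-hit classification.** Protein-level similarity hits (BLAST
outfmt 6) are collapsed to gene level through an explicit
protein-to-gene map, filtered at a significance threshold (default
E ≤ 1e-5; BLAST output conventions never define "significant", so the
threshold is a visible parameter recorded in every report header), and
reduced per query gene to the three highest-scoring distinct subject
genes. A query is *solo* when exactly one distinct significant subject
exists — judged before truncation to three, since a gene with four weak
distinct subjects plainly has more than one match. Ranking ties break by
bit score (descending), then e-value (ascending), then subject id; the
id tie-break is arbitrary but makes every downstream number reproducible
under permutation of the input.

Collapsing isoforms *before* picking the three best subjects (rather
than after) is a deliberate choice: the alternative lets one gene's
isoforms occupy all three slots. The per-query summaries aggregate into
the count matrix: per (query chromosome × subject chromosome) the
"top", "total" and "solo" counts, with per-query-chromosome denominators
(`n_queries_with_hits`, `n_solo_queries`). "Total" counts query genes
once per subject chromosome, not hits, so one query contributes at most
three total counts. The invariants (solo ≤ top ≤ total per cell; top and
solo column sums equal to the denominators; total sums at most three
times the query count) are enforced by `validate_count_matrix` and
exercised on random simulations in the test suite.

One tempting invariant is false and deliberately not enforced:
tightening the significance threshold does not monotonically decrease
per-cell counts, because removing a query's best subject can *shift* its
top attribution to another chromosome. What shrinks monotonically is the
evidence itself — the significant-hit set, each query's distinct-subject
count, and the number of queries with hits — and that is what the tests
assert.

**2. Chromosome-association tests.** The subject chromosomes descending
from the two WGD1 copies of the ancestral chromosome form two groups
(for the synuclein region: human {4, 5} vs {2, 8, 10}); chromosomes
outside both groups are ignored. For two query chromosomes, pooling a
count column over each group gives a 2×2 table tested with the Pearson
chi-square, X² = N(ad−bc)²/((a+b)(c+d)(a+c)(b+d)), df = 1, upper-tail
p. No Yates continuity correction is applied: the pooled tables here
have hundreds of observations where the correction is both unnecessary
and a mismatch to the closed form above (the correction changes the
top-column 8-vs-41 statistic from 7.86 to 7.21). Statistics are reported
at 2 decimals, p-values at 3, percentages at the nearest integer; the
unrounded values are returned by the functions.

A Monte-Carlo conditional permutation check (`permutation_chi_square_p`,
drawing tables with the observed margins via `r2dtable`) accompanies the
asymptotic p. The conditional null is discrete, so its plain p-value
systematically exceeds the continuous asymptotic p on sparse tables (the
8-vs-22 solo table, with a zero cell, is a clear example); the *mid-p*
(half-weighting ties) is the appropriate comparator against a continuous
reference, and agreement within Monte-Carlo error is expected — and
tested — only for tables whose expected cells are in the asymptotic
regime. Degenerate tables (a zero marginal) are refused with an error;
all-zero pooled tables are flagged untestable rather than tested.

**3. Local synteny.** Neighborhoods are the anchor gene plus up to five
genes on each side, in rank order (ranks are recomputed from coordinates
on read, with start/end/id tie-breaks, so input row order never
matters). Each flank gene maps to its best subject under the same
ranking rules as stage 1. Homology families are connected components of
best-hit links restricted to the compared neighborhoods — genes sharing
a best subject belong to one family. Order congruence is the absolute
Kendall rank correlation over shared families, so an exactly reversed
ordering scores 1: a chromosomal inversion preserves synteny. Orientation
congruence is the fraction of shared families whose relative
query/subject strand agrees. With fewer than two shared families the
order score is undefined and reported as `NA`, not zero.

Conserved blocks are maximal runs of families present — forward or
reversed, contiguously in family space — in enough neighborhoods.
Between consecutive block members, up to `gap_budget` (default 2)
*unlabeled* genes may intervene; a gene carrying a different family
label breaks the run. The default budget of 2 reflects how often
single-gene insertions interrupt otherwise conserved vertebrate blocks;
it is a visible parameter. Maximality means no reported block is a
contiguous sub-block of a longer reported block whose member set covers
it. Small-instance behavior is pinned to an exhaustive enumeration
oracle in the tests.

**4. The solo-gene loss-scenario model.** Three loss histories leave a
single human match for a lamprey query gene: (a) one loss after WGD1 but
before the agnathan/gnathostome split plus one after WGD2; (b) two
gnathostome losses, one before and one after WGD2; (c) three gnathostome
losses after WGD2. `ortholog_probability` enumerates every copy-loss
assignment, choosing uniformly which copy each unspecified loss strikes —
that symmetry assumption is what the probabilities rest on, so it is
explicit — and conditions on exactly one human survivor. Scenario (a)
forces orthology (probability 1); (b) and (c) give 1/2; under a per-loss
probability p, scenario (c) is rarer than (a) or (b) by exactly one
factor of p. The bias makes solo genes informative markers of
chromosome correspondence.

`simulate_solo_bias` demonstrates the bias with the genome simulator:
WGD1, a shared loss epoch, the split, per-lineage losses, gnathostome
WGD2, a final loss epoch (all at retention r), then noise-free
classification. The shared pre-split epoch matters: without it scenario
(a) cannot arise and the solo ortholog fraction is exactly 1/2. The solo
fraction is compared against the *match-level* ortholog fraction of
non-solo queries (all their distinct significant subjects, before
truncation), because that is the fair baseline: a multi-match query's
matches cannot be told apart without score information, whereas with
noise-free scores its *top* match is almost always the ortholog, which
would measure score resolution rather than the loss-history asymmetry.

## The genome simulator

`simulate_history` evolves an ancestral genome through an ordered event
schedule: shared events, a lineage split, then per-lineage events. Event
kinds are WGD (integer multiplier m ≥ 2; m = 3 models the agnathan
hexaploidization, treated as a single triplication — the
allo-/autopolyploid distinction is not modeled), chromosome fusion
(concatenating gene orders), loss epochs (each gene copy retained
independently with probability r, optionally overridden per chromosome
to model preferential retention), and transposition epochs (each gene
moved with probability q to a uniform position on a uniform chromosome,
keeping its strand with probability 1/2). Losses are i.i.d. per copy per
epoch — the simplest exchangeable model; preferential retention is
available as per-chromosome overrides rather than built in. Divergence
is counted in discrete epochs, not continuous time, because only the
ordinal depth structure matters to best-hit analysis: a cross-genome
pair's depth is the epoch count separating both genes from their most
recent common copy, so paralog pairs (diverging at a shared WGD) are
always deeper than ortholog pairs (diverging at the split) of the same
ancestral gene.

`emit_hit_table` models similarity directly in bit-score space — no
sequences are evolved — as base − decay·depth + Gaussian noise, dropping
pairs below a significance floor, with the e-value a fixed strictly
decreasing transform of the bit score (1e3·2^−bits, the standard
Karlin–Altschul shape with an arbitrary search-space constant). The
history seed and the noise seed are independent so noise can be varied
on a fixed history. Defaults (base 200, decay 10 per epoch, floor 50)
put several epochs of divergence between score levels, comfortably
inside the floor; they are arbitrary but only their ordering matters.

What the simulator deliberately does not capture: sequence-level
evolution (rate variation, convergence, alignment artifacts), gene
conversion between duplicates, partial-gene events, and real BLAST
statistics. Passing tests therefore show that the *pipeline logic* is
correct under a known generative model, not that real-genome noise
behaves like Gaussian score noise.

## Benchmark and problem sizes

`simulate_chromosome_benchmark` wires the simulator to the statistics at
the study's shape: one ancestral chromosome, WGD1, lineage A keeping the
two resulting chromosomes (each descending from one WGD1 copy), lineage
B undergoing a second WGD, losses at retention 0.6 in both lineages.
The event vocabulary includes fusions but not fissions, so the
five-chromosome layout of the human groups is emulated with two sister
groups of two B chromosomes each, grouped by WGD1-copy ancestry — the
pooling logic being tested is identical. The parameter-recovery test
runs 100 replicates at 500 ancestral genes and requires the pooled
top-column chi-square to reject at α = 0.05 in at least 90 of them.

Test problem sizes (30–1000 ancestral genes for invariant sweeps, 10⁴
for the solo-enrichment contrast, 10⁵ draws for permutation checks) were
chosen from the analytic standard errors so that modeled effects sit
several standard errors from their thresholds; they are the package's
study conditions, fixed in the tests.

## Known limitations

- Orthology truth labels cover cross-genome pairs; within-genome paralog
  tracking is limited to what `closest_paralog_counts` computes from
  hits.
- The chi-square is asymptotic; for sparse tables the permutation
  routine is the honest reference, and the discreteness gap documented
  above is a property of the test, not removable by implementation.
- Chromosome ids are opaque strings matched exactly ("8" and "chr8" are
  different chromosomes); alias handling belongs to input preparation.
- The conserved-block detector is anchor-neighborhood-scoped by design;
  it is not a genome-wide synteny chainer.
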
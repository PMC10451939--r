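# paralogon

Chromosome-scale homology inference for whole-genome-duplication (WGD)
ohnolog detection.

## The problem

Deciding whether a family of gene duplicates are **ohnologs** — copies
retained from a whole-genome duplication rather than from small-scale
duplications — is hard when the sequences are short and fast-evolving, as
for the vertebrate synuclein genes (*SNCA*, *SNCB*, *SNCG* in humans;
*ASYN1–ASYN4* in lampreys). Phylogenetic trees alone can be ambiguous.
`paralogon` implements a complementary, chromosome-scale line of evidence:
if two genes are ohnologs from the vertebrate WGDs, the chromosomes that
carry them should themselves be homologous, and that homology is testable
from whole-chromosome protein-similarity searches.

The package provides, for users comparing an agnathan (jawless vertebrate)
genome against a gnathostome one — or any pair of genomes related through
WGDs:

- **Best-hit classification** (`summarize_query`, `build_count_matrix`):
  for each query gene, the three highest-scoring distinct subject genes
  from a BLASTP-style search; per (query chromosome × subject chromosome),
  the counts of queries whose best hit ("top"), any of three best hits
  ("total"), or single significant hit ("solo") lands there.
- **Chromosome-association tests** (`pool_counts`,
  `pearson_chi_square`): pool subject chromosomes into the two groups
  descending from the two WGD1 copies of an ancestral chromosome
  (for the synuclein region: human {4,5} vs {2,8,10}) and test a 2×2
  contingency table with the Pearson chi-square,
  X² = N(ad−bc)² / ((a+b)(c+d)(a+c)(b+d)), df = 1, no continuity
  correction.
- **Local synteny** (`extract_neighborhood`, `map_neighborhood`,
  `congruence_scores`, `find_conserved_blocks`): ±5-gene windows around
  anchor genes, order/orientation congruence (inversion-aware Kendall
  rank correlation), and maximal conserved gene blocks shared across
  neighborhoods.
- **The solo-gene loss-scenario model** (`ortholog_probability`,
  `simulate_solo_bias`): exact enumeration of the gene-loss histories
  that leave a single cross-genome match, showing that "solo" matches are
  biased toward true orthologs (probability 1 under a pre-split loss,
  1/2 otherwise) and therefore usable as chromosome-correspondence
  markers.
- **A ground-truthed genome simulator** (`ancestral_genome`,
  `event_schedule`, `simulate_history`, `emit_hit_table`): WGDs
  (including triplication), chromosome fusions, stochastic gene loss and
  transposition, with exact ortholog/paralog labels and BLAST outfmt-6
  hit tables, so the entire pipeline is testable without any downloads.

Standard formats are supported throughout: BLAST tabular (outfmt 6) hit
tables, TSV/BED6 gene locations, two-column protein-to-gene (isoform) and
ohnolog-pair lists.

## Worked example

The package ships the per-chromosome counts comparing *Petromyzon
marinus* chromosomes 8, 41 and 22 (carriers of the lamprey synuclein
genes) with the human proteome:

```r
library(paralogon)
cm <- lamprey_human_counts()
cm
#> count_matrix: 3 query chromosome(s), 23 subject chromosome(s)
#>  query_chromosome n_queries_with_hits n_solo_queries
#>                 8                 180             23
#>                41                 157             32
#>                22                 204             52

tab <- pool_counts(cm, c("8", "41"), column = "top")
tab
#>         query
#> group     8 41
#>   4+5    73 81
#>   2+8+10 85 48
pearson_chi_square(tab)
#> Pearson chi-square = 7.86, df = 1, p = 0.005
```

Lamprey chromosome 41's genes are significantly skewed toward human
chromosomes 4 and 5 relative to chromosome 8's genes (p = 0.005): the two
lamprey chromosomes correspond to *different* WGD1-derived copies of the
ancestral chromosome, which is the chromosome-scale signature expected if
the lamprey α/β-synuclein and γ-synuclein genes are ohnologs. Of
chromosome 41's best hits, 82% land on the five WGD-related human
chromosomes:

```r
round(fraction_on_group(cm, "41", c("2", "4", "5", "8", "10")))
#> [1] 82
```

And the loss-scenario model quantifies why single-match ("solo") genes
carry extra information:

```r
ortholog_probability("b")
#> $probability
#> [1] 0.5
#> $n_losses
#> [1] 2
```

A scenario with both losses in the gnathostome lineage leaves the single
human survivor an ortholog of the lamprey gene only half the time,
whereas a loss before the agnathan/gnathostome split forces orthology
(`ortholog_probability("a")$probability` is 1) — so an excess of solo
genes concentrated on one chromosome group is strong evidence of true
chromosome correspondence.

`run_pipeline(run_config(...))` orchestrates the full analysis (from hit
tables, a saved count matrix, or a built-in benchmark simulation) and
writes TSV reports whose headers record the configuration hash, seed and
significance threshold.

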
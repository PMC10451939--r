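Package: paralogon
Title: Chromosome-Scale Homology Inference for Whole-Genome-Duplication
    Ohnolog Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether gene duplicates are ohnologs (retained
    from whole-genome duplication) using chromosome-scale homology evidence.
    Implements best-hit classification of protein similarity searches into
    per-chromosome "top", "total" and "solo" counts, pooled 2x2 contingency
    chi-square tests of chromosome association against WGD-derived chromosome
    groups, anchor-centered local synteny comparison with conserved-block
    detection, an exact enumeration model of gene-loss scenarios explaining
    single-copy ("solo") matches, and a ground-truthed simulator of genome
    evolution through whole-genome duplications, fusions, gene losses and
    transpositions that emits BLAST-like tabular hit tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
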
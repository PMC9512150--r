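Package: rareburden
Title: Rare-Allele Burden on Gene Expression in Selfing Plant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-based analysis of the burden of rare genetic variants
    (SNPs, indels and structural variants) on gene expression in a
    population, as used in studies of stabilizing selection on expression
    in selfing crops such as rice. Implements population variant
    filtering and structural-variant merging, robust-expression gene
    filtering, per-gene expression ranking, rare-variant assignment to
    genic and upstream distance windows, per-rank burden profiles with
    quadratic fits and rank-group tests, the extreme-to-middle ratio
    statistic phi = E_r/M_r with permutation and Fisher contingency
    comparisons, and stratified analyses by variant class, linkage
    window, recombination rate, fitness-consequence score, expression
    level and network connectivity. Includes a synthetic-population
    generator with planted cis-regulatory effects so every stage of the
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
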
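Package: famvar
Title: Family-Based Rare-Variant Co-Segregation and Burden Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for family-based rare-variant analysis in multiplex
    pedigrees, motivated by autosomal-dominant candidate-gene studies of
    eosinophilic esophagitis. Implements genotype-level quality-control
    filters (read depth, genotype quality, alternate-allele-ratio bands),
    variant rarity and in-silico deleteriousness consensus filtering,
    Mendelian-consistency and pedigree co-segregation checks, a
    genotype-phenotype concordance statistic over first-degree-relative
    scoring units with an exact binomial chance null, gene-level and
    carrier-level burden tests against external control counts (Fisher's
    exact test, odds ratios, chi-square), gene-set "second hit" enrichment,
    and phenotype-quantification formulas (histology score aggregation,
    delta-CT expression, and bench-assay readouts). A synthetic-data module
    simulates multiplex pedigrees segregating a rare heterozygous dominant
    variant with tunable penetrance and phenocopy rate, plus read-level
    genotype-call noise and annotation tables, so the full pipeline is
    testable without access-restricted exomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
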
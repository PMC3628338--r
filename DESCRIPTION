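Package: famdiv
Title: Divergence and Population Differentiation of Duplicated Gene Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for studying the divergence of tandemly
    duplicated gene families such as the human CEACAM/PSG cluster on
    chromosome 19. Provides marker-anchored syntenic-block detection and
    classification of family duplicates into tandem duplications versus
    whole-genome-duplication-derived co-orthologs; per-SNP unbiased
    (Weir-Cockerham) F_ST estimation with empirical percentile brackets and
    gene-family enrichment contrasts; synonymous/nonsynonymous SNP-density
    summaries; EM-based two-locus r^2 linkage-disequilibrium block detection;
    a copy-number-variation calculus (length and frequency filters, locus
    overlap, per-individual gene copy-number profiles and attainable
    copy-number ranges); seeded synthetic-data generators (Balding-Nichols
    genotype panels, marker-anchored gene landscapes, CNV genotypes); and a
    reproducible file-based pipeline driver with a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
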
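Package: meioscan
Title: Pedigree-Aware Variant Prioritization and Meiotic Phenotype Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable implementation of the computational chain used to
    nominate a recessive causal variant for severe male infertility in a
    consanguineous family and to characterize its meiotic consequences.
    Provides pedigree-aware exome filtering (autosomal-recessive and X-linked
    segregation, population frequency, functional impact), a testis-specificity
    score based on Pearson correlation of cross-tissue expression vectors with
    an exclusive-expression indicator, single-cell RNA-seq stage profiling
    (CPM normalization, marker-based cluster verification, median-normalized
    average expression across spermatogenesis stages), sperm and blastomere
    FISH aneuploidy classification and summary statistics, in-silico RFLP
    assay design (restriction digestion, allele discrimination, mismatch-primer
    site creation, coding-substitution consequence annotation, microsatellite
    flanking-haplotype comparison), cohort summaries (ICSI fertilization rates,
    carrier-screen tallies, fertility-assay comparisons), and a synthetic-data
    generator that emulates every input class so the full pipeline is testable
    offline with a planted causal variant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    mclust,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    optparse
Config/testthat/edition: 3
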
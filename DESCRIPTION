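Package: tmejscan
Title: APOBEC3 Mutational Footprints and Microhomology-Mediated Deletion
    Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting the genomic footprints that theta-mediated
    end joining (TMEJ) leaves behind when it repairs APOBEC3-induced DNA
    double-strand breaks. Classifies single-base substitutions into
    pyrimidine-normalized SBS-96 trinucleotide channels and flags APOBEC3
    TCW-motif substitutions; annotates insertions and deletions with
    repeat-unit and microhomology context in the ID83 channel scheme and
    flags microhomology-mediated deletions (MMDs); detects kataegis-like
    substitution clusters by intermutation distance and categorizes them by
    the two-thirds TCW rule; computes cluster-indel proximity statistics
    within a 0.1 Mb window; provides cohort-level burden correlations,
    HR-deficiency sample filtering, and a multi-caller somatic variant
    consensus filter; and ships a seeded synthetic-cohort generator with
    ground-truth tables so every stage of the analysis is verifiable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
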
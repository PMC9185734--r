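Package: PanelForge
Title: Design and Validation of Multiplexed Amplicon SNP Panels for
    Noninvasive Wildlife Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for designing and validating
    GT-seq-style multiplexed amplicon SNP panels aimed at noninvasive
    wildlife samples (feces, hair). Implements informativeness-driven
    marker selection (cumulative probability of identity P_ID and its
    sibling analogue P_IDsib, dyad simulation with relatedness
    classification, sex-marker screening by allele-frequency
    differential), an allele-ratio amplicon genotyper with panel-health
    diagnostics (on-target accounting, overrepresented primers,
    primer-interaction artifacts), genotype quality control (missingness
    filters, genotyping success, replicate and cross-method
    discordance), and forensic applications (unique-genotype
    mark-recapture, Loiselle pairwise kinship, Bayesian sex assignment).
    A synthetic-data module generates allele-frequency spectra,
    Hardy-Weinberg and pedigreed genotypes, sex-differentiated loci, and
    degraded amplicon read sets so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    igraph,
    vcfR,
    jsonlite,
    yaml,
    withr,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, Sequencing, QualityControl
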
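Package: adarcall
Title: Quantification and Site Calling for Cas13-ADAR RNA Base Editing
    from Targeted Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for programmable A-to-I(G) RNA base editing
    experiments that repair G>A premature stop codons with Cas13b-ADAR
    effectors. Designs tiled guide RNA spacers with an A-C mismatch at the
    target adenosine, normalizes dual-luciferase reporter plates to editing
    efficiencies, quantifies per-adenosine A>G editing rates from targeted
    amplicon FASTQ reads (quality filtering, orientation-aware alignment,
    allele counting), calls off-target bystander editing sites against
    pooled controls with two-sided Fisher exact tests and Benjamini-Hochberg
    adjustment, and estimates per-read bystander-free editing precision.
    Includes a synthetic amplicon read and reporter-plate simulator with an
    explicit generative editing model so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
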
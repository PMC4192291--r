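Package: ldpanel
Title: Design and Evaluation of Low-Density SNP Panels for Genotype Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate genotype imputation from low-density to
    high-density SNP chips in pedigreed livestock populations. Implements
    quality control of SNP genotypes (Hardy-Weinberg, minor allele frequency,
    call rate with per-call quality masking), windowed design of customized
    low-density chips and add-on chips (even spacing, MAF, linkage
    disequilibrium r2 and combined criteria), masking-based validation
    scenarios, baseline imputers, per-individual and per-SNP imputation
    accuracy metrics (concordance percentage and dosage correlation), the
    VanRaden genomic relationship matrix with Maxr/Mean10 relatedness
    summaries, regression of accuracy on relatedness, genome-window accuracy
    scans, and a pedigree gene-dropping simulator that generates blockwise-LD
    genotype data so the whole pipeline is testable without external data.
    Reads and writes PLINK PED/MAP and BED/BIM/FAM, VCF, chip manifests and
    pedigrees.
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
    withr,
    jsonlite
Config/testthat/edition: 3
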
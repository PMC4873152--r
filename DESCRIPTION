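Package: aneuscreen
Title: Cross-Species Aneuploidy Dosage Screening for Candidate Disease Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable implementation of a cross-species aneuploidy genetic
    screen for dosage-sensitive disease genes. Mouse trisomy models are
    classified by phenotype from per-animal measurements or printed summary
    statistics (mean, SEM, n), their dosage-altered genomic segments are
    combined by interval set algebra into a candidate region (triplicated in
    all affected models and in no unaffected model), candidates are projected
    to human orthologs, and the candidate list is narrowed by differential
    expression in case/control tissue and corroborated by covariate-adjusted
    methylation-expression association on Infinium-style beta values. Includes
    a seeded synthetic-study generator with planted ground truth for
    end-to-end validation, readers/writers for BED/TSV/GFF3 inputs, and a
    ranked evidence report.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    pracma,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
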
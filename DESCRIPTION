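Package: edgesnp
Title: Elastic Data-Driven Genotype Encoding and SNP-SNP Interaction Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a per-SNP heterozygous encoding weight (alpha) from a
    codominant dummy regression and uses it, alongside the additive, dominant,
    recessive and codominant encodings, to test SNP-SNP interactions with a
    full-versus-reduced likelihood ratio test. Includes a biallelic
    penetrance-model simulator (Hardy-Weinberg genotypes, case-control
    retrospective sampling, main-effect and pure-interaction models), a
    power and type-I-error study runner, readers and writers for genotype
    matrices (TSV, VCF, PLINK bed/bim/fam), candidate-pair selection for
    interaction scans, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
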
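Package: zdose
Title: Chromosome-Dosage qPCR Sex Genotyping for ZZ/Z0 Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for sex genotyping by relative quantification (delta-delta
    Cq) real-time PCR in species with ZZ/Z0 sex chromosomes, such as many
    cephalopods. Converts raw replicate quantification-cycle (Cq) tables into
    per-animal delta-Cq and delta-delta-Cq dosage estimates with outlier
    screening, two-cluster normalization and male/female/repeat calls;
    validates assays with exact one-sided binomial tests, Student's t tests
    and dilution-series efficiency estimation; screens candidate qPCR primer
    pairs under thermodynamic and compositional constraints with in-silico
    PCR specificity checks; and simulates realistic qPCR plates from known
    genotypes so the whole pipeline can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    BiocGenerics,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
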
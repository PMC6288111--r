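Package: lipidbridge
Title: Cross-Platform Harmonization and Differential Analysis of Lipidomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for comparing targeted (internal-standard based multiple
    reaction monitoring) and untargeted (liquid chromatography-mass
    spectrometry) lipidomics platforms. Provides lipid shorthand nomenclature
    parsing and annotation-level conversion (triacylglycerol fatty-acid level,
    sphingomyelin backbone subtraction), cross-platform coverage matching,
    internal-standard quantification of MRM scan data, feature-table
    normalization and filtering, precision and accuracy quality control from
    replicate injections and dilution series, inter-platform correlation, and
    two-group differential abundance analysis with false discovery rate
    control, together with a fully seeded synthetic paired-platform study
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
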
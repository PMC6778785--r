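Package: poolselect
Title: Pooled-Strain Selection-and-Sequencing Phenotyping of Starvation
    Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers per-strain frequencies in pooled cultures of isogenic
    nematode strains from read counts at strain-unique single-nucleotide
    variants, converts frequency trajectories over a starvation time course
    into regression-slope trait values, quantifies the theoretical
    measurement error of the pooled-frequency estimator by Poisson
    read-sampling simulation, fits logistic survival curves to manual
    starvation-survival assays for validation, and provides a clearly
    labelled naive single-marker association scan. Includes a synthetic-data
    generator emulating the pooled-selection experiment so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
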
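Package: coopfit
Title: Equilibrium Operator-Occupancy Modeling and Hill Analysis of
    Repressor-Promoter Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of transcription-factor autoregulation at
    promoters carrying multiple operator sites. Provides an equilibrium
    statistical-thermodynamic model of a repressor binding 1-8 operator
    sites (configuration and band-count distributions, fractional
    saturation, apparent Hill coefficient), the classical EMSA Hill-plot
    pipeline (band-intensity tables to fractional saturation, the theta
    transform, Hill coefficient and dissociation-constant extraction, and
    cooperativity classification), per-site affinity fitting from titration
    data, detection of inverted-repeat operator pairs in promoter DNA with
    consensus matrices, Miller-unit analysis of kinetic beta-galactosidase
    reporter reads, and seeded synthetic-data generators that emulate EMSA
    titrations, polyC mutant probes, planted-repeat promoter sequences and
    kinetic plate reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
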
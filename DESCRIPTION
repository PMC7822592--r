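Package: ocnforms
Title: Intact-Mass Proteoform Assignment and Plasma Half-Life Kinetics for
    Osteocalcin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for top-down (intact-protein) mass-spectrometry analysis of
    osteocalcin (OCN) proteoforms and for estimating OCN plasma half-life.
    Computes exact monoisotopic masses and isotope envelopes for modified
    proteins, assigns deconvoluted neutral masses to ranked combinations of
    post-translational modifications (gamma-carboxyglutamate, mucin-type
    core-1 O-glycan units, oxidation) within a ppm tolerance, aggregates
    proteoform-class relative abundances, and fits first-order decay models
    to ex vivo and in vivo concentration time courses with bootstrap
    confidence intervals. A seeded synthetic-data generator produces
    proteoform mixtures, isotope-resolved spectra and decay curves with
    realistic noise so every stage of the pipeline can be exercised without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    seqinr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
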
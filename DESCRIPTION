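Package: hdxpop
Title: Bimodal Deconvolution and Population Kinetics for HDX-MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Peptide-level analysis of amide hydrogen/deuterium exchange mass
    spectrometry (HDX-MS) data: theoretical isotope-envelope construction from
    peptide sequence, centroid-based deuterium-uptake tables with replicate
    statistics, state-vs-state differential exchange with a magnitude
    significance threshold, single- versus double-binomial deconvolution of
    spectral envelopes with F-test model selection and population-fraction
    reporting, exponential release-kinetics half-life estimation, and
    Michaelis-Menten analysis of linked phosphodiesterase assays. Includes a
    seeded synthetic-data generator emulating triplicate exchange experiments
    and enzyme assays for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    graphics,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
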
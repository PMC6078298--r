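Package: hdxgold
Title: Gas-Phase HDX-MS Envelope Deconvolution for Co-Populated Oligomer
    Conformers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of gas-phase hydrogen/deuterium exchange mass
    spectrometry (HDX-MS) of co-populated peptide oligomers, built around
    amyloid-beta 1-40. Provides exchangeable-proton accounting for
    side-chain and terminus hydrogens, exact isotopic envelope computation,
    an equal-probability (binomial) single-state deuteration model, and
    deconvolution of widened or split isotopic envelopes into a minimal
    family of differently exchanging conformational states using a boosted
    Gold multiplicative solver. Includes isobaric oligomer/charge-state
    assignment, ion-mobility drift-time conformer split detection, a
    ground-truthed synthetic spectrum generator, and an end-to-end
    pipeline with replicate comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    mzR,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
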
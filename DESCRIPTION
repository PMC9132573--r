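Package: eif2bkin
Title: Two-Step Substrate-Engagement Kinetics and Conformational Analysis of eIF2B
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of how the decameric guanine nucleotide
    exchange factor eIF2B engages its substrate eIF2. Implements a two-step,
    multi-interface engagement kinetic model for surface plasmon resonance
    (SPR) data: sensorgram simulation from microscopic rate constants,
    one-phase association and biphasic dissociation fitting, derivation of the
    second-step retraction rate, variable-association-time analysis, bound-state
    occupancy ratios and free-energy profiles. Also provides fluorescent-GDP
    nucleotide-exchange enzymology (exponential half-life fits, initial
    velocities, calibration, Michaelis-Menten parameters with an explicit
    catalytic-site convention for kcat, replicate-level t-tests), sigmoidal
    FRET assembly-titration EC50 fitting, structural conformation metrics
    (Kabsch superposition, tetramer-half hinge angles, residue-pair pocket
    distances) from PDB/mmCIF models, a seeded synthetic-data generator for
    every assay, and a pipeline driver that assembles a reproduction report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
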
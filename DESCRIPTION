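Package: theoceptor
Title: Binding-Affinity Prediction from Quantum Complexation Energies and Lipophilicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates and applies a three-coefficient linear scoring model that
    predicts protein-ligand binding affinity (pIC50/pKi/pKd) from a quantum
    mechanically computed complexation energy and the ligand's calculated log P.
    Includes leave-one-out coefficient-stability analysis, a random-covariate
    baseline to benchmark the lipophilicity term, Boltzmann aggregation of
    conformer ensembles into complexation energies, ranking of competing
    structural hypotheses (conformers, tautomers, heteroatom placements,
    protonation states) from bound- and free-state energies, a synthetic
    calibration-data generator, and a command-line interface. Quantum energies
    are inputs harvested from tables or plain-text output files; no electronic
    structure computation is performed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
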
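Package: ecoevotum
Title: Eco-Evolutionary Dynamics of Tumour Cells Under Hypoxia and Acidity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic simulator for a phenotype-structured partial
    integro-differential model of cancer-cell adaptation in a vascularised
    tissue strip. Tumour cells carry two continuous traits (resistance to
    acidity and to hypoxia) and interact with reaction-diffusion fields of
    oxygen, glucose and lactate through a quadratic selection-mutation
    fitness landscape with Michaelis-Menten metabolism and crowding death.
    Provides the calibrated parameter set, finite-difference operators with
    operator splitting and implicit-explicit reactions, quasi-stationary and
    co-integrated substrate solvers, trait-moment and habitat diagnostics,
    experiment presets (baseline invasion, selection-gradient sweeps) and a
    small command-line driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
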
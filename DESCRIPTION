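Package: pseudoham
Title: Pseudo-Hamiltonian Neural Networks for Molecular Orbital and
    Quasiparticle Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts many molecular orbital and quasiparticle energies
    simultaneously as the eigenvalues of a learned symmetric
    pseudo-Hamiltonian matrix produced by a continuous-filter
    message-passing neural network, with backpropagation through the
    eigendecomposition. Includes conventional single-state and
    multi-state output heads for comparison, a delta-learning corrector
    between levels of theory, Pseudo-Voigt photoemission spectrum
    generation, and a tight-binding synthetic data generator so the
    whole pipeline is testable end to end without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
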
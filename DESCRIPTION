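Package: mcdspin
Title: Spin-Hamiltonian Simulation and Fitting of Variable-Temperature
    Variable-Field Magnetic Circular Dichroism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the spin-Hamiltonian analysis of magnetic circular
    dichroism (MCD) C-term data of paramagnetic transition-metal complexes.
    Builds and exactly diagonalizes zero-field-splitting + Zeeman Hamiltonians
    for single spin centres and Heisenberg exchange-coupled dimers, simulates
    powder orientation-averaged variable-temperature variable-field (VTVH)
    saturation-magnetization curves, fits effective transition dipole moment
    products and spin-Hamiltonian parameters to multi-wavelength VTVH data
    with error-surface scans, performs simultaneous Gaussian deconvolution of
    paired absorption/MCD spectra with C0/D0-based band classification, and
    predicts MCD C-term and pseudo-A-term signs of one-electron d-d
    transitions from orbital angular-momentum matrix elements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    pracma,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
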
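Package: synapsim
Title: Lattice Monte Carlo Simulation of T-Cell Membrane Adhesion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Three-dimensional lattice Monte Carlo model of the adhesion of a
    T-cell membrane to an apposing membrane. Two membranes are described by a
    fluctuating separation field on a periodic square lattice of 15 nm
    patches with a discretized Helfrich bending energy, together with
    diffusing TCR, peptide-MHC, LFA-1 and ICAM-1 proteins that bind within
    length-specific separation windows (15 +/- 0.5 nm for TCR/peptide-MHC,
    40 +/- 0.5 nm for LFA-1/ICAM-1). Metropolis dynamics with separation,
    protein and complex-pair moves reproduce curvature-mediated segregation
    of the short and long complexes and the cooperative stabilization of
    close-contact zones. Includes observables (close-contact event
    probability, lifetime and area, complex concentrations, bond dwell-time
    statistics) and analytic companions (segregation threshold, the
    two-dimensional binding constant), scenario presets, snapshot and
    configuration file handling, and a command-line driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
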
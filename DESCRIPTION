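Package: chmpes
Title: Potential Energy Surface Fitting with Permutationally Invariant
    Polynomials and a Core-Hamiltonian Charge-Density Model
Version: 0.1.0
Authors@R: person("chmpes", "maintainers", email = "chmpes@example.org",
    role = c("aut", "cre"))
Description: Fits molecular potential energy surfaces (PES) to reference
    electronic energies using permutationally invariant polynomials (PIPs)
    in Morse-transformed internuclear distances.  Besides the conventional
    PIP(M) linear expansion, the package implements a core-Hamiltonian
    model, CHM(M), in which the energy is the nuclear repulsion plus the
    trace of a PIP-parameterized s-type charge density matrix against
    analytic one-electron integrals plus a PIP correction energy, fitted
    by weighted linear least squares with an optional total-charge
    constraint.  Includes covariant (atom- and pair-anchored) PIP bases,
    augmented bases, analytic s-Gaussian integrals, a velocity-Verlet
    configuration sampler with harmonic restraints, energy-stratified
    pruning, extended-XYZ dataset I/O, a command line interface, and a
    built-in restricted Hartree-Fock / full-CI engine for two-electron
    systems used for desk-scale ab initio checks.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
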
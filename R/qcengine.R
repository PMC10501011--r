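## Built-in restricted Hartree-Fock + full-CI engine over contracted
## Gaussian bases (McMurchie-Davidson integrals in src/).  Full CI is
## offered for systems with at most two electrons, where it coincides with
## CCSD; this is exactly what the desk-scale ab initio checks (HeH+, H3+,
## He) need.  Not a general-purpose quantum chemistry code.

## contracted basis data; exponents bohr^-2, unnormalized coefficients
.basis_library <- list(
  "cc-pvdz" = list(
    H = list(
      list(l = 0L, exps = c(13.0100, 1.9620, 0.4446, 0.1220),
           coefs = c(0.0196850, 0.1379770, 0.4781480, 0.5012400)),
      list(l = 0L, exps = 0.1220, coefs = 1.0),
      list(l = 1L, exps = 0.7270, coefs = 1.0)),
    He = list(
      list(l = 0L, exps = c(38.3600, 5.7700, 1.2400, 0.2976),
           coefs = c(0.0238090, 0.1548910, 0.4699870, 0.5130270)),
      list(l = 0L, exps = 0.2976, coefs = 1.0),
      list(l = 1L, exps = 1.2750, coefs = 1.0))),
  "sto-3g" = list(
    H = list(list(l = 0L, exps = c(3.42525091, 0.62391373, 0.16885540),
                  coefs = c(0.15432897, 0.53532814, 0.44463454))),
    He = list(list(l = 0L, exps = c(6.36242139, 1.15892300, 0.31364979),
                   coefs = c(0.15432897, 0.53532814, 0.44463454)))))

#' Available basis sets of the built-in engine
#' @return character vector of basis labels
#' @export
qc_basis_sets <- function() names(.basis_library)

.build_shells <- function(config, basis) {
  lib <- .basis_library[[tolower(basis)]]
  if (is.null(lib)) stop("unsupported basis set: ", basis)
  shells <- list()
  for (a in seq_along(config$elements)) {
    el <- config$elements[a]
    if (is.null(lib[[el]]))
      stop("basis ", basis, " has no data for element ", el)
    for (sh in lib[[el]])
      shells[[length(shells) + 1]] <- c(list(atom = a), sh)
  }
  shells
}

## one-/two-electron integrals for a configuration (coords Angstrom)
.qc_integrals <- function(config, basis, want_eri = TRUE) {
  coords <- ang2bohr(config$coords)
  Z <- as.integer(atomic_number(config$elements))
  ints <- cpp_md_integrals(coords, Z, .build_shells(config, basis),
                           want_eri)
  if (length(Z) >= 2) {
    d <- compute_distances(config)
    ps <- attr(d, "pairs")
    ints$Enuc <- sum(Z[ps[, 1]] * Z[ps[, 2]] / ang2bohr(d))
  } else ints$Enuc <- 0

  ints$Hcore <- ints$T + ints$V
  ints
}

## restricted Hartree-Fock; returns energy, MO coefficients, orbital
## energies
.rhf <- function(ints, nelec, maxit = 200, conv = 1e-10) {
  if (nelec %% 2 != 0) stop("RHF needs an even electron count")
  nocc <- nelec / 2
  K <- ints$K
  S <- ints$S; H <- ints$Hcore; ERI <- ints$ERI
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-10) stop("overlap matrix is near-singular")
  X <- es$vectors %*% diag(1 / sqrt(es$values), K) %*% t(es$vectors)
  exchange <- function(P) {
    A <- array(ERI, c(K, K, K, K))     # A[nu, mu, si, la] = (mu nu|la si)
    Kx <- matrix(0, K, K)
    for (mu in seq_len(K)) for (nu in seq_len(K))
      Kx[mu, nu] <- sum(A[, mu, , nu] * P)   # (mu la | nu si) P_{la si}
    Kx
  }
  P <- matrix(0, K, K)
  Eold <- Inf
  mix <- 0
  C <- NULL
  eps <- NULL
  for (it in seq_len(maxit)) {
    if (it == 1) {
      F <- H
    } else {
      J <- matrix(ERI %*% as.vector(P), K, K)
      F <- H + J - 0.5 * exchange(P)
    }
    Fp <- t(X) %*% F %*% X
    ef <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(ef$values)   # ascending orbital energies
    C <- X %*% ef$vectors[, ord, drop = FALSE]
    eps <- ef$values[ord]
    Pnew <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
    P <- if (mix > 0) mix * P + (1 - mix) * Pnew else Pnew
    J <- matrix(ERI %*% as.vector(P), K, K)
    F <- H + J - 0.5 * exchange(P)
    E <- 0.5 * sum(P * (H + F)) + ints$Enuc
    if (abs(E - Eold) < conv && it > 2) {
      return(list(energy = E, C = C, eps = eps, P = P, F = F))
    }
    if (it == 60 && mix == 0) mix <- 0.5  # damp stubborn cases
    Eold <- E
  }
  warning("SCF not fully converged (dE = ", format(abs(E - Eold)), ")")
  list(energy = E, C = C, eps = eps, P = P, F = F)
}

## full CI for exactly two electrons (one alpha, one beta) in the full MO
## space; exact (= CCSD) for two-electron systems
.fci2 <- function(ints, scf) {
  K <- ints$K
  C <- scf$C
  h <- t(C) %*% ints$Hcore %*% C
  W <- kronecker(C, C)
  G <- t(W) %*% ints$ERI %*% W      # G[(p-1)K+q, (r-1)K+s] = (pq|rs)
  G4 <- array(G, c(K, K, K, K))     # G4[q, p, s, r] = (pq|rs)
  M <- matrix(aperm(G4, c(4, 2, 3, 1)), K * K, K * K)  # (ik|jl) at (ij),(kl)
  I <- diag(K)
  Hf <- kronecker(h, I) + kronecker(I, h) + M
  ev <- eigen((Hf + t(Hf)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) + ints$Enuc
}

#' Single-point energy with the built-in engine
#'
#' Restricted Hartree-Fock for any closed-shell system the basis library
#' covers; `"FCI"` / `"CCSD"` (identical here) only for systems with one
#' or two electrons.
#'
#' @param config a [chm_config()]
#' @param method `"HF"`, `"CCSD"`, or `"FCI"`
#' @param basis a label from [qc_basis_sets()]
#' @param charge total charge
#' @return energy, hartree
#' @export
qc_energy <- function(config, method = "FCI", basis = "cc-pVDZ",
                      charge = 0) {
  nelec <- sum(atomic_number(config$elements)) - charge
  if (nelec < 1) stop("no electrons")
  ints <- .qc_integrals(config, basis)
  if (nelec == 1) {
    ## one-electron exact: lowest eigenvalue of the core Hamiltonian
    es <- eigen(ints$S, symmetric = TRUE)
    X <- es$vectors %*% diag(1 / sqrt(es$values), ints$K) %*% t(es$vectors)
    e1 <- min(eigen(t(X) %*% ints$Hcore %*% X, symmetric = TRUE,
                    only.values = TRUE)$values)
    return(e1 + ints$Enuc)
  }
  scf <- .rhf(ints, nelec)
  if (toupper(method) == "HF") return(scf$energy)
  if (nelec == 2) return(.fci2(ints, scf))
  stop("capability error: correlated methods are implemented only for ",
       "systems with at most two electrons (got ", nelec, "); plug in an ",
       "external engine via register_qc_engine()")
}

## register the built-in engine at load time
.fci2e_engine <- function(config, method, basis) {
  charge <- attr(config, "charge")
  if (is.null(charge)) charge <- 0
  qc_energy(config, method, basis, charge)
}

.onLoad <- function(libname, pkgname) {
  register_qc_engine("fci2e", .fci2e_engine)
}

#' Optimize a bond length with the built-in engine
#'
#' One-dimensional golden-section minimization of a diatomic (or any
#' single-parameter radial) energy curve.
#'
#' @param energy_fn function distance -> energy (hartree)
#' @param lower,upper bracket, Angstrom
#' @param tol convergence tolerance on the distance, Angstrom
#' @return list with `r` (minimizer) and `energy`
#' @export
optimize_bond <- function(energy_fn, lower, upper, tol = 1e-5) {
  opt <- stats::optimize(energy_fn, c(lower, upper), tol = tol)
  list(r = opt$minimum, energy = opt$objective)
}
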
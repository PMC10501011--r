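## Validation of the built-in RHF/full-CI engine.  For one-electron cases
## the engine must agree with the package's own closed-form s-integrals
## (dual route); two-electron results are checked for variational sanity,
## invariance, and against well-established reference energies.

test_that("one-electron route agrees with the analytic s-integral module", {
  ## H atom in a fake single-s basis == generalized eigenproblem of the
  ## closed-form matrices
  cfg <- chm_config(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.0)))
  t2 <- chm_typing(list(H = 1:2), c(H = 0.5), 1L, c(H = 1.1))
  cm <- core_matrices(cfg, t2)
  ev <- eigen(solve(cm$S, cm$Hcore), only.values = TRUE)$values
  e_ref <- min(Re(ev)) + cm$Enuc
  ## same one-electron problem through the C++ engine with matching shells
  shells <- list(list(atom = 1L, l = 0L, exps = 1.1, coefs = 1),
                 list(atom = 2L, l = 0L, exps = 1.1, coefs = 1))
  ints <- chmpes:::cpp_md_integrals(ang2bohr(cfg$coords), c(1L, 1L),
                                    shells, FALSE)
  S <- ints$S; H <- ints$T + ints$V
  e_cpp <- min(Re(eigen(solve(S, H), only.values = TRUE)$values)) + cm$Enuc
  expect_equal(e_cpp, e_ref, tolerance = 1e-10)
})

test_that("ERI matrix has the right symmetries and (ss|ss) closed form", {
  cfg <- chm_config(c("He", "H"), rbind(c(0, 0, 0), c(0, 0, 0.9)))
  ints <- chmpes:::.qc_integrals(cfg, "sto-3g")
  K <- ints$K
  ERI <- ints$ERI
  expect_equal(ERI, t(ERI), tolerance = 1e-12)       # (ab|cd) = (cd|ab)
  A <- array(ERI, c(K, K, K, K))
  expect_equal(A[1, 2, 1, 2], A[2, 1, 1, 2], tolerance = 1e-12)
  ## independent closed form for a primitive (ss|ss):
  ## (ab|cd) = 2 pi^{5/2}/(pq sqrt(p+q)) e^{-mu1 AB^2 - mu2 CD^2} F0(...)
  a <- 0.9; b <- 1.4
  shells <- list(list(atom = 1L, l = 0L, exps = a, coefs = 1),
                 list(atom = 2L, l = 0L, exps = b, coefs = 1))
  R <- 1.7  # bohr
  ints2 <- chmpes:::cpp_md_integrals(rbind(c(0, 0, 0), c(0, 0, R)),
                                     c(1L, 1L), shells, TRUE)
  p <- a + a; q <- b + b
  na <- (2 * a / pi)^0.75; nb <- (2 * b / pi)^0.75
  ref <- 2 * pi^2.5 / (p * q * sqrt(p + q)) *
    boys_f0(p * q / (p + q) * R^2) * na^2 * nb^2
  expect_equal(ints2$ERI[1, 4], ref, tolerance = 1e-12)  # (11|22)
})

test_that("RHF is variational and FCI lowers it", {
  heh <- chm_config(c("He", "H"), rbind(c(0, 0, 0), c(0, 0, 0.79)))
  e_hf <- qc_energy(heh, "HF", "cc-pVDZ", charge = 1)
  e_fci <- qc_energy(heh, "FCI", "cc-pVDZ", charge = 1)
  expect_lt(e_fci, e_hf)
  expect_lt(e_hf, -2.85)       # sane total energy scale
  expect_equal(qc_energy(heh, "CCSD", "cc-pVDZ", charge = 1), e_fci)
  expect_error(qc_energy(chm_config(c("C", "H"),
                                    rbind(c(0, 0, 0), c(0, 0, 1))),
                         "FCI", "sto-3g"), "capability|basis")
})

test_that("engine reproduces well-known reference energies", {
  ## restricted HF of He in cc-pVDZ: -2.855160 hartree (standard value)
  he <- chm_config("He", matrix(0, 1, 3))
  expect_equal(qc_energy(he, "HF", "cc-pVDZ"), -2.855160, tolerance = 2e-5)
  ## H2 at re = 0.7414 Angstrom: HF ~ -1.12871, FCI ~ -1.1634 hartree
  h2 <- chm_config(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.7414)))
  expect_equal(qc_energy(h2, "HF", "cc-pVDZ"), -1.12871, tolerance = 1e-4)
  expect_equal(qc_energy(h2, "FCI", "cc-pVDZ"), -1.1634, tolerance = 5e-4)
})

test_that("engine energies are invariant under rotation and translation", {
  cfg <- config_h3p(0.93)
  e0 <- qc_energy(cfg, "FCI", "cc-pVDZ", charge = 1)
  R <- random_rotation(41)
  moved <- chm_config(cfg$elements,
                      sweep(cfg$coords %*% t(R), 2, -c(0.3, 1, -2)))
  expect_equal(qc_energy(moved, "FCI", "cc-pVDZ", charge = 1), e0,
               tolerance = 1e-8)
})
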
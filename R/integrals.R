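## Analytic one-electron integrals for normalized s-type Cartesian
## Gaussians, phi(r) = (2 alpha / pi)^(3/4) exp(-alpha |r - A|^2), one
## function per atom.  Internal unit system: atomic units (bohr, hartree);
## user-facing coordinates in Angstrom are converted at entry.

#' An s-type Gaussian basis function
#'
#' @param center Cartesian position, bohr (length-3)
#' @param exponent alpha, bohr^-2, `> 0`
#' @return an object of class `chm_sgaussian`
#' @export
s_gaussian <- function(center, exponent) {
  if (length(center) != 3 || !all(is.finite(center)))
    stop("center must be a finite length-3 vector (bohr)")
  if (!is.numeric(exponent) || exponent <= 0)
    stop("exponent must be > 0")
  structure(list(center = as.numeric(center), exponent = exponent,
                 norm = (2 * exponent / pi)^0.75),
            class = "chm_sgaussian")
}

#' The Boys function F0
#'
#' `F0(t) = integral_0^1 exp(-t u^2) du = sqrt(pi/t) erf(sqrt(t)) / 2`,
#' with a Taylor branch near `t = 0` for stability.
#'
#' @param t non-negative numeric vector
#' @return F0 values; continuous and decreasing
#' @export
boys_f0 <- function(t) {
  if (any(t < 0)) stop("Boys function domain is t >= 0")
  out <- numeric(length(t))
  small <- t < 1e-6
  ts <- t[small]
  out[small] <- 1 - ts / 3 + ts^2 / 10 - ts^3 / 42
  tb <- t[!small]
  erf <- 2 * stats::pnorm(sqrt(tb) * sqrt(2)) - 1
  out[!small] <- 0.5 * sqrt(pi / tb) * erf
  out
}

.check_sg <- function(a) {
  if (!inherits(a, "chm_sgaussian")) stop("expected a chm_sgaussian")
}

#' Overlap of two normalized s-Gaussians
#' @param a,b `chm_sgaussian` objects
#' @return overlap in (0, 1]
#' @export
overlap_ss <- function(a, b) {
  .check_sg(a); .check_sg(b)
  al <- a$exponent; be <- b$exponent
  p <- al + be
  mu <- al * be / p
  r2 <- sum((a$center - b$center)^2)
  (4 * al * be / p^2)^0.75 * exp(-mu * r2)
}

#' Kinetic-energy matrix element between normalized s-Gaussians
#' @param a,b `chm_sgaussian` objects
#' @return `<a| -nabla^2/2 |b>` in hartree
#' @export
kinetic_ss <- function(a, b) {
  .check_sg(a); .check_sg(b)
  al <- a$exponent; be <- b$exponent
  p <- al + be
  mu <- al * be / p
  r2 <- sum((a$center - b$center)^2)
  mu * (3 - 2 * mu * r2) * overlap_ss(a, b)
}

#' Nuclear-attraction matrix element between normalized s-Gaussians
#'
#' Sum over nuclei of `-Z (2 pi / p) exp(-mu R_ab^2) F0(p |P - R_c|^2)`
#' with the Gaussian product center `P` and normalization included.
#'
#' @param a,b `chm_sgaussian` objects
#' @param nuclei list of `list(Z = charge, pos = position in bohr)` (or a
#'   matrix with columns Z, x, y, z)
#' @return attraction energy, hartree (`<= 0` for non-negative charges)
#' @export
nuclear_attraction_ss <- function(a, b, nuclei) {
  .check_sg(a); .check_sg(b)
  if (is.matrix(nuclei))
    nuclei <- lapply(seq_len(nrow(nuclei)),
                     function(i) list(Z = nuclei[i, 1], pos = nuclei[i, 2:4]))
  al <- a$exponent; be <- b$exponent
  p <- al + be
  mu <- al * be / p
  r2 <- sum((a$center - b$center)^2)
  P <- (al * a$center + be * b$center) / p
  pre <- (4 * al * be / pi^2)^0.75 * (2 * pi / p) * exp(-mu * r2)
  v <- 0
  for (nuc in nuclei) {
    if (nuc$Z < 0) stop("nuclear charges must be >= 0")
    v <- v - nuc$Z * pre * boys_f0(p * sum((P - nuc$pos)^2))
  }
  v
}

#' Core matrices of a configuration under an atom typing
#'
#' One s-Gaussian per atom with its class exponent.  Returns the overlap
#' matrix `S`, the core Hamiltonian `Hcore` (kinetic + nuclear attraction,
#' hartree) and the nuclear repulsion `Enuc = sum_{a<b} Z_a Z_b / d_ab`
#' (hartree).  Coordinates of the configuration are in Angstrom and are
#' converted internally.
#'
#' @param config a [chm_config()]
#' @param typing a [chm_typing()] supplying exponents per class
#' @return an object of class `chm_corematrices`: list(S, Hcore, Enuc)
#' @export
core_matrices <- function(config, typing) {
  n <- n_atoms(config)
  cls <- atom_class_of(typing)
  alpha <- typing$exponents[cls]
  Z <- atomic_number(config$elements)
  X <- ang2bohr(config$coords)
  out <- .core_matrices_batch(array(t(X), dim = c(3, n, 1)), Z, alpha)
  structure(list(S = out$S[, , 1], Hcore = out$H[, , 1], Enuc = out$Enuc[1]),
            class = "chm_corematrices")
}

## batch core matrices: coords array (3 x n x n_configs) in bohr
.core_matrices_batch <- function(X, Z, alpha) {
  n <- dim(X)[2]
  nc <- dim(X)[3]
  S <- array(0, c(n, n, nc))
  H <- array(0, c(n, n, nc))
  Enuc <- numeric(nc)
  ## precompute pairwise squared distances across configs
  r2 <- array(0, c(n, n, nc))
  for (a in seq_len(n)) for (b in seq_len(n)) if (a < b) {
    d2 <- (X[1, a, ] - X[1, b, ])^2 + (X[2, a, ] - X[2, b, ])^2 +
          (X[3, a, ] - X[3, b, ])^2
    if (any(d2 <= 0)) stop("degenerate geometry: coincident atoms")
    r2[a, b, ] <- d2
    r2[b, a, ] <- d2
    Enuc <- Enuc + Z[a] * Z[b] / sqrt(d2)
  }
  for (a in seq_len(n)) for (b in a:n) {
    al <- alpha[a]; be <- alpha[b]
    p <- al + be
    mu <- al * be / p
    Sab <- (4 * al * be / p^2)^0.75 * exp(-mu * r2[a, b, ])
    Tab <- mu * (3 - 2 * mu * r2[a, b, ]) * Sab
    ## Gaussian product center, per config
    Px <- (al * X[1, a, ] + be * X[1, b, ]) / p
    Py <- (al * X[2, a, ] + be * X[2, b, ]) / p
    Pz <- (al * X[3, a, ] + be * X[3, b, ]) / p
    pre <- (4 * al * be / pi^2)^0.75 * (2 * pi / p) * exp(-mu * r2[a, b, ])
    Vab <- numeric(nc)
    for (cc in seq_len(n)) {
      pc2 <- (Px - X[1, cc, ])^2 + (Py - X[2, cc, ])^2 + (Pz - X[3, cc, ])^2
      Vab <- Vab - Z[cc] * pre * boys_f0(p * pc2)
    }
    S[a, b, ] <- Sab; S[b, a, ] <- Sab
    H[a, b, ] <- Tab + Vab; H[b, a, ] <- Tab + Vab
  }
  list(S = S, H = H, Enuc = Enuc)
}
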
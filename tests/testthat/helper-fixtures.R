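## Shared fixtures and independent oracles for the test suite.  All
## fixtures are built in code; no data files.

## ---- typings --------------------------------------------------------------

typing_h3p <- function() {
  chm_typing(list(H = 1:3), c(H = 2 / 3), formal_charge = 1L,
             exponents = c(H = 1))
}

typing_hehp <- function() {
  chm_typing(list(He = 1, H = 2), c(He = 2, H = 0), formal_charge = 1L,
             exponents = c(He = 1.2, H = 0.8))
}

typing_ch5p <- function() {
  chm_typing(list(C = 1, H = 2:6), c(C = 6, H = 4 / 5), formal_charge = 1L,
             exponents = c(C = 1, H = 1))
}

typing_formamide <- function() {
  ## atoms: H1 H2 H' C N O (all three hydrogens one declared class)
  chm_typing(list(H = 1:3, C = 4, N = 5, O = 6),
             c(H = 1, C = 6, N = 7, O = 8), formal_charge = 0L,
             exponents = c(H = 1, C = 1, N = 1, O = 1))
}

## ---- geometries -----------------------------------------------------------

config_h3p <- function(side = 0.9) {
  h <- side / sqrt(3)
  chm_config(c("H", "H", "H"),
             rbind(c(h, 0, 0),
                   c(-h / 2, h * sqrt(3) / 2, 0),
                   c(-h / 2, -h * sqrt(3) / 2, 0)))
}

config_ch5p <- function(jitter = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- rbind(c(0, 0, 0),
                c(1.09, 0, 0),
                c(-0.36, 1.03, 0),
                c(-0.36, -0.51, 0.89),
                c(-0.36, -0.51, -0.89),
                c(0.55, 0.55, 0.80))
  chm_config(c("C", rep("H", 5)), base + jitter * matrix(stats::rnorm(18), 6))
}

random_config <- function(elements, seed = 1, spread = 1.5, min_sep = 0.5) {
  set.seed(seed)
  n <- length(elements)
  repeat {
    x <- matrix(stats::runif(3 * n, -spread, spread), n, 3)
    d <- stats::dist(x)
    if (min(d) > min_sep) return(chm_config(elements, x))
  }
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_out <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_out)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## a random like-atom permutation of a typing
random_class_perm <- function(typing, seed = 1) {
  set.seed(seed)
  perm <- seq_len(typing$n_atoms)
  for (cls in typing$classes)
    if (length(cls) > 1) perm[cls] <- sample(cls)
  perm
}

## ---- oracles --------------------------------------------------------------

## brute-force orbit counting, independent of the canonical-key machinery:
## apply every group element to every monomial, collect orbit sets as
## sorted string keys, count distinct
oracle_orbit_count <- function(typing, M) {
  group <- build_perm_group(typing)
  D <- ncol(group$slot_action)
  monos <- chmpes:::.enum_monomials(D, M)
  seen <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(monos))) {
    imgs <- character(group$order)
    for (g in seq_len(group$order)) {
      img <- integer(D)
      img[group$slot_action[g, ]] <- monos[r, ]
      imgs[g] <- paste(img, collapse = ",")
    }
    assign(paste(sort(imgs), collapse = ";"), TRUE, envir = seen)
  }
  length(ls(seen))
}

## brute-force full-group symmetrized evaluation of one orbit (distinct
## images), for comparison against evaluate_basis
oracle_orbit_value <- function(term, group, dist, scale) {
  y <- exp(-dist / scale)
  imgs <- unique(t(vapply(seq_len(group$order), function(g) {
    img <- integer(length(term))
    img[group$slot_action[g, ]] <- term
    img
  }, integer(length(term)))))
  sum(apply(imgs, 1, function(e) prod(y^e)))
}

## 1-D separable quadrature oracles for the s-Gaussian integrals
oracle_overlap <- function(a, b) {
  f1 <- function(dim) {
    integrand <- function(x)
      exp(-a$exponent * (x - a$center[dim])^2 -
            b$exponent * (x - b$center[dim])^2)
    stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-12)$value
  }
  a$norm * b$norm * f1(1) * f1(2) * f1(3)
}

oracle_kinetic <- function(a, b) {
  ## apply -0.5 laplacian to b analytically, integrate dimension-wise:
  ## lap phi_b = (4 b^2 r^2 - 6 b) phi_b  (s function)
  be <- b$exponent
  g1 <- function(dim, pow) {
    integrand <- function(x)
      (x - b$center[dim])^pow *
        exp(-a$exponent * (x - a$center[dim])^2 - be * (x - b$center[dim])^2)
    stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-12)$value
  }
  s0 <- c(g1(1, 0), g1(2, 0), g1(3, 0))
  s2 <- c(g1(1, 2), g1(2, 2), g1(3, 2))
  r2term <- s2[1] * s0[2] * s0[3] + s0[1] * s2[2] * s0[3] +
    s0[1] * s0[2] * s2[3]
  a$norm * b$norm * (-0.5) * (4 * be^2 * r2term - 6 * be * prod(s0))
}

## radial quadrature oracle for nuclear attraction: the angular integral of
## exp(2 p s d cos(theta)) is elementary (sinh), leaving a 1-D radial
## integral around the nucleus -- independent of the Boys/erf closed form
oracle_nuclear_one <- function(a, b, Z, Rc) {
  p <- a$exponent + b$exponent
  P <- (a$exponent * a$center + b$exponent * b$center) / p
  mu <- a$exponent * b$exponent / p
  r2 <- sum((a$center - b$center)^2)
  pref <- a$norm * b$norm * exp(-mu * r2)
  d <- sqrt(sum((P - Rc)^2))
  if (d < 1e-12) {
    val <- stats::integrate(function(s) 4 * pi * s * exp(-p * s^2),
                            0, Inf, rel.tol = 1e-12)$value
  } else {
    ## angular integral done analytically; the s^2 Jacobian cancels the
    ## 1/s Coulomb factor and the 1/s from the angular result:
    ## (pi / (p d)) [exp(-p(s-d)^2) - exp(-p(s+d)^2)]
    integrand <- function(s)
      pi / (p * d) * (exp(-p * (s - d)^2) - exp(-p * (s + d)^2))
    val <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-12)$value
  }
  -Z * pref * val
}

## finite-difference gradient of a surrogate PES
oracle_fd_gradient <- function(pes, config, h = 1e-6) {
  g <- matrix(0, n_atoms(config), 3)
  for (i in seq_len(n_atoms(config))) for (d in 1:3) {
    cp <- config; cm <- config
    cp$coords[i, d] <- cp$coords[i, d] + h
    cm$coords[i, d] <- cm$coords[i, d] - h
    g[i, d] <- (surrogate_energy_gradient(pes, cp)$energy -
                  surrogate_energy_gradient(pes, cm)$energy) / (2 * h)
  }
  g
}

## small H3+-like surrogate used across chm/datagen tests
surrogate_h3 <- function() {
  chm_surrogate_pes(typing_h3p(),
                    pair = list(HH = list(De = 0.15, a = 1.8, re = 0.9)),
                    three_body = list(k3 = 0.02, a3 = 1.5, r3 = 0.9))
}

## a CHM model with small random coefficients (for synthetic-recovery and
## invariance tests)
random_chm_model <- function(typing, M, seed = 1, scale = 1e-3,
                             nlparams = NULL) {
  set.seed(seed)
  bset <- chm_basis_set(typing, M)
  if (is.null(nlparams)) {
    alpha <- rep(1, length(typing$classes))
    names(alpha) <- names(typing$classes)
    nlparams <- chm_nlparams(d0 = 2, t0 = 2.5, alpha = alpha)
  }
  ng <- bset$n_gen
  rnd <- function(k) stats::rnorm(k, sd = scale)
  coeffs <- list(
    atom = stats::setNames(lapply(names(bset$atom), function(i) rnd(ng)),
                           names(bset$atom)),
    pair = stats::setNames(lapply(names(bset$pair), function(i) rnd(ng)),
                           names(bset$pair)),
    corr = rnd(bset$L))
  chm_model(bset, nlparams, coeffs)
}
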
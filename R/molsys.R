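## Molecular geometries, atom typing into permutation classes, internuclear
## distances, and the permutation group acting on distance-pair slots.

#' Create a molecular configuration
#'
#' A configuration is an ordered list of element symbols with Cartesian
#' coordinates in Angstrom.
#'
#' @param elements character vector of element symbols, one per atom
#' @param coords numeric matrix (n_atoms x 3) of Cartesian positions in
#'   Angstrom
#' @return an object of class `chm_config`
#' @export
chm_config <- function(elements, coords) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3)
    stop("coords must be an n x 3 numeric matrix")
  if (nrow(coords) != length(elements))
    stop("elements and coords disagree on the number of atoms")
  if (!all(is.finite(coords)))
    stop("non-finite coordinates")
  structure(list(elements = as.character(elements),
                 coords = unname(coords)),
            class = "chm_config")
}

#' @export
print.chm_config <- function(x, ...) {
  cat("<chm_config> ", paste(x$elements, collapse = ""), " (",
      length(x$elements), " atoms)\n", sep = "")
  invisible(x)
}

n_atoms <- function(config) length(config$elements)

#' Declare atom typing: permutation classes, populations, exponents
#'
#' Classes of permutationally equivalent atoms are user-declared (they are
#' not auto-detected from element symbols: e.g. all three formamide
#' hydrogens may be declared as one class even though they are chemically
#' inequivalent).  Permanent electron populations `n_a` are per class, as
#' are the s-Gaussian exponents used by the core-Hamiltonian model.
#'
#' @param classes named list of integer vectors partitioning `1..n_atoms`
#'   (1-based atom indices), e.g. `list(C = 1, H = 2:6)`
#' @param populations named numeric vector, permanent electron population
#'   per class (per atom, not per class total); `>= 0`
#' @param formal_charge integer formal charge of the system
#' @param exponents named numeric vector, Gaussian exponent alpha per class
#'   in bohr^-2; strictly positive
#' @return an object of class `chm_typing`
#' @export
chm_typing <- function(classes, populations, formal_charge = 0L,
                       exponents = NULL) {
  if (is.null(names(classes)) || any(names(classes) == ""))
    stop("classes must be a named list")
  idx <- sort(unlist(classes, use.names = FALSE))
  n <- length(idx)
  if (!identical(as.integer(idx), seq_len(n)))
    stop("classes must partition atom indices 1..n exactly once")
  populations <- populations[names(classes)]
  if (anyNA(populations) || any(populations < 0))
    stop("populations must be declared (>= 0) for every class")
  if (is.null(exponents)) {
    exponents <- rep(1, length(classes))
    names(exponents) <- names(classes)
  } else {
    exponents <- exponents[names(classes)]
    if (anyNA(exponents) || any(exponents <= 0))
      stop("exponents must be declared (> 0) for every class")
  }
  structure(list(classes = lapply(classes, as.integer),
                 populations = populations,
                 formal_charge = as.integer(formal_charge),
                 exponents = exponents,
                 n_atoms = n),
            class = "chm_typing")
}

#' Map atom index to class name
#' @param typing a `chm_typing`
#' @return character vector of length n_atoms
#' @export
atom_class_of <- function(typing) {
  out <- character(typing$n_atoms)
  for (nm in names(typing$classes)) out[typing$classes[[nm]]] <- nm
  out
}

#' Check electron bookkeeping of a typing against a configuration
#'
#' Verifies `sum(n_a) + formal_charge == sum(Z_a)`.
#'
#' @param typing a `chm_typing`
#' @param config a `chm_config`
#' @return TRUE invisibly; errors if inconsistent
#' @export
check_typing <- function(typing, config) {
  if (n_atoms(config) != typing$n_atoms)
    stop("typing and configuration disagree on the number of atoms")
  z <- sum(atomic_number(config$elements))
  cls <- atom_class_of(typing)
  ne <- sum(typing$populations[cls])
  if (abs(ne + typing$formal_charge - z) > 1e-9)
    stop(sprintf("electron count mismatch: sum(n_a)=%.6f + charge=%d != sum(Z)=%d",
                 ne, typing$formal_charge, z))
  invisible(TRUE)
}

#' Canonical ordered atom pairs
#'
#' The `n(n-1)/2` unordered pairs `(i, j)`, `i < j`, in lexicographic order.
#' This ordering defines the distance "slots" used by every PIP.
#'
#' @param n number of atoms
#' @return integer matrix (n_pairs x 2)
#' @export
pair_slots <- function(n) {
  if (n < 2) stop("need at least 2 atoms")
  p <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  colnames(p) <- c("i", "j")
  unname(p[, 1:2, drop = FALSE])
}

#' Internuclear distance vector
#'
#' Distances in Angstrom over the canonical pair slots.
#'
#' @param config a `chm_config` (or a bare n x 3 coordinate matrix)
#' @return numeric vector of length `n(n-1)/2` with attribute `"pairs"`
#' @export
compute_distances <- function(config) {
  coords <- if (inherits(config, "chm_config")) config$coords else as.matrix(config)
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 atoms for distances")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  ps <- pair_slots(n)
  d <- sqrt(rowSums((coords[ps[, 1], , drop = FALSE] -
                     coords[ps[, 2], , drop = FALSE])^2))
  if (any(d <= 0) || any(!is.finite(d)))
    stop("degenerate geometry: coincident atoms")
  attr(d, "pairs") <- ps
  d
}

## all permutations of a vector, rows of a matrix
.permutations_of <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  out <- matrix(0L, factorial(n), n)
  r <- 1L
  for (i in seq_len(n)) {
    rest <- .permutations_of(v[-i])
    k <- nrow(rest)
    out[r:(r + k - 1L), 1L] <- v[i]
    out[r:(r + k - 1L), -1L] <- rest
    r <- r + k
  }
  out
}

#' Build the permutation group of like atoms
#'
#' The direct product of symmetric groups over each atom class, fully
#' enumerated, together with its induced action on distance-pair slots.
#' Element `g` is stored as a vector `g[old] = new`? No: `g` is stored so
#' that atom `a` of the original is atom `g[a]` after relabeling, i.e.
#' applying `g` to a configuration moves the coordinates of atom `a` to
#' row `g[a]`.
#'
#' @param typing a `chm_typing`
#' @param n number of atoms (defaults to `typing$n_atoms`)
#' @param max_order guard on the group order (default 10!)
#' @return an object of class `chm_permgroup` with components `elements`
#'   (order x n matrix), `slot_action` (order x n_pairs matrix such that a
#'   distance vector transforms as `d_new[slot_action[g, ]] = d_old`),
#'   `order`, `pairs`
#' @export
build_perm_group <- function(typing, n = typing$n_atoms,
                             max_order = 3628800) {
  idx <- sort(unlist(typing$classes))
  if (!identical(as.integer(idx), seq_len(n)))
    stop("typing does not partition 1..n")
  ord <- prod(factorial(lengths(typing$classes)))
  if (ord > max_order) stop("group order ", ord, " exceeds max_order")
  mats <- lapply(typing$classes, .permutations_of)
  pick <- expand.grid(lapply(mats, function(m) seq_len(nrow(m))),
                      KEEP.OUT.ATTRS = FALSE)
  G <- matrix(rep(seq_len(n), each = nrow(pick)), nrow(pick), n)
  for (k in seq_along(mats)) {
    cls <- typing$classes[[k]]
    G[, cls] <- mats[[k]][pick[[k]], , drop = FALSE]
  }
  ps <- pair_slots(n)
  D <- nrow(ps)
  key <- function(i, j) (pmin(i, j) - 1L) * n + pmax(i, j)
  lookup <- integer(n * n)
  lookup[key(ps[, 1], ps[, 2])] <- seq_len(D)
  SA <- matrix(0L, nrow(G), D)
  for (g in seq_len(nrow(G)))
    SA[g, ] <- lookup[key(G[g, ps[, 1]], G[g, ps[, 2]])]
  structure(list(elements = G, slot_action = SA, order = nrow(G),
                 pairs = ps, classes = typing$classes),
            class = "chm_permgroup")
}

#' @export
print.chm_permgroup <- function(x, ...) {
  cat("<chm_permgroup> order", x$order, "on", ncol(x$elements), "atoms,",
      ncol(x$slot_action), "pair slots\n")
  invisible(x)
}

#' Apply a like-atom permutation to a configuration
#'
#' Atom `a` is relabeled to `perm[a]`; coordinates move accordingly.  The
#' permutation must only exchange atoms within one typing class.
#'
#' @param config a `chm_config`
#' @param perm integer vector, a permutation of `1..n_atoms`
#' @param typing optional `chm_typing`; when given, cross-class moves are
#'   rejected as symmetry violations
#' @return the permuted `chm_config`
#' @export
apply_permutation <- function(config, perm, typing = NULL) {
  n <- n_atoms(config)
  if (!identical(sort(as.integer(perm)), seq_len(n)))
    stop("perm is not a permutation of 1..n")
  if (!is.null(typing)) {
    cls <- atom_class_of(typing)
    if (any(cls != cls[perm]))
      stop("symmetry violation: permutation crosses atom classes")
  }
  coords <- config$coords
  coords[perm, ] <- config$coords
  elements <- config$elements
  elements[perm] <- config$elements
  chm_config(elements, coords)
}
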
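## Permutationally invariant polynomial (PIP) bases over Morse-transformed
## internuclear distances: enumeration and deduplication of symmetrized
## monomial orbits, atom- and pair-anchored covariant bases, augmented
## bases, and their evaluation.
##
## A monomial is an integer exponent vector over the canonical distance-pair
## slots.  The permutation group of like atoms acts on slots; an invariant
## PIP is the sum of one orbit of monomials under that action.  Covariant
## PIPs anchored at an atom (or unordered pair) are sums over the coset of
## group elements mapping the class reference anchor to the given anchor,
## which makes site values relabel consistently under like-atom
## permutations while the total energy stays invariant.

## ---- monomial bookkeeping -------------------------------------------------

## all exponent vectors over D slots with total degree exactly `deg`
.enum_degree <- function(D, deg) {
  if (deg == 0) return(matrix(0L, 1, D))
  if (D == 1) return(matrix(as.integer(deg), 1, 1))
  out <- vector("list", deg + 1L)
  for (e in 0:deg) {
    rest <- .enum_degree(D - 1L, deg - e)
    out[[e + 1L]] <- cbind(rep(as.integer(e), nrow(rest)), rest)
  }
  do.call(rbind, out)
}

## all exponent vectors with total degree <= M
.enum_monomials <- function(D, M, cap = 5e6) {
  n_total <- choose(D + M, M)
  if (n_total > cap)
    stop("enumeration of ", n_total, " raw monomials exceeds the cap (",
         cap, "); raise `cap` deliberately if you mean it")
  do.call(rbind, lapply(0:M, function(m) .enum_degree(D, m)))
}

## monomials matching one shape pattern (a degree partition placed on
## distinct slots, e.g. c(2, 1) -> all y_s^2 y_t with s != t)
.enum_shape <- function(D, shape) {
  shape <- as.integer(sort(shape, decreasing = TRUE))
  if (any(shape <= 0)) stop("shape parts must be positive integers")
  k <- length(shape)
  if (k > D) stop("shape has more parts than distance slots")
  ## distinct arrangements of the multiset `shape`
  arr <- unique(.permutations_of(shape))
  slots <- utils::combn(D, k)
  out <- matrix(0L, ncol(slots) * nrow(arr), D)
  r <- 1L
  for (ci in seq_len(ncol(slots))) {
    sl <- slots[, ci]
    for (ai in seq_len(nrow(arr))) {
      out[r, sl] <- arr[ai, ]
      r <- r + 1L
    }
  }
  unique(out)
}

## order-isomorphic numeric row keys (slot 1 most significant); falls back
## to fixed-width strings when the numeric encoding would overflow
.row_keys <- function(E, base) {
  D <- ncol(E)
  if (base^D < 2^52) {
    drop(E %*% base^((D - 1):0))
  } else {
    apply(E, 1, function(r) paste(formatC(r, width = 3, flag = "0"),
                                  collapse = ""))
  }
}

## canonical representative of each monomial's orbit: the lexicographically
## minimal image over all group slot actions
.canonicalize <- function(E, group) {
  base <- max(E) + 1L
  keys <- .row_keys(E, base)
  canonE <- E
  ck <- keys
  SA <- group$slot_action
  for (g in seq_len(nrow(SA))) {
    Eg <- E
    Eg[, SA[g, ]] <- E
    kg <- .row_keys(Eg, base)
    upd <- kg < ck
    if (any(upd)) {
      ck[upd] <- kg[upd]
      canonE[upd, ] <- Eg[upd, , drop = FALSE]
    }
  }
  list(canon = canonE, key = ck)
}

## order terms by total degree, then canonical key
.order_terms <- function(terms, keys) {
  order(rowSums(terms), keys)
}

## ---- invariant basis ------------------------------------------------------

#' Enumerate the invariant PIP basis
#'
#' All distinct orbits of monomials of total degree `<= M` in the
#' Morse-transformed internuclear distances, under the induced action of
#' the like-atom permutation group.  The count of orbits (including the
#' constant, degree-0 term when `include_constant`) is the PIP basis size
#' `L`.
#'
#' @param typing a [chm_typing()]
#' @param M maximal total polynomial power, `>= 0`
#' @param n number of atoms (defaults to the typing's)
#' @param include_constant keep the degree-0 term (default TRUE)
#' @param cap guard on the raw monomial count before symmetrization
#' @return an object of class `chm_pip_basis` with fields `terms`
#'   (L x n_pairs canonical exponent matrix), `degree`, `M`, `group`
#' @export
enumerate_invariant_basis <- function(typing, M, n = typing$n_atoms,
                                      include_constant = TRUE, cap = 5e6) {
  if (M < 0) stop("M must be >= 0")
  group <- build_perm_group(typing, n)
  D <- ncol(group$slot_action)
  E <- .enum_monomials(D, M, cap)
  cn <- .canonicalize(E, group)
  keep <- !duplicated(cn$key)
  terms <- cn$canon[keep, , drop = FALSE]
  keys <- cn$key[keep]
  ord <- .order_terms(terms, keys)
  terms <- terms[ord, , drop = FALSE]
  if (!include_constant) {
    nz <- rowSums(terms) > 0
    terms <- terms[nz, , drop = FALSE]
  }
  structure(list(terms = terms, degree = rowSums(terms), M = as.integer(M),
                 n_atoms = n, group = group,
                 includes_constant = include_constant,
                 cache = new.env(parent = emptyenv())),
            class = "chm_pip_basis")
}

#' Number of terms in a basis
#' @param basis a `chm_pip_basis` or `chm_covariant_basis`
#' @return integer count (the `L` of an invariant basis)
#' @export
basis_size <- function(basis) nrow(basis$terms)

#' @export
print.chm_pip_basis <- function(x, ...) {
  cat("<chm_pip_basis> L =", nrow(x$terms), " (M =", x$M,
      if (x$includes_constant) ", constant included" else "", ")\n")
  invisible(x)
}

#' Augment a PIP basis with extra monomial shapes
#'
#' Adds every orbit generated by the given shape patterns (degree
#' partitions placed on distinct distance slots, with no restriction on
#' atoms shared between slots), deduplicated against the base terms.  Base
#' term order is preserved; genuinely new orbits are appended in
#' degree-then-key order.
#'
#' @param basis a `chm_pip_basis`
#' @param patterns list of integer vectors, e.g. `list(3, c(2, 1))` for the
#'   cubic augmentation and `list(4, c(3, 1), c(2, 2), c(2, 1, 1))` for the
#'   quartic one
#' @return the augmented `chm_pip_basis` (M unchanged; `augmented = TRUE`)
#' @export
augment_basis <- function(basis, patterns) {
  D <- ncol(basis$terms)
  extra <- do.call(rbind, lapply(patterns, function(s) .enum_shape(D, s)))
  if (any(rowSums(extra) <= basis$M))
    warning("some pattern degrees do not exceed the base M; duplicates are dropped")
  cn <- .canonicalize(extra, basis$group)
  keep <- !duplicated(cn$key)
  newt <- cn$canon[keep, , drop = FALSE]
  newk <- cn$key[keep]
  base_keys <- .row_keys(basis$terms, max(max(extra), max(basis$terms)) + 1L)
  newk2 <- .row_keys(newt, max(max(extra), max(basis$terms)) + 1L)
  fresh <- !(newk2 %in% base_keys)
  newt <- newt[fresh, , drop = FALSE]
  newk <- newk[fresh]
  ord <- .order_terms(newt, newk)
  terms <- rbind(basis$terms, newt[ord, , drop = FALSE])
  out <- basis
  out$terms <- terms
  out$degree <- rowSums(terms)
  out$augmented <- TRUE
  out$cache <- new.env(parent = emptyenv())
  out
}

## ---- covariant bases ------------------------------------------------------

#' Orbits of distance slots: the symmetry-unique pair classes
#'
#' @param typing a [chm_typing()]
#' @param n number of atoms
#' @return a list with `class_id` (integer per slot), `names` (e.g. "HH",
#'   "CH"), `representative` (slot index of the lexicographically first
#'   member of each class)
#' @export
pair_classes <- function(typing, n = typing$n_atoms) {
  group <- build_perm_group(typing, n)
  D <- ncol(group$slot_action)
  class_id <- integer(D)
  nxt <- 0L
  for (s in seq_len(D)) {
    if (class_id[s] == 0L) {
      nxt <- nxt + 1L
      class_id[group$slot_action[, s]] <- nxt
    }
  }
  cls <- atom_class_of(typing)
  reps <- vapply(seq_len(nxt), function(k) which(class_id == k)[1], 1L)
  nm <- vapply(reps, function(s) {
    ij <- group$pairs[s, ]
    paste(sort(c(cls[ij[1]], cls[ij[2]])), collapse = "")
  }, "")
  ## disambiguate rare name collisions between distinct orbits
  if (anyDuplicated(nm)) nm <- make.unique(nm, sep = "#")
  list(class_id = class_id, names = nm, representative = reps)
}

## coset of group elements mapping the reference anchor to `anchor`
.atom_coset <- function(group, ref, anchor) {
  which(group$elements[, ref] == anchor)
}
.pair_coset <- function(group, ref_pair, anchor_pair) {
  gi <- group$elements[, ref_pair[1]]
  gj <- group$elements[, ref_pair[2]]
  which((gi == anchor_pair[1] & gj == anchor_pair[2]) |
        (gi == anchor_pair[2] & gj == anchor_pair[1]))
}

.covariant_from_coset <- function(typing, M, n, anchor, coset_rows, kind,
                                  group, cap = 5e6) {
  inv <- enumerate_invariant_basis(typing, M, n, include_constant = TRUE,
                                   cap = cap)
  gen <- inv$terms[inv$degree > 0, , drop = FALSE]
  structure(list(terms = gen, degree = rowSums(gen), M = as.integer(M),
                 n_atoms = n, group = group, anchor = anchor, kind = kind,
                 coset_rows = coset_rows,
                 cache = new.env(parent = emptyenv())),
            class = "chm_covariant_basis")
}

#' Enumerate the atom-anchored covariant PIP basis
#'
#' One covariant function per invariant generator of degree `1..M`
#' (count `L - 1`).  Each function is the sum of the generator's images
#' under the coset of group elements mapping the anchor's class reference
#' atom (its smallest index) to the anchor, so that permuting like atoms
#' 1, 2 exchanges the anchor-1 and anchor-2 values exactly.
#'
#' @param typing a [chm_typing()]
#' @param M maximal total power, `>= 1`
#' @param anchor atom index (1-based)
#' @param n number of atoms
#' @return an object of class `chm_covariant_basis`
#' @export
enumerate_atom_covariant_basis <- function(typing, M, anchor,
                                           n = typing$n_atoms) {
  if (M < 1) stop("covariant bases need M >= 1")
  if (anchor < 1 || anchor > n) stop("anchor out of range")
  group <- build_perm_group(typing, n)
  cls <- atom_class_of(typing)
  ref <- min(typing$classes[[cls[anchor]]])
  .covariant_from_coset(typing, M, n, anchor,
                        .atom_coset(group, ref, anchor), "atom", group)
}

#' Enumerate the pair-anchored covariant PIP basis
#'
#' As [enumerate_atom_covariant_basis()] but anchored at an unordered pair
#' of distinct atoms; built over the coset of the setwise stabilizer of the
#' pair class's reference pair.  Symmetric in the two anchor atoms, and the
#' family of values over all pairs relabels covariantly under like-atom
#' permutations (the P_1c to P_2c exchange behavior).
#'
#' @param typing a [chm_typing()]
#' @param M maximal total power, `>= 1`
#' @param anchor integer pair of distinct atom indices
#' @param n number of atoms
#' @return an object of class `chm_covariant_basis`
#' @export
enumerate_pair_covariant_basis <- function(typing, M, anchor,
                                           n = typing$n_atoms) {
  if (M < 1) stop("covariant bases need M >= 1")
  anchor <- as.integer(anchor)
  if (length(anchor) != 2 || anchor[1] == anchor[2])
    stop("anchor must be a pair of distinct atoms")
  group <- build_perm_group(typing, n)
  pc <- pair_classes(typing, n)
  slot_of <- function(p) which(group$pairs[, 1] == min(p) &
                               group$pairs[, 2] == max(p))
  ref <- group$pairs[pc$representative[pc$class_id[slot_of(anchor)]], ]
  .covariant_from_coset(typing, M, n, sort(anchor),
                        .pair_coset(group, ref, anchor), "pair", group)
}

#' @export
print.chm_covariant_basis <- function(x, ...) {
  cat("<chm_covariant_basis>", x$kind, "anchor",
      paste(x$anchor, collapse = ","), ":", nrow(x$terms), "functions\n")
  invisible(x)
}

## ---- evaluation -----------------------------------------------------------

#' Morse transform of a distance vector
#'
#' `y = exp(-d / scale)` per slot.  Integer powers are applied at
#' evaluation time as `y^p = exp(-p d / scale)`.
#'
#' @param dist distances (Angstrom)
#' @param scale range parameter `d0` (Angstrom), `> 0`
#' @return transformed vector
#' @export
morse_variables <- function(dist, scale) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  exp(-dist / scale)
}

## expansion table: all distinct monomials of all orbit/coset sums with a
## row-aggregation index.  `rows` = which group rows to sum over.
.eval_table <- function(terms, group, rows) {
  SA <- group$slot_action[rows, , drop = FALSE]
  L <- nrow(terms)
  D <- ncol(terms)
  big <- matrix(0L, L * nrow(SA), D)
  term_id <- integer(L * nrow(SA))
  r <- 0L
  for (g in seq_len(nrow(SA))) {
    Eg <- terms
    Eg[, SA[g, ]] <- terms
    big[r + seq_len(L), ] <- Eg
    term_id[r + seq_len(L)] <- seq_len(L)
    r <- r + L
  }
  ## drop duplicate (term, monomial) pairs: a monomial determines its orbit,
  ## so dedup on (term_id, exponent row)
  base <- max(big) + 1L
  k <- .row_keys(big, base)
  dk <- if (is.numeric(k) && (L + 1) * (base^D + 1) < 2^52)
    k + term_id * (base^D + 1) else paste(term_id, k)
  keep <- !duplicated(dk)
  list(E = big[keep, , drop = FALSE], term_id = term_id[keep], L = L)
}

.get_eval_table <- function(basis) {
  if (is.null(basis$cache$tab)) {
    rows <- if (inherits(basis, "chm_covariant_basis")) basis$coset_rows
            else seq_len(basis$group$order)
    basis$cache$tab <- .eval_table(basis$terms, basis$group, rows)
  }
  basis$cache$tab
}

#' Evaluate a PIP basis on one or many distance vectors
#'
#' Each term value is the plain sum of its distinct orbit (or coset)
#' monomials evaluated on the Morse variables `exp(-d/scale)`.
#'
#' @param basis a `chm_pip_basis` or `chm_covariant_basis`
#' @param dist a distance vector, or a matrix with one column per
#'   configuration (n_pairs x n_configs)
#' @param scale Morse range parameter (Angstrom): `d0` for invariant and
#'   atom bases, `t0` for pair bases
#' @return a value vector (length = number of terms), or a matrix
#'   (terms x n_configs) for matrix input
#' @export
evaluate_basis <- function(basis, dist, scale) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  tab <- .get_eval_table(basis)
  dm <- if (is.matrix(dist)) dist else matrix(dist, ncol = 1)
  if (nrow(dm) != ncol(basis$terms))
    stop("distance vector length does not match the basis slot count")
  ## monomial value = exp(-(E . d)/scale); aggregate by term
  mono <- exp(-(tab$E %*% dm) / scale)
  out <- unname(rowsum(mono, tab$term_id, reorder = TRUE))
  if (is.matrix(dist)) out else drop(out)
}
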
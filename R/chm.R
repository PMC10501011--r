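## The core-Hamiltonian model (CHM): a PIP-parameterized s-type charge
## density matrix contracted with analytic one-electron core matrices,
## plus a PIP correction energy, fitted linearly to reference energies.
## Also the conventional PIP(M) baseline fit and the nonlinear-parameter
## search shared by both.
##
## Energy model (atomic units internally):
##   E(R) = Enuc(R) + sum_a P_aa Hcore_aa + 2 sum_{a<b} P_ab Hcore_ab
##        + dE(R) + offset
##   P_aa = n_a + sigma_a(R) sum_i c_i^class(a) u_{a,i}(R)
##   P_ab = tau(d_ab) sum_i c_i^pairclass(ab) v_{ab,i}(R)
##   dE   = sum_i c_i^corr u_i(R)
## u are atom-covariant PIPs on Morse variables exp(-d/d0), v pair-covariant
## PIPs on exp(-d/t0), u_i invariant PIPs on exp(-d/d0).

## ---- datasets -------------------------------------------------------------

#' Bundle configurations with reference energies and fit weights
#'
#' @param configs list of [chm_config()] (identical element ordering)
#' @param energies reference energies, one per configuration
#' @param unit unit of `energies`: "hartree" (default) or "cm-1"
#' @param weights per-point fit weights (default 1)
#' @return an object of class `chm_dataset`; energies stored in hartree
#' @export
chm_dataset <- function(configs, energies, unit = "hartree", weights = NULL) {
  if (length(configs) == 0) stop("empty dataset")
  if (length(configs) != length(energies))
    stop("configs and energies differ in length")
  if (!all(is.finite(energies))) stop("non-finite reference energies")
  if (is.null(weights)) weights <- rep(1, length(energies))
  if (length(weights) != length(energies))
    stop("weights and energies differ in length")
  structure(list(configs = configs,
                 energies = convert_energy(energies, unit, "hartree"),
                 weights = weights),
            class = "chm_dataset")
}

#' @export
print.chm_dataset <- function(x, ...) {
  cat("<chm_dataset>", length(x$configs), "configurations, energy span",
      format(hartree2cm(diff(range(x$energies))), digits = 6), "cm-1\n")
  invisible(x)
}

#' @export
length.chm_dataset <- function(x) length(x$configs)

## coordinates of a dataset / config list as a (3 x n_atoms x n_configs)
## array in bohr
.coords_array <- function(configs) {
  n <- n_atoms(configs[[1]])
  X <- array(0, c(3, n, length(configs)))
  for (k in seq_along(configs)) X[, , k] <- t(ang2bohr(configs[[k]]$coords))
  X
}

## distance matrix (n_pairs x n_configs), Angstrom
.dist_matrix <- function(configs) {
  vapply(configs, function(cf) as.numeric(compute_distances(cf)),
         numeric(nrow(pair_slots(n_atoms(configs[[1]])))))
}

## ---- basis-set bundle -----------------------------------------------------

## covariant basis object sharing a precomputed generator table
.make_cov <- function(gen, group, anchor, coset_rows, kind, M, n) {
  structure(list(terms = gen, degree = rowSums(gen), M = M, n_atoms = n,
                 group = group, anchor = anchor, kind = kind,
                 coset_rows = coset_rows,
                 cache = new.env(parent = emptyenv())),
            class = "chm_covariant_basis")
}

#' Build the full CHM basis bundle for one system
#'
#' Enumerates the invariant PIP basis (optionally augmented), then the
#' atom-covariant family for every atom of every class and the
#' pair-covariant family for every symmetry-unique pair class.
#'
#' @param typing a [chm_typing()]
#' @param M maximal total PIP power
#' @param patterns optional augmentation shape patterns
#'   (see [augment_basis()])
#' @param convention `"exclude_constant"` (default): density-class
#'   expansions carry the `L - 1` non-constant generators and only the
#'   correction term keeps the constant, total
#'   `(n_classes)(L - 1) + L` coefficients. `"per_class"`: every class
#'   carries all `L` terms (the per-class-L counting used for the smallest
#'   systems).
#' @return an object of class `chm_basis_set`
#' @export
chm_basis_set <- function(typing, M,
                          patterns = NULL,
                          convention = c("exclude_constant", "per_class")) {
  convention <- match.arg(convention)
  inv <- enumerate_invariant_basis(typing, M)
  if (!is.null(patterns)) inv <- augment_basis(inv, patterns)
  group <- inv$group
  n <- typing$n_atoms
  L <- nrow(inv$terms)
  gen <- if (convention == "exclude_constant")
    inv$terms[inv$degree > 0, , drop = FALSE] else inv$terms
  atom <- list()
  for (nm in names(typing$classes)) {
    anchors <- typing$classes[[nm]]
    ref <- min(anchors)
    bases <- lapply(anchors, function(a)
      .make_cov(gen, group, a, .atom_coset(group, ref, a), "atom", inv$M, n))
    atom[[nm]] <- list(anchors = anchors, bases = bases)
  }
  pc <- pair_classes(typing, n)
  pair <- list()
  for (k in seq_along(pc$names)) {
    slots <- which(pc$class_id == k)
    ref <- group$pairs[pc$representative[k], ]
    bases <- lapply(slots, function(s) {
      ap <- group$pairs[s, ]
      .make_cov(gen, group, ap, .pair_coset(group, ref, ap), "pair", inv$M, n)
    })
    pair[[pc$names[k]]] <- list(slots = slots,
                                anchors = group$pairs[slots, , drop = FALSE],
                                bases = bases)
  }
  structure(list(typing = typing, M = as.integer(M), patterns = patterns,
                 convention = convention, inv = inv, atom = atom,
                 pair = pair, L = L,
                 n_gen = nrow(gen)),
            class = "chm_basis_set")
}

#' Total number of linear coefficients of a CHM basis bundle
#' @param bset a [chm_basis_set()]
#' @return `(n_atom_classes + n_pair_classes) * n_gen + L`
#' @export
chm_coef_count <- function(bset) {
  (length(bset$atom) + length(bset$pair)) * bset$n_gen + bset$L
}

#' @export
print.chm_basis_set <- function(x, ...) {
  cat("<chm_basis_set> M =", x$M, if (!is.null(x$patterns)) "(augmented)",
      " L =", x$L, "; classes:",
      paste(c(names(x$atom), names(x$pair)), collapse = ", "),
      "; coefficients:", chm_coef_count(x), "\n")
  invisible(x)
}

## ---- nonlinear parameters and the model object ----------------------------

#' Nonlinear parameters of the CHM model
#'
#' @param d0 Morse range for atom/correction PIPs, Angstrom, `> 0`
#' @param t0 Morse range for pair PIPs, Angstrom, `> 0`
#' @param alpha named numeric vector of s-Gaussian exponents per atom
#'   class, bohr^-2, `> 0`
#' @param tau_rs length scale (Angstrom) of the short-range damping
#'   `tau(d) = 1 - exp(-(d / tau_rs)^2)` applied to off-diagonal density
#'   elements so they vanish smoothly at the united-atom limit
#' @return an object of class `chm_nlparams`
#' @export
chm_nlparams <- function(d0 = 2, t0 = 2, alpha, tau_rs = 0.05) {
  if (d0 <= 0 || t0 <= 0 || tau_rs <= 0 || any(alpha <= 0))
    stop("all nonlinear parameters must be strictly positive")
  structure(list(d0 = d0, t0 = t0, alpha = alpha, tau_rs = tau_rs),
            class = "chm_nlparams")
}

.tau <- function(d, rs) 1 - exp(-(d / rs)^2)

#' Construct a CHM model
#'
#' @param bset a [chm_basis_set()]
#' @param nlparams a [chm_nlparams()]
#' @param coeffs optional named list with `atom` (list per class), `pair`
#'   (list per class) and `corr` coefficient vectors; defaults to zeros
#' @param energy_offset reference-energy origin, hartree
#' @return an object of class `chm_model`
#' @export
chm_model <- function(bset, nlparams, coeffs = NULL, energy_offset = 0) {
  ng <- bset$n_gen
  if (is.null(coeffs)) {
    z <- function(nms) stats::setNames(lapply(nms, function(i) numeric(ng)), nms)
    coeffs <- list(atom = z(names(bset$atom)), pair = z(names(bset$pair)),
                   corr = numeric(bset$L))
  }
  stopifnot(all(lengths(coeffs$atom) == ng),
            all(lengths(coeffs$pair) == ng),
            length(coeffs$corr) == bset$L)
  ## exponents in the typing follow the nonlinear parameters
  typing <- bset$typing
  typing$exponents <- nlparams$alpha[names(typing$classes)]
  if (anyNA(typing$exponents))
    stop("nlparams$alpha must carry one named exponent per atom class (",
         paste(names(typing$classes), collapse = ", "), ")")
  bset$typing <- typing
  structure(list(bset = bset, typing = typing, nlparams = nlparams,
                 coeffs = coeffs, energy_offset = energy_offset),
            class = "chm_model")
}

#' @export
print.chm_model <- function(x, ...) {
  cat("<chm_model> M =", x$bset$M, ", L =", x$bset$L, ",",
      chm_coef_count(x$bset), "linear coefficients; d0 =",
      format(x$nlparams$d0, digits = 4), "t0 =",
      format(x$nlparams$t0, digits = 4), "\n")
  invisible(x)
}

## flatten / unflatten the coefficient vector in design-column order:
## [atom classes x n_gen | pair classes x n_gen | correction x L]
.flatten_coeffs <- function(coeffs) {
  c(unlist(coeffs$atom, use.names = FALSE),
    unlist(coeffs$pair, use.names = FALSE), coeffs$corr)
}
.unflatten_coeffs <- function(beta, bset) {
  ng <- bset$n_gen
  pos <- 0
  take <- function(k) {
    out <- beta[pos + seq_len(k)]
    pos <<- pos + k
    out
  }
  atom <- stats::setNames(lapply(names(bset$atom), function(nm) take(ng)),
                          names(bset$atom))
  pair <- stats::setNames(lapply(names(bset$pair), function(nm) take(ng)),
                          names(bset$pair))
  list(atom = atom, pair = pair, corr = take(bset$L))
}

## ---- design blocks --------------------------------------------------------

## Everything the linear model needs, for a list of configurations:
##   base   : Enuc + sum_a n_a Hcore_aa              (nc)
##   Xe     : energy design block                    (nc x p)
##   Xq     : total-charge design block (target 0)   (nc x p)
##   Enuc   : nuclear repulsion                      (nc)
## Columns ordered [atom classes | pair classes | correction].
.design_blocks <- function(bset, configs, nlparams, want_charge = TRUE) {
  typing <- bset$typing
  typing$exponents <- nlparams$alpha[names(typing$classes)]
  nc <- length(configs)
  n <- typing$n_atoms
  cls <- atom_class_of(typing)
  X <- .coords_array(configs)
  cm <- .core_matrices_batch(X, atomic_number(configs[[1]]$elements),
                             typing$exponents[cls])
  Dmat <- .dist_matrix(configs)
  ng <- bset$n_gen
  p <- chm_coef_count(bset)
  Xe <- matrix(0, nc, p)
  Xq <- if (want_charge) matrix(0, nc, p) else NULL
  col <- 0
  for (nm in names(bset$atom)) {
    blkE <- matrix(0, ng, nc)
    blkQ <- matrix(0, ng, nc)
    fam <- bset$atom[[nm]]
    for (j in seq_along(fam$anchors)) {
      a <- fam$anchors[j]
      U <- evaluate_basis(fam$bases[[j]], Dmat, nlparams$d0) # ng x nc
      if (!is.matrix(U)) U <- matrix(U, ng, nc)
      haa <- cm$H[a, a, ]
      blkE <- blkE + U * rep(haa, each = ng)
      if (want_charge) blkQ <- blkQ + U            # S_aa = 1
    }
    Xe[, col + seq_len(ng)] <- t(blkE)
    if (want_charge) Xq[, col + seq_len(ng)] <- t(blkQ)
    col <- col + ng
  }
  for (nm in names(bset$pair)) {
    blkE <- matrix(0, ng, nc)
    blkQ <- matrix(0, ng, nc)
    fam <- bset$pair[[nm]]
    for (j in seq_along(fam$slots)) {
      s <- fam$slots[j]
      ab <- fam$anchors[j, ]
      V <- evaluate_basis(fam$bases[[j]], Dmat, nlparams$t0)
      if (!is.matrix(V)) V <- matrix(V, ng, nc)
      tauv <- .tau(Dmat[s, ], nlparams$tau_rs)
      hab <- cm$H[ab[1], ab[2], ]
      sab <- cm$S[ab[1], ab[2], ]
      blkE <- blkE + V * rep(2 * tauv * hab, each = ng)
      if (want_charge) blkQ <- blkQ + V * rep(2 * tauv * sab, each = ng)
    }
    Xe[, col + seq_len(ng)] <- t(blkE)
    if (want_charge) Xq[, col + seq_len(ng)] <- t(blkQ)
    col <- col + ng
  }
  U0 <- evaluate_basis(bset$inv, Dmat, nlparams$d0)  # L x nc
  if (!is.matrix(U0)) U0 <- matrix(U0, bset$L, nc)
  Xe[, col + seq_len(bset$L)] <- t(U0)
  pop <- typing$populations[cls]
  haa_sum <- numeric(nc)
  for (a in seq_len(n)) haa_sum <- haa_sum + pop[a] * cm$H[a, a, ]
  list(base = cm$Enuc + haa_sum, Xe = Xe, Xq = Xq, Enuc = cm$Enuc,
       S = cm$S, H = cm$H, Dmat = Dmat, n_electrons = sum(pop))
}

## ---- model evaluation -----------------------------------------------------

.as_config_list <- function(x) {
  if (inherits(x, "chm_config")) list(x)
  else if (inherits(x, "chm_dataset")) x$configs
  else x
}

#' CHM potential energy of one or more configurations
#'
#' @param config a [chm_config()], list of them, or a [chm_dataset()]
#' @param model a [chm_model()]
#' @return energies in hartree (vector)
#' @export
chm_energy <- function(config, model) {
  configs <- .as_config_list(config)
  db <- .design_blocks(model$bset, configs, model$nlparams,
                       want_charge = FALSE)
  drop(db$base + db$Xe %*% .flatten_coeffs(model$coeffs)) +
    model$energy_offset
}

#' Diagonal density matrix element P_aa
#'
#' `P_aa = n_a + sigma_a(R) sum_i c_i u_{a,i}(R)`; the long-range damping
#' `sigma_a` is 1 by default (the Morse variables already decay).  Reduces
#' to the permanent population `n_a` for zero coefficients.
#'
#' @param config a [chm_config()]
#' @param model a [chm_model()]
#' @param a atom index (1-based)
#' @return electrons on atom `a`
#' @export
density_diagonal <- function(config, model, a) {
  typing <- model$typing
  cls <- atom_class_of(typing)
  if (a < 1 || a > typing$n_atoms) stop("unknown atom index")
  nm <- cls[a]
  fam <- model$bset$atom[[nm]]
  j <- match(a, fam$anchors)
  d <- compute_distances(config)
  u <- evaluate_basis(fam$bases[[j]], d, model$nlparams$d0)
  unname(typing$populations[nm] + sum(model$coeffs$atom[[nm]] * u))
}

#' Off-diagonal density matrix element P_ab
#'
#' `P_ab = tau(d_ab) sum_i c_i v_{ab,i}(R)`, symmetric in `a, b`, vanishing
#' at large separation (exponential decay of the t-variables) and at the
#' united-atom limit (short-range damping `tau`).
#'
#' @param config a [chm_config()]
#' @param model a [chm_model()]
#' @param a,b distinct atom indices
#' @return bond-order element (dimensionless)
#' @export
density_offdiagonal <- function(config, model, a, b) {
  if (a == b) stop("diagonal element requested: use density_diagonal()")
  group <- model$bset$inv$group
  slot <- which(group$pairs[, 1] == min(a, b) & group$pairs[, 2] == max(a, b))
  nm <- NULL
  for (cand in names(model$bset$pair))
    if (slot %in% model$bset$pair[[cand]]$slots) nm <- cand
  fam <- model$bset$pair[[nm]]
  j <- match(slot, fam$slots)
  d <- compute_distances(config)
  v <- evaluate_basis(fam$bases[[j]], d, model$nlparams$t0)
  unname(.tau(d[slot], model$nlparams$tau_rs) *
           sum(model$coeffs$pair[[nm]] * v))
}

#' Configuration-dependent total electron count
#'
#' `n(R) = sum_ab P_ab(R) S_ab(R)`; equals `sum_a n_a` for zero
#' coefficients.
#'
#' @param config a [chm_config()] (or list / dataset)
#' @param model a [chm_model()]
#' @return electron count(s)
#' @export
total_electron_count <- function(config, model) {
  configs <- .as_config_list(config)
  db <- .design_blocks(model$bset, configs, model$nlparams)
  drop(db$n_electrons + db$Xq %*% .flatten_coeffs(model$coeffs))
}

#' Split the CHM energy into its HF-like and correction components
#'
#' The HF-like part is `Enuc + sum_ab P_ab Hcore_ab` (plus the stored
#' offset); the correction is the standalone PIP expansion `dE`.  The two
#' sum exactly to [chm_energy()].
#'
#' @param config a [chm_config()] (or list / dataset)
#' @param model a [chm_model()]
#' @return list with components `hf_like` and `correction`, cm^-1
#' @export
energy_decomposition <- function(config, model) {
  configs <- .as_config_list(config)
  db <- .design_blocks(model$bset, configs, model$nlparams,
                       want_charge = FALSE)
  beta <- .flatten_coeffs(model$coeffs)
  p <- length(beta)
  L <- model$bset$L
  beta_hf <- beta; beta_hf[(p - L + 1):p] <- 0
  beta_corr <- beta; beta_corr[seq_len(p - L)] <- 0
  hf <- drop(db$base + db$Xe %*% beta_hf) + model$energy_offset
  corr <- drop(db$Xe %*% beta_corr)
  list(hf_like = hartree2cm(hf), correction = hartree2cm(corr))
}

## ---- design assembly and linear fitting -----------------------------------

#' Assemble the weighted linear system for a CHM fit
#'
#' One energy row per configuration (targets
#' `E_ref - offset - Enuc - sum_a n_a Hcore_aa`, hartree) and, when
#' `charge_weight > 0`, one total-charge row per configuration with target
#' 0 and the given weight.
#'
#' @param dataset a [chm_dataset()]
#' @param bset a [chm_basis_set()] (or pass `typing` and `M`)
#' @param nlparams a [chm_nlparams()]
#' @param charge_weight least-squares weight of the charge-conservation
#'   rows (0.01 by default; 0 disables them)
#' @param offset energy origin subtracted from the targets (default: the
#'   dataset minimum energy)
#' @return list with design `X`, targets `y`, weights `w`, `n_energy_rows`,
#'   `offset`, and the block structure
#' @export
assemble_design <- function(dataset, bset, nlparams, charge_weight = 0.01,
                            offset = NULL) {
  if (length(dataset) == 0) stop("empty dataset")
  if (is.null(offset)) offset <- min(dataset$energies)
  db <- .design_blocks(bset, dataset$configs, nlparams,
                       want_charge = charge_weight > 0)
  y <- dataset$energies - offset - db$base
  X <- db$Xe
  w <- dataset$weights
  if (charge_weight > 0) {
    X <- rbind(X, db$Xq)
    y <- c(y, numeric(length(dataset)))
    w <- c(w, rep(charge_weight, length(dataset)))
  }
  if (!all(is.finite(X)))
    stop("non-finite design entries in rows ",
         paste(utils::head(which(!apply(is.finite(X), 1, all))), collapse = ","))
  list(X = X, y = y, w = w, n_energy_rows = length(dataset),
       offset = offset,
       blocks = c(stats::setNames(rep(bset$n_gen, length(bset$atom) +
                                        length(bset$pair)),
                                  c(names(bset$atom), names(bset$pair))),
                  corr = bset$L))
}

#' Weighted linear least squares by QR, with a minimum-norm fallback
#'
#' Solves `min || sqrt(w) (X b - y) ||`.  Full-rank systems go through the
#' QR decomposition; rank-deficient ones fall back to the SVD minimum-norm
#' solution and are flagged (never a hard failure: near-duplicate sampled
#' configurations make this routine).
#'
#' @param X design matrix
#' @param y targets
#' @param w weights (default 1)
#' @return list with `coef`, `rank`, `rank_deficient`, `condition`
#' @export
fit_linear <- function(X, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  if (nrow(X) != length(y) || length(w) != length(y))
    stop("X, y, w dimensions disagree")
  if (all(w == 0)) stop("all-zero weights")
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  qrx <- qr(Xw, LAPACK = TRUE)
  rank_tol <- max(dim(Xw)) * .Machine$double.eps
  dR <- abs(diag(qr.R(qrx)))
  rank <- sum(dR > max(dR) * rank_tol)
  if (rank == ncol(X)) {
    beta <- qr.coef(qrx, yw)
    cond <- max(dR) / min(dR)
    list(coef = unname(beta), rank = rank, rank_deficient = FALSE,
         condition = cond)
  } else {
    sv <- svd(Xw)
    pos <- sv$d > max(sv$d) * rank_tol
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% yw) / sv$d[pos])
    warning("rank-deficient design (rank ", sum(pos), " of ", ncol(X),
            "): returning the minimum-norm solution")
    list(coef = drop(beta), rank = sum(pos), rank_deficient = TRUE,
         condition = max(sv$d) / min(sv$d[pos]))
  }
}

.fit_report <- function(model, residuals_cm, n_params, diagnostics,
                        rmse_test = NA_real_) {
  structure(list(model = model,
                 rmse_train = sqrt(mean(residuals_cm^2)),
                 rmse_test = rmse_test,
                 residuals = residuals_cm,
                 n_params = n_params,
                 condition_note = diagnostics),
            class = "chm_fit")
}

#' @export
print.chm_fit <- function(x, ...) {
  cat("<chm_fit>", x$n_params, "parameters; train RMSE",
      format(x$rmse_train, digits = 5), "cm-1",
      if (!is.na(x$rmse_test)) paste("; test RMSE",
                                     format(x$rmse_test, digits = 5), "cm-1"),
      "\n")
  invisible(x)
}

#' Fit a CHM model to a dataset
#'
#' @param dataset a [chm_dataset()]
#' @param typing a [chm_typing()]
#' @param M PIP order
#' @param nlparams a [chm_nlparams()]
#' @param charge_weight weight of the total-charge rows (default 0.01)
#' @param patterns optional augmentation patterns
#' @param convention see [chm_basis_set()]
#' @param bset optionally a prebuilt [chm_basis_set()] (overrides
#'   `M`/`patterns`/`convention`)
#' @return a `chm_fit` report; the fitted model is `$model`
#' @export
fit_chm <- function(dataset, typing, M, nlparams, charge_weight = 0.01,
                    patterns = NULL,
                    convention = "exclude_constant", bset = NULL) {
  if (is.null(bset))
    bset <- chm_basis_set(typing, M, patterns, convention)
  des <- assemble_design(dataset, bset, nlparams, charge_weight)
  fl <- fit_linear(des$X, des$y, des$w)
  model <- chm_model(bset, nlparams, .unflatten_coeffs(fl$coef, bset),
                     energy_offset = des$offset)
  pred <- des$X[seq_len(des$n_energy_rows), , drop = FALSE] %*% fl$coef
  res <- hartree2cm(drop(pred) - des$y[seq_len(des$n_energy_rows)])
  .fit_report(model, res, length(fl$coef),
              sprintf("rank %d/%d, condition %.3g%s", fl$rank, ncol(des$X),
                      fl$condition,
                      if (fl$rank_deficient) " (minimum-norm)" else ""))
}

## ---- conventional PIP(M) baseline -----------------------------------------

#' Fit the conventional PIP(M) baseline
#'
#' Plain weighted linear fit `E(R) ~ sum_i c_i u_i(R)` over the `L`
#' invariant PIPs (constant included).
#'
#' @param dataset a [chm_dataset()]
#' @param typing a [chm_typing()]
#' @param M PIP order
#' @param d0 Morse range parameter, Angstrom
#' @param patterns optional augmentation patterns
#' @param basis optionally a prebuilt invariant `chm_pip_basis`
#' @return a `chm_fit` report; `$model` is a `chm_pip_model`
#' @export
fit_pip_baseline <- function(dataset, typing, M, d0 = 2, patterns = NULL,
                             basis = NULL) {
  if (is.null(basis)) {
    basis <- enumerate_invariant_basis(typing, M)
    if (!is.null(patterns)) basis <- augment_basis(basis, patterns)
  }
  offset <- min(dataset$energies)
  Dmat <- .dist_matrix(dataset$configs)
  U <- evaluate_basis(basis, Dmat, d0)
  if (!is.matrix(U)) U <- matrix(U, nrow(basis$terms), length(dataset))
  X <- t(U)
  y <- dataset$energies - offset
  fl <- fit_linear(X, y, dataset$weights)
  model <- structure(list(basis = basis, coeffs = fl$coef, d0 = d0,
                          energy_offset = offset, typing = typing),
                     class = "chm_pip_model")
  res <- hartree2cm(drop(X %*% fl$coef) - y)
  .fit_report(model, res, length(fl$coef),
              sprintf("rank %d/%d, condition %.3g", fl$rank, ncol(X),
                      fl$condition))
}

#' Energy and analytic gradient of the conventional PIP model
#'
#' Gradient by the chain rule through the Morse variables: for each
#' monomial, `d/d d_s = -(p_s / d0) * value`, mapped onto Cartesian
#' displacements along the pair unit vectors.
#'
#' @param config a [chm_config()]
#' @param model a `chm_pip_model`
#' @return list with `energy` (hartree) and `gradient`
#'   (hartree/Angstrom, n_atoms x 3); suitable as the `pes` argument of
#'   [run_nve()]
#' @export
pip_energy_gradient <- function(config, model) {
  d <- compute_distances(config)
  ps <- attr(d, "pairs")
  tab <- .get_eval_table(model$basis)
  mono <- drop(exp(-(tab$E %*% as.numeric(d)) / model$d0))
  cterm <- model$coeffs[tab$term_id]
  energy <- sum(cterm * mono) + model$energy_offset
  ## dE/dd_s = sum_monomials c * (-E[, s]/d0) * mono
  dE_dd <- drop(crossprod(tab$E, cterm * mono)) * (-1 / model$d0)
  n <- n_atoms(config)
  grad <- matrix(0, n, 3)
  for (s in seq_along(d)) {
    i <- ps[s, 1]; j <- ps[s, 2]
    u <- (config$coords[i, ] - config$coords[j, ]) / d[s]
    grad[i, ] <- grad[i, ] + dE_dd[s] * u
    grad[j, ] <- grad[j, ] - dE_dd[s] * u
  }
  list(energy = energy, gradient = grad)
}

#' Energy of the conventional PIP model
#' @param config a [chm_config()] (or list / dataset)
#' @param model a `chm_pip_model`
#' @return energies, hartree
#' @export
pip_energy <- function(config, model) {
  configs <- .as_config_list(config)
  Dmat <- .dist_matrix(configs)
  U <- evaluate_basis(model$basis, Dmat, model$d0)
  if (!is.matrix(U)) U <- matrix(U, length(model$coeffs), length(configs))
  drop(crossprod(U, model$coeffs)) + model$energy_offset
}

## ---- reporting ------------------------------------------------------------

#' Evaluate a fitted model on a test dataset
#'
#' @param model a `chm_model` or `chm_pip_model` (or a `chm_fit`, whose
#'   model is used)
#' @param dataset a [chm_dataset()]
#' @return a `chm_report`: residuals (cm^-1), RMSE, maximum error and its
#'   configuration index, and a residual-versus-energy table
#' @export
evaluate_report <- function(model, dataset) {
  if (inherits(model, "chm_fit")) model <- model$model
  pred <- if (inherits(model, "chm_pip_model")) pip_energy(dataset, model)
          else chm_energy(dataset, model)
  res <- hartree2cm(pred - dataset$energies)
  e_above <- hartree2cm(dataset$energies - min(dataset$energies))
  structure(list(rmse = sqrt(mean(res^2)),
                 residuals = res,
                 max_error = max(abs(res)),
                 max_error_index = which.max(abs(res)),
                 table = data.frame(energy_above_min = e_above,
                                    residual = res)),
            class = "chm_report")
}

#' @export
print.chm_report <- function(x, ...) {
  cat("<chm_report> RMSE", format(x$rmse, digits = 6), "cm-1; max |err|",
      format(x$max_error, digits = 6), "cm-1 at point", x$max_error_index,
      "\n")
  invisible(x)
}

## ---- nonlinear parameter search -------------------------------------------

#' Default search space for the nonlinear parameters
#'
#' `d0`, `t0` on a 9-point logarithmic grid over `[1, 5]` Angstrom; every
#' class exponent on a 7-point grid over `[0.2, 2]` bohr^-2.
#'
#' @param typing a [chm_typing()]
#' @return named list of grids
#' @export
default_search_space <- function(typing) {
  gs <- list(d0 = exp(seq(log(1), log(5), length.out = 9)),
             t0 = exp(seq(log(1), log(5), length.out = 9)))
  for (nm in names(typing$classes))
    gs[[paste0("alpha.", nm)]] <- exp(seq(log(0.2), log(2), length.out = 7))
  gs
}

.nl_to_params <- function(theta, typing, tau_rs) {
  alpha <- theta[paste0("alpha.", names(typing$classes))]
  names(alpha) <- names(typing$classes)
  if ("tau_rs" %in% names(theta)) tau_rs <- theta[["tau_rs"]]
  chm_nlparams(d0 = theta[["d0"]], t0 = theta[["t0"]], alpha = alpha,
               tau_rs = tau_rs)
}

#' Optimize the nonlinear range parameters and exponents
#'
#' Coordinate-wise search over the supplied grids (cycled until no
#' parameter moves, at most `max_sweeps` sweeps), followed by Nelder-Mead
#' refinement in log space with a bounded evaluation budget.  The
#' objective is the validation-set energy RMSE of the refitted model.
#' Deterministic given the seed and the search space.
#'
#' @param dataset_train a [chm_dataset()]
#' @param dataset_val validation dataset (defaults to the training set,
#'   giving the variationally best training RMSE)
#' @param typing a [chm_typing()]
#' @param M PIP order
#' @param search_space named list of finite grids as from
#'   [default_search_space()]; an optional `tau_rs` grid adds the
#'   short-range damping scale to the search
#' @param seed RNG seed (the search itself is deterministic; the seed is
#'   fixed for reproducibility of any downstream stochastic use)
#' @param charge_weight passed to [fit_chm()]
#' @param patterns,convention passed to [chm_basis_set()]
#' @param tau_rs short-range damping scale, Angstrom
#' @param max_sweeps coordinate-descent sweep budget
#' @param simplex_evals Nelder-Mead evaluation budget (0 disables)
#' @return list with `nlparams`, `fit` (a `chm_fit` on the training set),
#'   `objective` (validation RMSE, cm^-1), `n_eval`
#' @export
optimize_nonlinear <- function(dataset_train, dataset_val = NULL, typing, M,
                               search_space = default_search_space(typing),
                               seed = 0, charge_weight = 0.01,
                               patterns = NULL,
                               convention = "exclude_constant",
                               tau_rs = 0.05, max_sweeps = 3,
                               simplex_evals = 200) {
  if (any(!vapply(search_space, function(g) all(is.finite(g)) &&
                    length(g) >= 1, TRUE)))
    stop("search space must consist of finite grids")
  set.seed(as.integer(seed))
  if (is.null(dataset_val)) dataset_val <- dataset_train
  bset <- chm_basis_set(typing, M, patterns, convention)
  n_eval <- 0L
  objective <- function(theta) {
    nl <- .nl_to_params(theta, typing, tau_rs)
    fit <- fit_chm(dataset_train, typing, M, nl, charge_weight, bset = bset)
    n_eval <<- n_eval + 1L
    evaluate_report(fit$model, dataset_val)$rmse
  }
  theta <- vapply(search_space, function(g) g[ceiling(length(g) / 2)], 1)
  best <- suppressWarnings(objective(theta))
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (nm in names(search_space)) {
      for (val in search_space[[nm]]) {
        if (val == theta[[nm]]) next
        cand <- theta
        cand[[nm]] <- val
        obj <- suppressWarnings(objective(cand))
        if (obj < best - 1e-12) {
          best <- obj
          theta <- cand
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  if (simplex_evals > 0) {
    nm_names <- names(theta)
    opt <- suppressWarnings(stats::optim(
      log(unlist(theta)),
      function(lt) {
        th <- stats::setNames(as.list(exp(lt)), nm_names)
        objective(unlist(th))
      },
      method = "Nelder-Mead",
      control = list(maxit = simplex_evals)))
    if (opt$value < best) {
      best <- opt$value
      theta <- stats::setNames(exp(opt$par), nm_names)
    }
  }
  nl <- .nl_to_params(unlist(theta), typing, tau_rs)
  fit <- fit_chm(dataset_train, typing, M, nl, charge_weight, bset = bset)
  list(nlparams = nl, fit = fit, objective = best, n_eval = n_eval)
}
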
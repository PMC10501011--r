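## Dataset, basis and model I/O.  Geometries travel as (extended) XYZ:
## atom count, a comment line carrying key=value metadata (energy=...,
## unit=hartree|cm-1), then "element x y z" in Angstrom.  Bases and models
## serialize to JSON so they can be reloaded without re-enumeration.

#' Read an (extended) XYZ file
#'
#' @param path file path
#' @return a [chm_dataset()] when every frame carries an `energy=` tag,
#'   otherwise a list of [chm_config()]
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  configs <- list()
  energies <- numeric(0)
  units <- character(0)
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("parse error at line ", i, ": expected atom count")
    if (i + 1 + nat > length(lines))
      stop("parse error at line ", i, ": truncated frame")
    comment <- lines[i + 1]
    rows <- strsplit(trimws(lines[(i + 2):(i + 1 + nat)]), "\\s+")
    if (any(lengths(rows) < 4))
      stop("parse error near line ", i + 2, ": need 'element x y z'")
    el <- vapply(rows, `[`, "", 1)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("parse error near line ", i + 2,
                         ": non-numeric coordinate")
    configs[[length(configs) + 1]] <- chm_config(el, xyz)
    kv <- .parse_kv(comment)
    energies <- c(energies, if (!is.null(kv$energy)) as.numeric(kv$energy)
                            else NA_real_)
    units <- c(units, if (!is.null(kv$unit)) kv$unit else "hartree")
    i <- i + 2 + nat
  }
  if (length(configs) == 0) stop("no frames in ", path)
  if (!anyNA(energies)) {
    u <- unique(units)
    if (length(u) > 1) stop("mixed energy units in ", path)
    chm_dataset(configs, energies, unit = u)
  } else configs
}

.parse_kv <- function(comment) {
  toks <- regmatches(comment,
                     gregexpr("[A-Za-z_][A-Za-z0-9_-]*=[^ \t]+", comment))[[1]]
  out <- list()
  for (tk in toks) {
    eq <- regexpr("=", tk, fixed = TRUE)
    out[[substr(tk, 1, eq - 1)]] <- substr(tk, eq + 1, nchar(tk))
  }
  out
}

#' Write configurations (optionally with energies) as extended XYZ
#'
#' @param x a [chm_dataset()], a list of [chm_config()], or one config
#' @param path output file
#' @param unit energy unit to write (`"hartree"` default)
#' @param comment extra key=value text appended to every comment line
#'   (e.g. provenance: seed, preset)
#' @return `path`, invisibly
#' @export
write_xyz <- function(x, path, unit = "hartree", comment = "") {
  configs <- .as_config_list(x)
  energies <- if (inherits(x, "chm_dataset"))
    convert_energy(x$energies, "hartree", unit) else NULL
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(configs)) {
    cf <- configs[[k]]
    writeLines(as.character(n_atoms(cf)), con)
    head <- if (!is.null(energies))
      sprintf("energy=%.12e unit=%s", energies[k], unit) else ""
    writeLines(trimws(paste(head, comment)), con)
    writeLines(sprintf("%-2s % .12f % .12f % .12f", cf$elements,
                       cf$coords[, 1], cf$coords[, 2], cf$coords[, 3]), con)
  }
  invisible(path)
}

## ---- basis / model serialization ------------------------------------------

.typing_to_list <- function(typing) {
  list(classes = typing$classes,
       populations = as.list(typing$populations),
       formal_charge = typing$formal_charge,
       exponents = as.list(typing$exponents))
}
.typing_from_list <- function(x) {
  chm_typing(lapply(x$classes, as.integer),
             unlist(x$populations), x$formal_charge,
             unlist(x$exponents))
}

#' Write an invariant PIP basis to a JSON file
#'
#' Stores the canonical exponent vectors and the typing, so the basis can
#' be reloaded and evaluated without re-enumeration.
#'
#' @param basis a `chm_pip_basis`
#' @param typing the [chm_typing()] it was built with
#' @param path output file
#' @return `path`, invisibly
#' @export
write_basis <- function(basis, typing, path) {
  jsonlite::write_json(
    list(format = "chmpes-basis-1",
         M = basis$M,
         n_atoms = basis$n_atoms,
         includes_constant = basis$includes_constant,
         augmented = isTRUE(basis$augmented),
         typing = .typing_to_list(typing),
         terms = unname(as.matrix(basis$terms))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PIP basis written by [write_basis()]
#' @param path file path
#' @return list with `basis` (a `chm_pip_basis`) and `typing`
#' @export
read_basis <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "chmpes-basis-1")) stop("not a chmpes basis file")
  typing <- .typing_from_list(x$typing)
  group <- build_perm_group(typing, x$n_atoms)
  terms <- matrix(as.integer(x$terms), ncol = ncol(group$slot_action))
  basis <- structure(list(terms = terms, degree = rowSums(terms),
                          M = as.integer(x$M), n_atoms = x$n_atoms,
                          group = group,
                          includes_constant = x$includes_constant,
                          cache = new.env(parent = emptyenv())),
                     class = "chm_pip_basis")
  if (isTRUE(x$augmented)) basis$augmented <- TRUE
  list(basis = basis, typing = typing)
}

#' Write a fitted CHM model to a JSON file
#'
#' Captures the typing, PIP order and augmentation patterns, the
#' constant-term convention, all linear coefficients, the nonlinear
#' parameters, the energy offset, and provenance metadata.
#'
#' @param model a `chm_model`
#' @param path output file
#' @param provenance optional named list stored verbatim (dataset hash,
#'   seeds, timestamps)
#' @return `path`, invisibly
#' @export
write_model <- function(model, path, provenance = NULL) {
  bset <- model$bset
  jsonlite::write_json(
    list(format = "chmpes-model-1",
         typing = .typing_to_list(model$typing),
         M = bset$M,
         patterns = bset$patterns,
         convention = bset$convention,
         nlparams = model$nlparams[c("d0", "t0", "tau_rs")],
         alpha = as.list(model$nlparams$alpha),
         coeffs = model$coeffs,
         energy_offset = model$energy_offset,
         provenance = provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path file path
#' @return a `chm_model`
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "chmpes-model-1")) stop("not a chmpes model file")
  typing <- .typing_from_list(x$typing)
  patterns <- if (length(x$patterns)) {
    if (is.list(x$patterns)) lapply(x$patterns, as.integer)
    else list(as.integer(x$patterns))
  } else NULL
  bset <- chm_basis_set(typing, x$M, patterns, x$convention)
  nl <- chm_nlparams(d0 = x$nlparams$d0, t0 = x$nlparams$t0,
                     alpha = unlist(x$alpha), tau_rs = x$nlparams$tau_rs)
  coeffs <- list(atom = lapply(x$coeffs$atom, as.numeric),
                 pair = lapply(x$coeffs$pair, as.numeric),
                 corr = as.numeric(x$coeffs$corr))
  chm_model(bset, nl, coeffs, x$energy_offset)
}
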
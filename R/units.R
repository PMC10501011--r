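## Physical constants and unit conversions.  Coordinates are carried in
## Angstrom at the user level; integrals and dynamics work in atomic units.

#' Unit conversion constants
#'
#' Conversion factors used throughout the package: `bohr` (Angstrom per
#' bohr), `hartree_cm1` (cm^-1 per hartree), `amu_me` (electron masses per
#' unified atomic mass unit), `fs_au` (atomic time units per femtosecond),
#' `kcal_hartree` (hartree per kcal/mol).
#'
#' @format A named list of scalars.
#' @export
chm_units <- list(
  bohr        = 0.529177210903,     # Angstrom / bohr
  hartree_cm1 = 219474.6313632,     # cm^-1 / hartree
  amu_me      = 1822.888486209,     # m_e / u
  fs_au       = 1 / 0.02418884326509, # a.u. of time / fs
  kcal_hartree = 1 / 627.5094740631 # hartree / (kcal/mol)
)

ang2bohr <- function(x) x / chm_units$bohr
bohr2ang <- function(x) x * chm_units$bohr
hartree2cm <- function(x) x * chm_units$hartree_cm1
cm2hartree <- function(x) x / chm_units$hartree_cm1

## isotopically averaged atomic masses (u) for the elements exercised here
.atomic_masses <- c(H = 1.00782503207, He = 4.002602, C = 12.0,
                    N = 14.0030740048, O = 15.9949146196)

## nuclear charges
.atomic_numbers <- c(H = 1, He = 2, C = 6, N = 7, O = 8)

#' Nuclear charge of an element symbol
#' @param elements character vector of element symbols
#' @return integer vector of nuclear charges
#' @export
atomic_number <- function(elements) {
  z <- .atomic_numbers[elements]
  if (anyNA(z)) stop("unknown element symbol: ",
                     paste(elements[is.na(z)], collapse = ", "))
  unname(z)
}

#' Atomic mass of an element symbol
#' @param elements character vector of element symbols
#' @return masses in unified atomic mass units
#' @export
atomic_mass <- function(elements) {
  m <- .atomic_masses[elements]
  if (anyNA(m)) stop("unknown element symbol: ",
                     paste(elements[is.na(m)], collapse = ", "))
  unname(m)
}

#' Convert an energy between supported units
#'
#' @param x numeric energies
#' @param from,to one of `"hartree"`, `"cm-1"`, `"kcal/mol"`
#' @return converted energies
#' @export
convert_energy <- function(x, from = "hartree", to = "cm-1") {
  to_hartree <- switch(from,
    "hartree" = x,
    "cm-1" = cm2hartree(x),
    "kcal/mol" = x * chm_units$kcal_hartree,
    stop("unknown energy unit: ", from))
  switch(to,
    "hartree" = to_hartree,
    "cm-1" = hartree2cm(to_hartree),
    "kcal/mol" = to_hartree / chm_units$kcal_hartree,
    stop("unknown energy unit: ", to))
}
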
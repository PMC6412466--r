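# Physical constants and element tables.
# All internal quantities are in atomic units (bohr, hartree).

# CODATA 2014 Bohr radius in Angstrom.
BOHR_ANGSTROM <- 0.52917721067

#' Convert Angstrom to bohr
#' @param x length(s) in Angstrom
#' @return length(s) in bohr
#' @export
angstrom_to_bohr <- function(x) x / BOHR_ANGSTROM

# Element symbols indexed by atomic number (1..54).
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe")

#' Atomic number from element symbol
#' @param symbol element symbol(s), case-insensitive
#' @return integer atomic number(s)
#' @export
element_z <- function(symbol) {
  sym <- paste0(toupper(substr(symbol, 1, 1)), tolower(substring(symbol, 2)))
  z <- match(sym, .element_symbols)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(z)]), collapse = ", "))
  }
  as.integer(z)
}

# Bragg-Slater atomic radii in Angstrom (Slater 1964), used to scale the
# Euler-Maclaurin radial map. Hydrogen is set to 0.35 A, the value customary
# in molecular DFT quadrature rather than Slater's 0.25 A. Noble gases take
# the radius of the preceding halogen-row element.
.bragg_slater_A <- c(
  H = 0.35, He = 0.35, Li = 1.45, Be = 1.05, B = 0.85, C = 0.70,
  N = 0.65, O = 0.60, F = 0.50, Ne = 0.50, Na = 1.80, Mg = 1.50,
  Al = 1.25, Si = 1.10, P = 1.00, S = 1.00, Cl = 1.00, Ar = 1.00,
  K = 2.20, Ca = 1.80, Sc = 1.60, Ti = 1.40, V = 1.35, Cr = 1.40,
  Mn = 1.40, Fe = 1.40, Co = 1.35, Ni = 1.35, Cu = 1.35, Zn = 1.35,
  Ga = 1.30, Ge = 1.25, As = 1.15, Se = 1.15, Br = 1.15, Kr = 1.15,
  Rb = 2.35, Sr = 2.00, Y = 1.80, Zr = 1.55, Nb = 1.45, Mo = 1.45,
  Tc = 1.35, Ru = 1.30, Rh = 1.35, Pd = 1.40, Ag = 1.60, Cd = 1.55,
  In = 1.55, Sn = 1.45, Sb = 1.45, Te = 1.40, I = 1.40, Xe = 1.40)

#' Bragg-Slater radius of an element in bohr
#'
#' @param element element symbol
#' @param fallback optional radius in bohr returned for elements absent from
#'   the table; by default an unknown element is an error.
#' @return radius in bohr
#' @export
bragg_slater_radius <- function(element, fallback = NULL) {
  r <- .bragg_slater_A[element]
  if (anyNA(r)) {
    if (is.null(fallback)) {
      stop("no Bragg-Slater radius for element: ",
           paste(element[is.na(r)], collapse = ", "),
           " (supply `fallback` to override)")
    }
    r[is.na(r)] <- fallback * BOHR_ANGSTROM
  }
  unname(r) / BOHR_ANGSTROM
}

# Covalent radii in Angstrom (Cordero et al. 2008); high-spin values for
# Mn/Fe/Co. Used only for the optional fragment-completion step of the
# QM-region suggestion.
.covalent_A <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76,
  N = 0.71, O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41,
  Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06,
  K = 2.03, Ca = 1.76, Sc = 1.70, Ti = 1.60, V = 1.53, Cr = 1.39,
  Mn = 1.61, Fe = 1.52, Co = 1.50, Ni = 1.24, Cu = 1.32, Zn = 1.22,
  Ga = 1.22, Ge = 1.20, As = 1.19, Se = 1.20, Br = 1.20, Kr = 1.16,
  I = 1.39)

#' Covalent radius of an element in bohr
#' @param element element symbol
#' @return radius in bohr
#' @export
covalent_radius <- function(element) {
  r <- .covalent_A[element]
  if (anyNA(r)) {
    stop("no covalent radius tabulated for element: ",
         paste(element[is.na(r)], collapse = ", "))
  }
  unname(r) / BOHR_ANGSTROM
}
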
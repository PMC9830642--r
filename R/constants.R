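# Single source of truth for unit conversions used across the package.
# Energies are carried in Hartree, coordinates in Angstrom at the interfaces,
# dipoles in Debye; engines work in atomic units internally.

.oef <- list(
  debye_to_au      = 0.3934303,     # 1 Debye in atomic units of dipole
  hartree_to_kcal  = 627.5095,      # 1 Hartree in kcal/mol
  bohr_to_angstrom = 0.52917721067, # CODATA bohr radius, Angstrom
  angstrom_to_bohr = 1 / 0.52917721067
)

#' Unit-conversion constants
#'
#' Returns the package-wide table of physical conversion factors. Every unit
#' conversion in the package goes through this table so that, e.g., the
#' Debye-to-atomic-unit factor used by the first-order barrier estimate is
#' identical to the one used by the toy engine.
#'
#' @return Named list with elements `debye_to_au` (a.u. dipole per Debye),
#'   `hartree_to_kcal` (kcal/mol per Hartree), `bohr_to_angstrom` and
#'   `angstrom_to_bohr`.
#' @examples
#' oef_constants()$hartree_to_kcal
#' @export
oef_constants <- function() .oef

# Recognized element symbols (IUPAC 1..118), indexed by atomic number.
.elements <- c(
  "H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P","S",
  "Cl","Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn","Ga",
  "Ge","As","Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc","Ru","Rh","Pd",
  "Ag","Cd","In","Sn","Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd","Pm",
  "Sm","Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu","Hf","Ta","W","Re","Os",
  "Ir","Pt","Au","Hg","Tl","Pb","Bi","Po","At","Rn","Fr","Ra","Ac","Th","Pa",
  "U","Np","Pu","Am","Cm","Bk","Cf","Es","Fm","Md","No","Lr","Rf","Db","Sg",
  "Bh","Hs","Mt","Ds","Rg","Cn","Nh","Fl","Mc","Lv","Ts","Og"
)

#' Element symbol / atomic number lookup
#'
#' @param x Character vector of element symbols or integer vector of atomic
#'   numbers.
#' @return For symbols, the atomic numbers; for numbers, the symbols.
#' @export
element_number <- function(x) {
  z <- match(x, .elements)
  if (anyNA(z)) {
    stop("unrecognized element symbol(s): ",
         paste(unique(x[is.na(z)]), collapse = ", "))
  }
  z
}

#' @rdname element_number
#' @export
element_symbol <- function(x) {
  x <- as.integer(x)
  if (any(is.na(x)) || any(x < 1L) || any(x > length(.elements))) {
    stop("atomic number out of range")
  }
  .elements[x]
}
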
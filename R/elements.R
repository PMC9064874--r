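# Element symbols indexed by atomic number, H (1) through Mt (109).
.element_symbols <- c(
  "H",  "He", "Li", "Be", "B",  "C",  "N",  "O",  "F",  "Ne",
  "Na", "Mg", "Al", "Si", "P",  "S",  "Cl", "Ar", "K",  "Ca",
  "Sc", "Ti", "V",  "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y",  "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I",  "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W",  "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U",  "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt"
)

#' Atomic number of an element symbol
#'
#' Recognizes elements 1 (H) through 109 (Mt). Matching is case sensitive in
#' the conventional way (`"He"`, not `"HE"`).
#'
#' @param symbol Character vector of element symbols.
#' @return Integer vector of atomic numbers.
#' @examples
#' atomic_number(c("H", "C", "Sr"))
#' @export
atomic_number <- function(symbol) {
  z <- match(symbol, .element_symbols)
  if (anyNA(z)) {
    bad <- unique(symbol[is.na(z)])
    stop("invalid-element: unknown element symbol(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  z
}

# Bohr per Angstrom (CODATA).
.bohr_per_angstrom <- 1.8897259886
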
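# Element data used across the package.
#
# Atomic masses: IUPAC 2021 standard atomic weights (abridged to 4 decimals).
# Van der Waals radii: Bondi (1964) compilation, Angstrom; elements absent
# from Bondi's table fall back to 2.0 A, a common generic heavy-atom radius.

.ELEMENT_MASS <- c(
  H = 1.008,  B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.086, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38, Se = 78.971,
  Br = 79.904, I = 126.904
)

.VDW_RADIUS <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  Cl = 1.75, Br = 1.85, I = 1.98, Se = 1.90, Si = 2.10, B = 1.92,
  Na = 2.27, Mg = 1.73, K = 2.75, Ca = 2.31, Zn = 1.39, Fe = 2.00
)

.HALOGENS <- c("F", "Cl", "Br", "I")

# Default valences used to infer implicit hydrogen counts on ligand graphs
# (neutral atoms; +1 N gets 4, -1 O gets 1).
.DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                      F = 1, Cl = 1, Br = 1, I = 1, B = 3, Se = 2, Si = 4, H = 1)

#' Standard atomic mass of an element
#'
#' @param element Character vector of element symbols (e.g. `"C"`, `"Cl"`).
#' @return Numeric vector of atomic masses in Dalton.
#' @examples
#' atomic_mass(c("C", "O", "H"))
#' @export
atomic_mass <- function(element) {
  m <- .ELEMENT_MASS[normalize_element(element)]
  if (anyNA(m)) vs_stop("unknown element(s): %s",
                        paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Bondi van der Waals radius of an element
#'
#' Elements not in Bondi's compilation get a generic 2.0 Angstrom radius.
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @examples
#' vdw_radius(c("C", "N"))
#' @export
vdw_radius <- function(element) {
  r <- .VDW_RADIUS[normalize_element(element)]
  r[is.na(r)] <- 2.0
  unname(r)
}

# "CL" -> "Cl", "c" -> "C" etc.; leaves unknown strings as-is for the caller
# to reject or map to the "other" channel.
normalize_element <- function(element) {
  e <- as.character(element)
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e))))
}
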
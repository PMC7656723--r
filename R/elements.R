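#' Single-bond covalent radii
#'
#' Covalent radii (in Angstrom) used by the geometric bond-perception rule.
#' Values follow the widely used single-bond compilation of Cordero et al.
#' for the elements that occur in drug-like molecules; the table can be
#' overridden per call (see [covalent_radius_table()]).
#'
#' @format Named numeric vector, element symbol -> radius in Angstrom.
#' @keywords internal
.covalent_radii <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Na = 1.66, Mg = 1.41, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  K = 2.03, Ca = 1.76, Mn = 1.39, Fe = 1.32, Co = 1.26, Ni = 1.24,
  Cu = 1.32, Zn = 1.22, Se = 1.20, Br = 1.20, I = 1.39
)

.known_elements <- c(
  names(.covalent_radii),
  "He", "Li", "Be", "Ne", "Al", "Ar", "Sc", "Ti", "V", "Cr", "Ga",
  "Ge", "As", "Kr", "Rb", "Sr", "Mo", "Ru", "Rh", "Pd", "Ag", "Cd",
  "Sn", "Sb", "Te", "Xe", "Cs", "Ba", "W", "Pt", "Au", "Hg", "Pb", "Bi"
)

.atomic_numbers <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9,
  Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16,
  Cl = 17, Ar = 18, K = 19, Ca = 20, Mn = 25, Fe = 26, Co = 27,
  Ni = 28, Cu = 29, Zn = 30, As = 33, Se = 34, Br = 35, I = 53
)

#' Normalise an element symbol ("CL" -> "Cl")
#' @keywords internal
normalize_element <- function(sym) {
  sym <- gsub("[^A-Za-z]", "", sym)
  out <- ifelse(nchar(sym) == 0, NA_character_,
                paste0(toupper(substr(sym, 1, 1)),
                       tolower(substr(sym, 2, nchar(sym)))))
  out
}

#' Infer the element from a PDB atom-name field
#'
#' Docking outputs frequently leave PDB columns 77-78 blank, so the element
#' must be recovered from the atom name. PDB convention: the element is
#' right-justified in columns 13-14 of the name field, so a name starting in
#' column 13 with a two-letter element ("CL", "BR", "FE") encodes that
#' element, while names starting in column 14 ("CA", "CB", "N") are
#' single-letter elements with remoteness suffixes. AutoDock atom types
#' ("OA", "NA", "HD") reduce to their leading element.
#'
#' @param name atom-name string, raw (possibly padded) or stripped.
#' @param raw_field the untrimmed 4-character name field if available; used
#'   to detect left-justified two-letter elements.
#' @return element symbol or `NA` when the name is uninformative.
#' @keywords internal
element_from_name <- function(name, raw_field = NULL) {
  nm <- toupper(trimws(name))
  if (nchar(nm) == 0L) return(NA_character_)
  two <- normalize_element(substr(nm, 1, 2))
  one <- normalize_element(substr(nm, 1, 1))
  # a name occupying column 13 (no leading space in the raw field) with a
  # recognised two-letter element is that element: "CL1 ", "FE  "
  if (!is.null(raw_field) && nchar(raw_field) >= 1 &&
      substr(raw_field, 1, 1) != " " &&
      !is.na(two) && two %in% .known_elements && !(two %in% c("Ca", "Cd", "Co", "Cs", "Na", "Ne", "Ni"))) {
    return(two)
  }
  if (!is.na(one) && one %in% .known_elements) return(one)
  # leading digits (hydrogens like "1HB")
  stripped <- sub("^[0-9]+", "", nm)
  one <- normalize_element(substr(stripped, 1, 1))
  if (!is.na(one) && one %in% .known_elements) return(one)
  NA_character_
}
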
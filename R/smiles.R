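# A compact parser for linear molecular notations. One scanning core
# handles both SMILES templates and SMARTS patterns: branches, ring
# closures (including %nn), explicit bond symbols, bracket atoms, and the
# organic subset with aromatic lowercase forms. The supported subset is
# what docked-pose filters actually use; stereo marks are accepted and
# ignored, and unsupported constructs fail loudly at parse time.

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.aromatic_organic <- c("b", "c", "n", "o", "p", "s")

# scan a SMILES/SMARTS string into atoms + symbolic bonds.
# atom_parser(token, bracket) -> atom spec (any R object).
scan_linear_notation <- function(s, atom_parser) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  atoms <- list()
  bonds <- data.frame(i = integer(), j = integer(), sym = character(),
                      stringsAsFactors = FALSE)
  prev <- 0L                 # atom index the next atom bonds to; 0 = none
  pending <- "default"
  stack <- integer()
  rings <- list()            # ring-closure digit -> c(atom, bondsym)
  add_bond <- function(i, j, sym) {
    bonds[nrow(bonds) + 1L, ] <<- list(i, j, sym)
  }
  k <- 1L
  while (k <= n) {
    ch <- chars[k]
    if (ch %in% c("-", "=", "#", ":", "~", "/", "\\")) {
      pending <- if (ch %in% c("/", "\\")) "-" else ch
      k <- k + 1L
    } else if (ch == ".") {
      prev <- 0L; pending <- "default"; k <- k + 1L
    } else if (ch == "(") {
      if (prev == 0L) stop("branch before any atom in '", s, "'")
      stack <- c(stack, prev); k <- k + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in '", s, "'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      k <- k + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (k + 2L > n) stop("truncated %nn ring closure in '", s, "'")
        lab <- paste0(chars[k + 1L], chars[k + 2L]); k <- k + 3L
      } else { lab <- ch; k <- k + 1L }
      if (prev == 0L) stop("ring closure before any atom in '", s, "'")
      if (!is.null(rings[[lab]])) {
        other <- rings[[lab]]
        sym <- if (!identical(pending, "default")) pending
        else if (!identical(other$sym, "default")) other$sym
        else "default"
        add_bond(other$atom, prev, sym)
        rings[[lab]] <- NULL
      } else {
        rings[[lab]] <- list(atom = prev, sym = pending)
      }
      pending <- "default"
    } else if (ch == "[") {
      close <- k
      while (close <= n && chars[close] != "]") close <- close + 1L
      if (close > n) stop("unbalanced '[' in '", s, "'")
      token <- paste(chars[(k + 1L):(close - 1L)], collapse = "")
      atoms[[length(atoms) + 1L]] <- atom_parser(token, bracket = TRUE)
      idx <- length(atoms)
      if (prev > 0L) add_bond(prev, idx, pending)
      prev <- idx; pending <- "default"
      k <- close + 1L
    } else if (grepl("[A-Za-z*]", ch)) {
      token <- ch
      if (ch %in% c("C", "B") && k < n && chars[k + 1L] %in% c("l", "r")) {
        cand <- paste0(ch, chars[k + 1L])
        if (cand %in% .organic_subset) { token <- cand; k <- k + 1L }
      }
      atoms[[length(atoms) + 1L]] <- atom_parser(token, bracket = FALSE)
      idx <- length(atoms)
      if (prev > 0L) add_bond(prev, idx, pending)
      prev <- idx; pending <- "default"
      k <- k + 1L
    } else {
      stop("unexpected character '", ch, "' in '", s, "'")
    }
  }
  if (length(stack)) stop("unbalanced '(' in '", s, "'")
  if (length(rings)) stop("unclosed ring bond in '", s, "'")
  if (length(atoms) == 0L) stop("no atoms in '", s, "'")
  list(atoms = atoms, bonds = bonds)
}

smiles_atom_parser <- function(token, bracket) {
  if (bracket) {
    # strip isotope, chirality, H-count, charge, atom-class: keep symbol
    m <- regmatches(token, regexec("^[0-9]*([A-Za-z][a-z]?)", token))[[1]]
    if (length(m) < 2L) stop("cannot parse bracket atom '[", token, "]'")
    sym <- m[2]
    if (identical(sym, "H") && grepl("^[0-9]*H", token)) {
      return(list(element = "H", aromatic = FALSE))
    }
  } else sym <- token
  aromatic <- sym %in% .aromatic_organic
  element <- if (aromatic) normalize_element(sym) else sym
  if (!bracket && !aromatic && !(sym %in% .organic_subset))
    stop("'", sym, "' is not in the SMILES organic subset; use brackets")
  element <- normalize_element(element)
  if (is.na(element) || !(element %in% .known_elements))
    stop("unknown element '", sym, "' in SMILES")
  list(element = element, aromatic = aromatic)
}

#' Parse a SMILES string into a template molecular graph
#'
#' Supports the organic subset, aromatic lowercase atoms, bracket atoms
#' (isotope, H-count, charge and chirality are accepted and ignored),
#' branches, explicit bond symbols, and ring closures. Implicit hydrogens
#' are not materialised: the template is used for heavy-atom connectivity
#' and bond orders only.
#'
#' @param smiles SMILES string, e.g. `"c1ccccc1"` or `"NCCO"`.
#' @return list with `element` (character vector), `aromatic` (logical
#'   vector), `bonds` (data.frame `i`, `j`, `order`).
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  parsed <- scan_linear_notation(trimws(smiles), smiles_atom_parser)
  element <- vapply(parsed$atoms, `[[`, character(1), "element")
  aromatic <- vapply(parsed$atoms, `[[`, logical(1), "aromatic")
  b <- parsed$bonds
  order <- character(nrow(b))
  for (k in seq_len(nrow(b))) {
    order[k] <- switch(b$sym[k],
                       "-" = "single", "=" = "double", "#" = "triple",
                       ":" = "aromatic",
                       "default" = if (aromatic[b$i[k]] && aromatic[b$j[k]])
                         "aromatic" else "single",
                       stop("bond symbol '", b$sym[k],
                            "' is not valid in SMILES"))
  }
  bonds <- data.frame(i = b$i, j = b$j, order = order,
                      stringsAsFactors = FALSE)
  list(element = element, aromatic = aromatic, bonds = bonds)
}
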
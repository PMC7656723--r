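# SMARTS pattern compilation and subgraph matching. The engine needs the
# *atom indices* of every substructure embedding (distances to the query
# point are measured from them), so matching is done here by explicit
# backtracking over the pose's molecular graph.
#
# Supported SMARTS subset: organic-subset atoms (C, N, O, ... aliphatic;
# c, n, o, ... aromatic), "*", bracket atoms with atomic-number primitives
# ("#7"), element symbols, "a"/"A", negation "!", conjunction "&" and ";"
# and disjunction "," at the usual precedences; bond symbols "-", "=",
# "#", ":", "~" and the default single-or-aromatic bond; branches and ring
# closures. Recursive SMARTS, charge/valence/degree primitives and
# disconnected (dot-separated) patterns are rejected at parse time.

smarts_primitive <- function(tok) {
  neg <- FALSE
  if (startsWith(tok, "!")) { neg <- TRUE; tok <- substring(tok, 2) }
  if (!nzchar(tok)) stop("empty SMARTS primitive")
  spec <-
    if (tok == "*") list(kind = "any")
    else if (tok == "A") list(kind = "aliphatic")
    else if (tok == "a") list(kind = "aromatic")
    else if (grepl("^#[0-9]+$", tok)) {
      z <- as.integer(substring(tok, 2))
      el <- names(.atomic_numbers)[match(z, .atomic_numbers)]
      if (is.na(el)) stop("unsupported atomic number #", z, " in SMARTS")
      list(kind = "element_any", element = el)
    } else if (grepl("^[A-Z][a-z]?$", tok)) {
      el <- normalize_element(tok)
      if (!(el %in% .known_elements))
        stop("unknown element '", tok, "' in SMARTS")
      list(kind = "element_aliphatic", element = el)
    } else if (grepl("^[a-z]$", tok) && tok %in% .aromatic_organic) {
      list(kind = "element_aromatic", element = normalize_element(tok))
    } else {
      stop("unsupported SMARTS primitive '", tok, "'")
    }
  spec$neg <- neg
  spec
}

smarts_atom_parser <- function(token, bracket) {
  if (!bracket) {
    if (!(token == "*" || token %in% .organic_subset ||
            token %in% .aromatic_organic))
      stop("atom '", token, "' must be written in brackets in SMARTS")
    return(structure(list(list(list(smarts_primitive(token)))),
                     conj = TRUE))
  }
  if (grepl("\\$", token)) stop("recursive SMARTS are not supported")
  # precedence: ';' (AND, low) over ',' (OR) over '&' (AND, high)
  groups <- list()
  for (part in strsplit(token, ";", fixed = TRUE)[[1]]) {
    alts <- strsplit(part, ",", fixed = TRUE)[[1]]
    groups[[length(groups) + 1L]] <-
      lapply(alts, function(alt) {
        prims <- strsplit(alt, "&", fixed = TRUE)[[1]]
        lapply(prims, smarts_primitive)
      })
  }
  # flatten: each ';' part is a list of OR-alternatives whose members are
  # AND-lists; overall atom spec = AND over parts
  structure(groups, conj = TRUE)
}

primitive_matches <- function(p, element, aromatic) {
  hit <- switch(p$kind,
                any = TRUE,
                aliphatic = !aromatic,
                aromatic = aromatic,
                element_any = element == p$element,
                element_aliphatic = element == p$element && !aromatic,
                element_aromatic = element == p$element && aromatic)
  if (p$neg) !hit else hit
}

atom_spec_matches <- function(spec, element, aromatic) {
  for (part in spec) {
    ok <- FALSE
    for (alt in part) {
      if (all(vapply(alt, primitive_matches, logical(1), element, aromatic))) {
        ok <- TRUE; break
      }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Compile a SMARTS pattern
#'
#' @param smarts pattern string, e.g. `"[#7,#8]"`, `"cc"`, `"C1OCCCC1"`.
#' @return object of class `smarts_pattern`.
#' @seealso [match_substructure()]
#' @export
parse_smarts <- function(smarts) {
  stopifnot(is.character(smarts), length(smarts) == 1L, nzchar(smarts))
  if (grepl(".", smarts, fixed = TRUE))
    stop("disconnected (dot-separated) SMARTS are not supported")
  parsed <- scan_linear_notation(trimws(smarts), smarts_atom_parser)
  np <- length(parsed$atoms)
  # matching requires every atom after the first to touch an earlier atom
  if (np > 1L) {
    reached <- c(TRUE, rep(FALSE, np - 1L))
    for (k in 2:np) {
      nb <- c(parsed$bonds$i[parsed$bonds$j == k],
              parsed$bonds$j[parsed$bonds$i == k])
      if (any(nb < k)) reached[k] <- TRUE
    }
    if (!all(reached)) stop("SMARTS pattern must be connected: ", smarts)
  }
  structure(list(atoms = parsed$atoms, bonds = parsed$bonds,
                 source = smarts),
            class = "smarts_pattern")
}

#' @export
print.smarts_pattern <- function(x, ...) {
  cat(sprintf("SMARTS pattern '%s': %d atoms, %d bonds\n", x$source,
              length(x$atoms), nrow(x$bonds)))
  invisible(x)
}

bond_sym_matches <- function(sym, order) {
  switch(sym,
         "default" = order %in% c("single", "aromatic"),
         "-" = order == "single",
         "=" = order == "double",
         "#" = order == "triple",
         ":" = order == "aromatic",
         "~" = TRUE,
         stop("unsupported SMARTS bond symbol '", sym, "'"))
}

#' Aromatic flags of a molecular graph's atoms
#'
#' An atom is aromatic when it participates in at least one aromatic bond.
#' Geometric single-bond graphs therefore have no aromatic atoms, which is
#' exactly why aromatic SMARTS cannot match under NONE-mode perception.
#' @param graph a `MolecularGraph`.
#' @return logical vector over atoms.
#' @keywords internal
graph_aromatic_flags <- function(graph) {
  arom <- rep(FALSE, nrow(graph$atoms))
  ab <- graph$bonds[graph$bonds$order == "aromatic", , drop = FALSE]
  arom[unique(c(ab$i, ab$j))] <- TRUE
  arom
}

#' Find all embeddings of a SMARTS pattern in a molecular graph
#'
#' Backtracking subgraph matching: an embedding assigns each pattern atom
#' to a distinct molecule atom such that every atom primitive and every
#' pattern bond (including the implicit single-or-aromatic default bond)
#' is satisfied. Embeddings that use the same atom set (automorphic
#' images) are collapsed to one.
#'
#' @param graph a `MolecularGraph` with bonds assigned (any provenance).
#' @param smarts a pattern string or compiled `smarts_pattern`.
#' @return list of integer vectors (sorted atom-index sets), empty when no
#'   embedding exists.
#' @examples
#' # "[#7,#8]" on a graph with two N and one O yields three 1-atom matches
#' @export
match_substructure <- function(graph, smarts) {
  stopifnot(inherits(graph, "MolecularGraph"))
  pat <- if (inherits(smarts, "smarts_pattern")) smarts
  else parse_smarts(smarts)
  mol_elem <- graph$atoms$element
  arom <- graph_aromatic_flags(graph)
  nm <- length(mol_elem)
  np <- length(pat$atoms)
  if (np > nm) return(list())
  order_tab <- matrix(NA_character_, nm, nm)
  if (nrow(graph$bonds)) {
    order_tab[cbind(graph$bonds$i, graph$bonds$j)] <- graph$bonds$order
    order_tab[cbind(graph$bonds$j, graph$bonds$i)] <- graph$bonds$order
  }
  # candidate molecule atoms per pattern atom
  cands <- lapply(pat$atoms, function(spec)
    which(vapply(seq_len(nm), function(m)
      atom_spec_matches(spec, mol_elem[m], arom[m]), logical(1))))
  pb <- pat$bonds
  earlier <- lapply(seq_len(np), function(k) {
    sel <- (pb$i == k & pb$j < k) | (pb$j == k & pb$i < k)
    if (!any(sel)) return(NULL)
    data.frame(other = ifelse(pb$i[sel] == k, pb$j[sel], pb$i[sel]),
               sym = pb$sym[sel], stringsAsFactors = FALSE)
  })
  found <- list()
  assign <- integer(np)
  used <- logical(nm)
  recurse <- function(k) {
    if (k > np) {
      found[[length(found) + 1L]] <<- sort(assign)
      return(invisible(NULL))
    }
    for (cand in cands[[k]]) {
      if (used[cand]) next
      req <- earlier[[k]]
      ok <- TRUE
      if (!is.null(req)) {
        for (q in seq_len(nrow(req))) {
          o <- order_tab[assign[req$other[q]], cand]
          if (is.na(o) || !bond_sym_matches(req$sym[q], o)) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      assign[k] <<- cand; used[cand] <<- TRUE
      recurse(k + 1L)
      used[cand] <<- FALSE
    }
    invisible(NULL)
  }
  recurse(1L)
  unique(found)
}
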
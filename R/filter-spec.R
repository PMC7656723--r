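# The JSON filters file: a list of filters, each combining a SMARTS
# substructure, a 3D query point (literal "coordinate" or a "receptorAtom"
# selector), a "distance" cutoff in Angstrom, and an optional "exclude"
# flag. Key names follow the published schema verbatim so existing filter
# files work unchanged.

.filter_keys <- c("smarts", "coordinate", "receptorAtom", "distance",
                  "exclude")
.receptor_atom_keys <- c("chain", "resid", "atomname")

#' Load and validate a JSON filters file
#'
#' Each entry must carry `"smarts"`, exactly one of `"coordinate"` (an
#' `[x, y, z]` triple in Angstrom) or `"receptorAtom"` (object with
#' `"chain"`, `"resid"`, `"atomname"`), a positive `"distance"` cutoff,
#' and optionally `"exclude"`. Unknown keys, malformed entries, invalid
#' SMARTS and non-positive cutoffs are fatal, naming the offending filter
#' index. An empty list is legal: the conjunction over zero filters is
#' vacuously true and every parseable compound passes.
#'
#' @param path path to the JSON filters file.
#' @return list of `FilterDefinition` objects (fields `smarts`, `pattern`,
#'   `coordinate` or `receptor_atom`, `cutoff`, `exclude`).
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeLines('[{"smarts": "[#7,#8]",
#'   "receptorAtom": {"chain": "A", "resid": 863, "atomname": "CA"},
#'   "distance": 5.5}]', f)
#' load_filters(f)
#' @export
load_filters <- function(path) {
  if (!file.exists(path)) stop("filters file not found: ", path)
  defs <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in filters file: ",
                             conditionMessage(e), call. = FALSE))
  if (!is.list(defs))
    stop("filters file must contain a JSON list of filters")
  lapply(seq_along(defs), function(ix) {
    d <- defs[[ix]]
    where <- sprintf("filter #%d", ix)
    if (!is.list(d)) stop(where, ": each filter must be a JSON object")
    bad <- setdiff(names(d), .filter_keys)
    if (length(bad))
      stop(where, ": unknown key(s): ", paste(bad, collapse = ", "))
    if (is.null(d$smarts) || !is.character(d$smarts[[1]]))
      stop(where, ": missing required key 'smarts'")
    has_coord <- !is.null(d$coordinate)
    has_ratom <- !is.null(d$receptorAtom)
    if (has_coord == has_ratom)
      stop(where, ": exactly one of 'coordinate' or 'receptorAtom' ",
           "must be given")
    if (is.null(d$distance)) stop(where, ": missing required key 'distance'")
    cutoff <- suppressWarnings(as.numeric(d$distance[[1]]))
    if (is.na(cutoff) || cutoff <= 0)
      stop(where, ": 'distance' must be a positive number")
    pattern <- tryCatch(parse_smarts(d$smarts[[1]]), error = function(e)
      stop(where, ": invalid SMARTS '", d$smarts[[1]], "': ",
           conditionMessage(e), call. = FALSE))
    out <- list(smarts = d$smarts[[1]], pattern = pattern, cutoff = cutoff,
                exclude = isTRUE(unlist(d$exclude)[1]))
    if (has_coord) {
      coord <- suppressWarnings(as.numeric(unlist(d$coordinate)))
      if (length(coord) != 3L || anyNA(coord) || !all(is.finite(coord)))
        stop(where, ": 'coordinate' must be a finite [x, y, z] triple")
      out$coordinate <- coord
    } else {
      ra <- d$receptorAtom
      miss <- setdiff(.receptor_atom_keys, names(ra))
      if (length(miss))
        stop(where, ": 'receptorAtom' missing key(s): ",
             paste(miss, collapse = ", "))
      out$receptor_atom <- list(chain = as.character(ra$chain[[1]]),
                                resid = as.integer(ra$resid[[1]]),
                                atomname = as.character(ra$atomname[[1]]))
    }
    structure(out, class = "FilterDefinition")
  })
}

#' @export
print.FilterDefinition <- function(x, ...) {
  qp <- if (!is.null(x$coordinate))
    sprintf("coordinate (%.2f, %.2f, %.2f)", x$coordinate[1],
            x$coordinate[2], x$coordinate[3])
  else sprintf("receptorAtom (%s, %d, %s)", x$receptor_atom$chain,
               x$receptor_atom$resid, x$receptor_atom$atomname)
  cat(sprintf("Filter: smarts '%s' within %.2f A of %s%s\n", x$smarts,
              x$cutoff, qp, if (x$exclude) " [exclude]" else ""))
  invisible(x)
}

#' Serialise filter definitions back to the JSON schema
#'
#' Inverse of [load_filters()]; loading the serialised output yields the
#' same definitions (schema round-trip).
#'
#' @param filters list of `FilterDefinition`.
#' @param path destination JSON file.
#' @return `path`, invisibly.
#' @export
write_filters <- function(filters, path) {
  out <- lapply(filters, function(f) {
    d <- list(smarts = f$smarts)
    if (!is.null(f$coordinate)) d$coordinate <- f$coordinate
    else d$receptorAtom <- list(chain = f$receptor_atom$chain,
                                resid = f$receptor_atom$resid,
                                atomname = f$receptor_atom$atomname)
    d$distance <- f$cutoff
    if (f$exclude) d$exclude <- TRUE
    d
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Resolve a filter's query point to concrete coordinates
#'
#' Coordinate filters copy their triple verbatim; receptor-atom filters
#' anchor to the matched atom's coordinates via [select_atom()], which
#' fails fast (before any pose is evaluated) if the selector does not
#' resolve to exactly one atom.
#'
#' @param f a `FilterDefinition`.
#' @param receptor a `Receptor`; required only for receptorAtom filters.
#' @return `ResolvedFilter`: fields `smarts`, `pattern`, `query_point`,
#'   `cutoff`, `exclude`, `label`.
#' @export
resolve_query_point <- function(f, receptor = NULL) {
  stopifnot(inherits(f, "FilterDefinition"))
  if (!is.null(f$coordinate)) {
    qp <- f$coordinate
    label <- sprintf("%s@coord(%.2f,%.2f,%.2f)", f$smarts, qp[1], qp[2], qp[3])
  } else {
    if (is.null(receptor))
      stop("a receptor is required to resolve receptorAtom filters")
    atom <- select_atom(receptor, f$receptor_atom$chain,
                        f$receptor_atom$resid, f$receptor_atom$atomname)
    qp <- c(atom$x, atom$y, atom$z)
    label <- sprintf("%s@%s:%d:%s", f$smarts, f$receptor_atom$chain,
                     f$receptor_atom$resid, f$receptor_atom$atomname)
  }
  structure(list(smarts = f$smarts, pattern = f$pattern, query_point = qp,
                 cutoff = f$cutoff, exclude = f$exclude, label = label),
            class = "ResolvedFilter")
}

#' Warn about SMARTS/mode combinations that cannot work as intended
#'
#' Under NONE mode, PDB/PDBQT poses get single-bond-only graphs, so a
#' SMARTS with aromatic or higher-order bonds (or aromatic atoms) can
#' never match; that combination draws a warning. SMILES and OPENBABEL
#' modes are advisory-warned for SDF inputs, whose files already carry
#' bond orders. Warnings never stop the run.
#'
#' @param f a `FilterDefinition`.
#' @param mode `"NONE"`, `"SMILES"`, or `"OPENBABEL"`.
#' @param formats_present character subset of `c("PDB", "PDBQT", "SDF")`.
#' @return character vector of warning messages (also emitted via
#'   `warning()`), possibly empty.
#' @export
validate_smarts_for_mode <- function(f, mode, formats_present) {
  mode <- match.arg(mode, c("NONE", "SMILES", "OPENBABEL"))
  warns <- character()
  needs_orders <- smarts_needs_bond_orders(f$pattern)
  if (identical(mode, "NONE") && needs_orders &&
      any(c("PDB", "PDBQT") %in% formats_present)) {
    warns <- c(warns, sprintf(
      paste0("SMARTS '%s' requires aromatic or higher-order bonds, but ",
             "NONE mode assigns only single bonds to PDB/PDBQT poses; ",
             "it can never match those files. Use SMILES or OPENBABEL ",
             "mode."), f$smarts))
  }
  if (mode %in% c("SMILES", "OPENBABEL") && "SDF" %in% formats_present) {
    warns <- c(warns, sprintf(
      paste0("%s mode is not needed for SDF files, which already carry ",
             "bond orders; their bond blocks are used directly."), mode))
  }
  for (w in warns) warning(w, call. = FALSE)
  invisible(warns)
}

# does the pattern reference aromaticity or bond orders beyond single?
smarts_needs_bond_orders <- function(pattern) {
  if (any(pattern$bonds$sym %in% c("=", "#", ":"))) return(TRUE)
  for (spec in pattern$atoms) {
    for (part in spec) for (alt in part) for (p in alt) {
      if (p$kind %in% c("aromatic", "element_aromatic") && !p$neg)
        return(TRUE)
    }
  }
  FALSE
}
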
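# Readers and writers for the three docked-pose formats (PDBQT, PDB, SDF)
# and for PDB/PDBQT receptors. The PDB/PDBQT parser is fixed-column and
# deliberately forgiving: docking pipelines emit many dialect variations.

# AutoDock atom types (PDBQT columns 78-79) -> element.
.autodock_types <- c(
  A = "C", C = "C", N = "N", NA. = "N", NS = "N", OA = "O", OS = "O",
  O = "O", S = "S", SA = "S", H = "H", HD = "H", HS = "H", P = "P",
  F = "F", CL = "Cl", BR = "Br", I = "I", MG = "Mg", MN = "Mn",
  ZN = "Zn", FE = "Fe", CA = "Ca"
)

empty_atom_table <- function() {
  data.frame(serial = integer(), name = character(), element = character(),
             x = numeric(), y = numeric(), z = numeric(),
             chain = character(), resid = integer(), resname = character(),
             is_hydrogen = logical(), stringsAsFactors = FALSE)
}

#' Parse the ATOM/HETATM records of a PDB or PDBQT file
#'
#' @param lines character vector of file lines.
#' @param pdbqt whether to interpret AutoDock type columns.
#' @return list(atoms = data.frame, warnings = character())
#' @keywords internal
parse_pdb_atoms <- function(lines, pdbqt = FALSE) {
  warns <- character()
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM") |
                  trimws(rec) %in% c("ATOM", "HETATM"))
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- lines[keep[k]]
    if (nchar(ln) < 54) {
      warns <- c(warns, sprintf("skipping short atom record: '%s'", ln))
      next
    }
    x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    if (anyNA(c(x, y, z)) || !all(is.finite(c(x, y, z)))) {
      warns <- c(warns, sprintf("malformed coordinates, line skipped: '%s'", ln))
      next
    }
    serial <- suppressWarnings(as.integer(trimws(substr(ln, 7, 11))))
    raw_name <- substr(ln, 13, 16)
    name <- trimws(raw_name)
    resname <- trimws(substr(ln, 18, 20))
    chain <- trimws(substr(ln, 22, 22))
    resid <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
    elem_field <- if (nchar(ln) >= 78) trimws(substr(ln, 77, 78)) else ""
    element <- NA_character_
    if (pdbqt) {
      # PDBQT: columns 78-79 carry the AutoDock atom type
      type_field <- if (nchar(ln) >= 78) trimws(substr(ln, 78, 79)) else ""
      key <- if (identical(toupper(type_field), "NA")) "NA." else toupper(type_field)
      if (nzchar(type_field) && key %in% names(.autodock_types))
        element <- unname(.autodock_types[key])
    }
    if (is.na(element) && nzchar(elem_field) &&
        !grepl("[0-9+-]", elem_field)) {
      cand <- normalize_element(elem_field)
      if (!is.na(cand) && cand %in% .known_elements) element <- cand
    }
    if (is.na(element)) element <- element_from_name(name, raw_name)
    if (is.na(element)) {
      warns <- c(warns, sprintf("cannot infer element for atom '%s'; line skipped", name))
      next
    }
    rows[[k]] <- data.frame(
      serial = if (is.na(serial)) k else serial,
      name = name, element = element, x = x, y = y, z = z,
      chain = chain, resid = if (is.na(resid)) 0L else resid,
      resname = resname, is_hydrogen = identical(element, "H"),
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  atoms <- if (length(rows)) do.call(rbind, rows) else empty_atom_table()
  rownames(atoms) <- NULL
  list(atoms = atoms, warnings = warns)
}

#' Read a receptor structure (PDB or PDBQT)
#'
#' Loads every ATOM/HETATM record into an atom table addressable by the
#' (chain, resid, atomname) triples used to anchor receptor-atom filters.
#' PDBQT partial-charge and atom-type columns are consumed but only the
#' element, coordinates and identity fields are used downstream. HETATM
#' records (e.g. co-crystallised cofactors) are accepted as anchors.
#'
#' @param path path to a `.pdb` or `.pdbqt` file.
#' @return an object of class `Receptor`: list with `atoms` (data.frame),
#'   `source_path`, `format`.
#' @examples
#' rec_file <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  N   GLY A 863       0.500   1.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  GLY A 863       0.000   0.000   0.000  1.00  0.00           C"),
#'   rec_file)
#' rec <- read_receptor(rec_file)
#' select_atom(rec, "A", 863, "CA")
#' @seealso [select_atom()], [read_poses()]
#' @export
read_receptor <- function(path) {
  if (!file.exists(path)) stop("receptor file not found: ", path)
  fmt <- toupper(tools::file_ext(path))
  if (!fmt %in% c("PDB", "PDBQT"))
    stop("receptor must be PDB or PDBQT, got: ", path)
  lines <- readLines(path, warn = FALSE)
  parsed <- parse_pdb_atoms(lines, pdbqt = identical(fmt, "PDBQT"))
  for (w in parsed$warnings) warning(w, call. = FALSE)
  atoms <- parsed$atoms
  if (nrow(atoms) == 0L)
    stop("no atoms found in receptor file: ", path)
  key <- paste(atoms$chain, atoms$resid, atoms$name, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (chain, resid, atomname) triples in receptor: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  structure(list(atoms = atoms, source_path = path, format = fmt),
            class = "Receptor")
}

#' @export
print.Receptor <- function(x, ...) {
  cat(sprintf("Receptor: %d atoms (%s, %s)\n", nrow(x$atoms), x$format,
              basename(x$source_path)))
  invisible(x)
}

#' Look up a receptor atom by chain, residue id, and atom name
#'
#' The anchor of a receptor-atom filter. Exactly one atom must match;
#' anything else is a configuration error that aborts the run before any
#' pose is evaluated (a filter that cannot be anchored must never silently
#' pass everything). Insertion codes and altLoc indicators do not take part
#' in matching.
#'
#' @param receptor a `Receptor` from [read_receptor()].
#' @param chain chain identifier string.
#' @param resid integer residue id.
#' @param atomname atom-name string (e.g. `"CA"`, `"CZ"`).
#' @return one-row data.frame (the matching atom).
#' @export
select_atom <- function(receptor, chain, resid, atomname) {
  stopifnot(inherits(receptor, "Receptor"))
  a <- receptor$atoms
  hit <- which(a$chain == as.character(chain) &
                 a$resid == as.integer(resid) &
                 a$name == as.character(atomname))
  sel <- sprintf("(chain %s, resid %s, atomname %s)", chain, resid, atomname)
  if (length(hit) == 0L)
    stop("receptorAtom selector matched no atom: ", sel)
  if (length(hit) > 1L)
    stop("receptorAtom selector matched multiple atoms: ", sel)
  a[hit, , drop = FALSE]
}

new_pose_record <- function(atoms, bonds, pose_index, source_path, format) {
  structure(list(atoms = atoms, bonds = bonds, pose_index = pose_index,
                 source_path = source_path, format = format),
            class = "PoseRecord")
}

#' @export
print.PoseRecord <- function(x, ...) {
  cat(sprintf("PoseRecord #%d: %d atoms, %s bonds (%s)\n", x$pose_index,
              nrow(x$atoms),
              if (is.null(x$bonds)) "no" else nrow(x$bonds), x$format))
  invisible(x)
}

.bond_order_names <- c("single", "double", "triple", "aromatic")

read_poses_pdbish <- function(path, fmt) {
  lines <- readLines(path, warn = FALSE)
  rec6 <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec6) == "MODEL")
  if (length(model_starts) == 0L) {
    blocks <- list(lines)
  } else {
    ends <- which(trimws(rec6) == "ENDMDL")
    blocks <- lapply(seq_along(model_starts), function(i) {
      from <- model_starts[i]
      to <- ends[ends > from]
      to <- if (length(to)) min(to) else length(lines)
      lines[from:to]
    })
  }
  poses <- list()
  for (i in seq_along(blocks)) {
    parsed <- parse_pdb_atoms(blocks[[i]], pdbqt = identical(fmt, "PDBQT"))
    for (w in parsed$warnings) warning(w, call. = FALSE)
    if (nrow(parsed$atoms) == 0L) next
    poses[[length(poses) + 1L]] <-
      new_pose_record(parsed$atoms, NULL, length(poses) + 1L, path, fmt)
  }
  if (length(poses) == 0L) stop("no atoms found in pose file: ", path)
  poses
}

# SDF reading goes through ChemmineR when it is installed (the standard
# V2000 reader in the R ecosystem); a compact fallback parser covers the
# same records otherwise.
read_poses_sdf <- function(path) {
  if (requireNamespace("ChemmineR", quietly = TRUE)) {
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
    valid <- suppressWarnings(ChemmineR::validSDF(sdfset))
    sdfset <- sdfset[valid]
    if (length(sdfset) == 0L) stop("no parseable molecules in SDF: ", path)
    poses <- vector("list", length(sdfset))
    for (i in seq_along(sdfset)) {
      ab <- ChemmineR::atomblock(sdfset[[i]])
      bb <- ChemmineR::bondblock(sdfset[[i]])
      elem <- normalize_element(sub("_[0-9]+$", "", rownames(ab)))
      atoms <- data.frame(
        serial = seq_len(nrow(ab)),
        name = paste0(elem, seq_len(nrow(ab))), element = elem,
        x = ab[, 1], y = ab[, 2], z = ab[, 3],
        chain = "", resid = 0L, resname = "LIG",
        is_hydrogen = elem == "H", stringsAsFactors = FALSE)
      rownames(atoms) <- NULL
      bb <- as.matrix(bb)
      ord <- pmin(pmax(as.integer(bb[, 3]), 1L), 4L)
      bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                          order = .bond_order_names[ord],
                          stringsAsFactors = FALSE)
      if (any(bonds$i > nrow(atoms) | bonds$j > nrow(atoms) |
                bonds$i < 1L | bonds$j < 1L))
        stop("SDF bond block refers to atoms outside the atom block: ", path)
      poses[[i]] <- new_pose_record(atoms, bonds, i, path, "SDF")
    }
    return(poses)
  }
  read_poses_sdf_base(path)
}

read_poses_sdf_base <- function(path) {
  lines <- readLines(path, warn = FALSE)
  delims <- c(0L, which(trimws(lines) == "$$$$"))
  if (length(delims) == 1L) delims <- c(0L, length(lines))
  poses <- list()
  for (b in seq_len(length(delims) - 1L)) {
    mol <- lines[(delims[b] + 1L):(delims[b + 1L])]
    mol <- mol[trimws(mol) != "$$$$"]
    if (length(mol) < 4L || all(!nzchar(trimws(mol)))) next
    counts <- mol[4]
    na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
    nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
    if (is.na(na) || is.na(nb) || length(mol) < 4 + na + nb)
      stop("malformed V2000 counts line in ", path)
    at <- mol[5:(4 + na)]
    elem <- normalize_element(trimws(substr(at, 32, 34)))
    if (any(is.na(elem) | !(elem %in% .known_elements)))
      stop("unrecognised element in SDF atom block: ", path)
    atoms <- data.frame(
      serial = seq_len(na), name = paste0(elem, seq_len(na)),
      element = elem,
      x = as.numeric(substr(at, 1, 10)),
      y = as.numeric(substr(at, 11, 20)),
      z = as.numeric(substr(at, 21, 30)),
      chain = "", resid = 0L, resname = "LIG",
      is_hydrogen = elem == "H", stringsAsFactors = FALSE)
    if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z))
      stop("malformed coordinates in SDF atom block: ", path)
    bonds <- empty_bond_table()
    if (nb > 0) {
      bt <- mol[(5 + na):(4 + na + nb)]
      bi <- as.integer(substr(bt, 1, 3))
      bj <- as.integer(substr(bt, 4, 6))
      bo <- pmin(pmax(as.integer(substr(bt, 7, 9)), 1L), 4L)
      if (anyNA(bi) || anyNA(bj) || any(bi < 1 | bj < 1 | bi > na | bj > na))
        stop("SDF bond block refers to atoms outside the atom block: ", path)
      bonds <- data.frame(i = bi, j = bj, order = .bond_order_names[bo],
                          stringsAsFactors = FALSE)
    }
    poses[[length(poses) + 1L]] <-
      new_pose_record(atoms, bonds, length(poses) + 1L, path, "SDF")
  }
  if (length(poses) == 0L) stop("no parseable molecules in SDF: ", path)
  poses
}

#' Read docked poses from a PDBQT, PDB, or SDF file
#'
#' PDB/PDBQT files with MODEL/ENDMDL blocks yield one pose per block
#' (AutoDock Vina writes up to nine); files without MODEL records yield a
#' single pose. SDF files yield one pose per molecule entry, with bonds
#' taken verbatim from the V2000 bond block. Errors in individual files are
#' the caller's concern: [run_screen()] converts them into skip records
#' rather than aborting the screen.
#'
#' @param path pose file (`.pdbqt`, `.pdb`, or `.sdf`).
#' @return list of `PoseRecord` objects, `pose_index` 1..n.
#' @seealso [read_receptor()], [run_screen()]
#' @export
read_poses <- function(path) {
  if (!file.exists(path)) stop("pose file not found: ", path)
  fmt <- toupper(tools::file_ext(path))
  switch(fmt,
         PDB = read_poses_pdbish(path, "PDB"),
         PDBQT = read_poses_pdbish(path, "PDBQT"),
         SDF = read_poses_sdf(path),
         stop("unsupported pose format '", fmt, "': ", path))
}

format_pdb_atom_line <- function(a, k, record = "HETATM", pdbqt = FALSE) {
  elem <- a$element[k]
  name <- a$name[k]
  # element right-justified in columns 13-14 per PDB convention
  name_field <- if (nchar(elem) == 2L) sprintf("%-4s", substr(name, 1, 4))
  else sprintf(" %-3s", substr(name, 1, 3))
  base <- sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                  record, a$serial[k], name_field,
                  substr(a$resname[k], 1, 3),
                  substr(a$chain[k], 1, 1), a$resid[k],
                  a$x[k], a$y[k], a$z[k], 1.00, 0.00)
  if (pdbqt) {
    type <- toupper(elem)
    paste0(base, sprintf("    %6.3f %-2s", 0.0, type))
  } else {
    paste0(base, sprintf("          %2s", toupper(elem)))
  }
}

#' Write a pose (or several) back to PDB, PDBQT, or SDF
#'
#' Used by the fixture generator and for round-trip checks. Multi-pose PDB
#' and PDBQT files are written as MODEL/ENDMDL blocks; SDF output uses a
#' V2000 connection table. Coordinates are written at the PDB fixed-width
#' precision of three decimals.
#'
#' @param poses a `PoseRecord` or list of them (all same molecule family).
#' @param path destination file; the extension selects the format.
#' @param format override `"PDB"`, `"PDBQT"`, or `"SDF"`; default from the
#'   extension.
#' @return `path`, invisibly.
#' @export
write_poses <- function(poses, path, format = NULL) {
  if (inherits(poses, "PoseRecord")) poses <- list(poses)
  fmt <- toupper(if (is.null(format)) tools::file_ext(path) else format)
  out <- character()
  if (fmt %in% c("PDB", "PDBQT")) {
    multi <- length(poses) > 1L
    for (p in poses) {
      a <- p$atoms
      if (multi) out <- c(out, sprintf("MODEL %8d", p$pose_index))
      out <- c(out, vapply(seq_len(nrow(a)), function(k)
        format_pdb_atom_line(a, k, pdbqt = identical(fmt, "PDBQT")),
        character(1)))
      if (multi) out <- c(out, "ENDMDL")
    }
    if (!multi) out <- c(out, "END")
  } else if (fmt == "SDF") {
    for (p in poses) {
      a <- p$atoms
      b <- if (is.null(p$bonds)) empty_bond_table() else p$bonds
      ord <- match(b$order, .bond_order_names)
      out <- c(out,
               sprintf("pose_%d", p$pose_index), "  posegrep", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)),
               vapply(seq_len(nrow(a)), function(k)
                 sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         a$x[k], a$y[k], a$z[k], a$element[k]), character(1)),
               if (nrow(b)) vapply(seq_len(nrow(b)), function(k)
                 sprintf("%3d%3d%3d  0", b$i[k], b$j[k], ord[k]),
                 character(1)) else character(0),
               "M  END", "$$$$")
    }
  } else stop("unsupported output format: ", fmt)
  writeLines(out, path)
  invisible(path)
}
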
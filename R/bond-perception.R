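# Bond assignment for docked poses. PDB/PDBQT poses carry no bond
# information, so connectivity must come from geometry (NONE mode), from a
# user-supplied SMILES template (SMILES mode), or from an external
# PDB->SDF converter such as Open Babel (OPENBABEL mode). SDF poses carry
# their own bond block and bypass perception entirely.

empty_bond_table <- function() {
  data.frame(i = integer(), j = integer(), order = character(),
             stringsAsFactors = FALSE)
}

#' Construct a molecular graph
#'
#' @param atoms atom data.frame (as in a `PoseRecord`).
#' @param bonds data.frame with columns `i`, `j`, `order` (one of
#'   `"single"`, `"double"`, `"triple"`, `"aromatic"`); undirected, no
#'   self-bonds or duplicates.
#' @param provenance one of `"geometric"`, `"sdf_block"`,
#'   `"smiles_template"`, `"external_tool"`.
#' @return `MolecularGraph` object.
#' @export
molecular_graph <- function(atoms, bonds, provenance) {
  provenance <- match.arg(provenance,
                          c("geometric", "sdf_block", "smiles_template",
                            "external_tool"))
  if (nrow(bonds)) {
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    if (any(bonds$i == bonds$j)) stop("self-bond in molecular graph")
    if (anyDuplicated(bonds[, c("i", "j")]))
      stop("duplicate bond in molecular graph")
    if (any(bonds$i < 1L | bonds$j > nrow(atoms)))
      stop("bond index outside atom range")
    if (identical(provenance, "geometric") &&
        !all(bonds$order == "single"))
      stop("geometric perception can only assign single bonds")
  }
  structure(list(atoms = atoms, bonds = bonds, provenance = provenance),
            class = "MolecularGraph")
}

#' @export
print.MolecularGraph <- function(x, ...) {
  cat(sprintf("MolecularGraph: %d atoms, %d bonds (%s)\n",
              nrow(x$atoms), nrow(x$bonds), x$provenance))
  invisible(x)
}

#' Covalent-radius table for geometric bond perception
#'
#' Two atoms are considered bonded when their distance does not exceed the
#' sum of their covalent radii plus an additive tolerance. The default
#' tolerance of 0.45 Angstrom absorbs the geometric distortion typical of
#' docked conformers without fusing non-bonded contacts; a floor of 0.4
#' Angstrom rejects coincident-atom artifacts.
#'
#' @param radii named numeric vector of per-element overrides (Angstrom).
#' @param tolerance additive slack in Angstrom (default 0.45).
#' @param min_dist minimum distance in Angstrom below which a contact is
#'   treated as an artifact, never a bond (default 0.4).
#' @return `CovalentRadiusTable` object.
#' @export
covalent_radius_table <- function(radii = NULL, tolerance = 0.45,
                                  min_dist = 0.4) {
  tab <- .covalent_radii
  if (!is.null(radii)) {
    stopifnot(!is.null(names(radii)), all(radii > 0))
    tab[names(radii)] <- radii
  }
  stopifnot(tolerance >= 0, min_dist >= 0)
  structure(list(radii = tab, tolerance = tolerance, min_dist = min_dist),
            class = "CovalentRadiusTable")
}

#' Infer single bonds from interatomic distances
#'
#' The geometric rule behind NONE mode for PDB/PDBQT poses: every atom is
#' treated as sp3, and atoms i, j are joined by a single bond iff
#' `d(i, j) <= radius(i) + radius(j) + tolerance` (and `d >= min_dist`).
#' SDF poses must never pass through this: their bond block is
#' authoritative (use [graph_from_pose()]).
#'
#' @param pose a `PoseRecord`.
#' @param radii a `CovalentRadiusTable` (default table if omitted).
#' @return `MolecularGraph` with provenance `"geometric"`.
#' @examples
#' # two carbons at a C-C bond length are joined; at 3 A they are not
#' @export
infer_bonds_geometric <- function(pose, radii = covalent_radius_table()) {
  stopifnot(inherits(pose, "PoseRecord") || is.data.frame(pose$atoms))
  a <- pose$atoms
  n <- nrow(a)
  if (n == 0L) stop("pose has no atoms")
  r <- unname(radii$radii[a$element])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("no covalent radius for element(s): ",
            paste(unique(a$element[unknown]), collapse = ", "),
            "; those atoms get no inferred bonds", call. = FALSE)
  }
  if (n == 1L)
    return(molecular_graph(a, empty_bond_table(), "geometric"))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(r, r, "+") + radii$tolerance
  thr[is.na(thr)] <- -Inf       # unknown elements never bond
  adj <- d <= thr & d >= radii$min_dist
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  bonds <- if (nrow(idx)) {
    data.frame(i = idx[, 1], j = idx[, 2], order = "single",
               stringsAsFactors = FALSE)
  } else empty_bond_table()
  molecular_graph(a, bonds, "geometric")
}

#' Build the working graph for a pose under a bond-assignment mode
#'
#' SDF poses always use their own bond block (provenance `"sdf_block"`),
#' whatever the mode; PDB/PDBQT poses are routed to geometric inference,
#' SMILES-template assignment, or an external converter.
#'
#' @param pose a `PoseRecord`.
#' @param mode `"NONE"`, `"SMILES"`, or `"OPENBABEL"`.
#' @param smiles SMILES string (SMILES mode; `NULL` falls back to NONE with
#'   a warning).
#' @param radii `CovalentRadiusTable` for geometric inference.
#' @param babel_exec path to the external converter (OPENBABEL mode).
#' @return `MolecularGraph`.
#' @export
graph_from_pose <- function(pose, mode = "NONE", smiles = NULL,
                            radii = covalent_radius_table(),
                            babel_exec = NULL) {
  mode <- match.arg(mode, c("NONE", "SMILES", "OPENBABEL"))
  if (identical(pose$format, "SDF"))
    return(molecular_graph(pose$atoms, pose$bonds, "sdf_block"))
  if (identical(mode, "NONE"))
    return(infer_bonds_geometric(pose, radii))
  if (identical(mode, "SMILES")) {
    if (is.null(smiles)) {
      warning("no SMILES template for ", basename(pose$source_path),
              "; falling back to geometric single bonds", call. = FALSE)
      return(infer_bonds_geometric(pose, radii))
    }
    return(bonds_from_smiles_template(pose, smiles, radii))
  }
  bonds_from_external_tool(pose$source_path, babel_exec,
                           pose_index = pose$pose_index)
}

#' Assign bond orders from a SMILES template
#'
#' PDBQT files strip non-polar hydrogens, so the template is mapped onto
#' the pose over heavy atoms only: an element-labelled graph embedding is
#' sought between the template's heavy-atom graph and the pose's geometric
#' connectivity, and template bond orders (and aromatic flags) are copied
#' onto the mapped atoms. When several mappings exist (symmetric
#' molecules), the first is used; bond orders agree across automorphic
#' mappings, so filter outcomes do not depend on the choice.
#' Stereochemistry and formal charge are ignored.
#'
#' On any failure (SMILES parse error, element multiset mismatch, no
#' mapping) the pose is evaluated under geometric single bonds with a
#' warning, mirroring the tool's warn-and-continue policy.
#'
#' @param pose a `PoseRecord` (PDB/PDBQT).
#' @param smiles template SMILES string.
#' @param radii `CovalentRadiusTable` used for the pose-side connectivity.
#' @return `MolecularGraph` with provenance `"smiles_template"` (or
#'   `"geometric"` after fallback).
#' @export
bonds_from_smiles_template <- function(pose, smiles,
                                       radii = covalent_radius_table()) {
  geo <- infer_bonds_geometric(pose, radii)
  tmpl <- tryCatch(parse_smiles(smiles), error = function(e) e)
  if (inherits(tmpl, "error")) {
    warning("SMILES template failed to parse ('", smiles, "'): ",
            conditionMessage(tmpl), "; using geometric single bonds",
            call. = FALSE)
    return(geo)
  }
  heavy_pose <- which(!pose$atoms$is_hydrogen)
  heavy_tmpl <- which(tmpl$element != "H")
  if (length(heavy_pose) != length(heavy_tmpl) ||
      !identical(sort(pose$atoms$element[heavy_pose]),
                 sort(tmpl$element[heavy_tmpl]))) {
    warning("heavy-atom element mismatch between pose and SMILES template '",
            smiles, "'; using geometric single bonds", call. = FALSE)
    return(geo)
  }
  # template heavy-atom graph
  tmap <- match(seq_along(tmpl$element), heavy_tmpl)
  tb <- tmpl$bonds[tmpl$element[tmpl$bonds$i] != "H" &
                     tmpl$element[tmpl$bonds$j] != "H", , drop = FALSE]
  tb$i <- tmap[tb$i]; tb$j <- tmap[tb$j]
  # pose heavy-atom geometric graph
  pmap <- match(seq_len(nrow(pose$atoms)), heavy_pose)
  pb <- geo$bonds[!pose$atoms$is_hydrogen[geo$bonds$i] &
                    !pose$atoms$is_hydrogen[geo$bonds$j], , drop = FALSE]
  pb$i <- pmap[pb$i]; pb$j <- pmap[pb$j]
  mapping <- match_labelled_graph(
    pat_elem = tmpl$element[heavy_tmpl], pat_bonds = tb,
    mol_elem = pose$atoms$element[heavy_pose], mol_bonds = pb)
  if (is.null(mapping)) {
    warning("no heavy-atom mapping between pose and SMILES template '",
            smiles, "'; using geometric single bonds", call. = FALSE)
    return(geo)
  }
  bonds <- data.frame(i = heavy_pose[mapping[tb$i]],
                      j = heavy_pose[mapping[tb$j]],
                      order = tb$order, stringsAsFactors = FALSE)
  # hydrogens surviving in the pose keep their geometric single bonds
  hb <- geo$bonds[pose$atoms$is_hydrogen[geo$bonds$i] |
                    pose$atoms$is_hydrogen[geo$bonds$j], , drop = FALSE]
  if (nrow(hb)) bonds <- rbind(bonds, hb)
  molecular_graph(pose$atoms, bonds, "smiles_template")
}

# Embed an element-labelled pattern graph into a molecule graph: find an
# injective atom mapping preserving elements under which every pattern
# edge maps onto a molecule edge. Used with equal atom counts this is a
# monomorphism that tolerates spurious geometric edges on the pose side.
match_labelled_graph <- function(pat_elem, pat_bonds, mol_elem, mol_bonds) {
  np <- length(pat_elem); nm <- length(mol_elem)
  if (np > nm) return(NULL)
  adj <- matrix(FALSE, nm, nm)
  if (nrow(mol_bonds)) {
    adj[cbind(mol_bonds$i, mol_bonds$j)] <- TRUE
    adj[cbind(mol_bonds$j, mol_bonds$i)] <- TRUE
  }
  padj <- lapply(seq_len(np), function(k) {
    c(pat_bonds$j[pat_bonds$i == k], pat_bonds$i[pat_bonds$j == k])
  })
  assign <- integer(np)
  used <- logical(nm)
  recurse <- function(k) {
    if (k > np) return(TRUE)
    for (cand in which(!used & mol_elem == pat_elem[k])) {
      nb <- padj[[k]]
      ok <- TRUE
      for (q in nb[nb < k]) if (!adj[assign[q], cand]) { ok <- FALSE; break }
      if (!ok) next
      assign[k] <<- cand; used[cand] <<- TRUE
      if (recurse(k + 1L)) return(TRUE)
      used[cand] <<- FALSE
    }
    FALSE
  }
  if (recurse(1L)) assign else NULL
}

#' Assign bonds via an external PDB/PDBQT-to-SDF converter
#'
#' Subprocess contract around an Open Babel-style converter. The file is
#' first converted with all missing hydrogens added (`-h`); if the
#' converter's heavy-atom assignment does not match the input file, the
#' conversion is retried with pH 7.4 protonation (`-p 7.4`). If both
#' attempts fail the caller receives an error, which [run_screen()] turns
#' into a skip record so the screen moves on to the next compound file.
#'
#' @param path the PDB/PDBQT pose file.
#' @param tool_exec path to the converter executable.
#' @param pose_index which pose of the converted file to return (default 1).
#' @return `MolecularGraph` with provenance `"external_tool"`.
#' @export
bonds_from_external_tool <- function(path, tool_exec, pose_index = 1L) {
  if (is.null(tool_exec) || !file.exists(tool_exec))
    stop("external converter not found: ",
         if (is.null(tool_exec)) "(not specified)" else tool_exec)
  ref <- read_poses(path)
  ref_heavy <- sort(ref[[min(pose_index, length(ref))]]$atoms$element[
    !ref[[min(pose_index, length(ref))]]$atoms$is_hydrogen])
  attempt <- function(extra_args) {
    out_sdf <- tempfile(fileext = ".sdf")
    on.exit(unlink(out_sdf), add = TRUE)
    status <- suppressWarnings(system2(
      tool_exec, c(shQuote(path), "-osdf", "-O", shQuote(out_sdf),
                   extra_args),
      stdout = FALSE, stderr = FALSE))
    if (!identical(status, 0L) || !file.exists(out_sdf) ||
        file.size(out_sdf) == 0) return(NULL)
    poses <- tryCatch(read_poses_sdf(out_sdf), error = function(e) NULL)
    if (is.null(poses)) return(NULL)
    p <- poses[[min(pose_index, length(poses))]]
    heavy <- sort(p$atoms$element[!p$atoms$is_hydrogen])
    if (!identical(heavy, ref_heavy)) return(NULL)
    molecular_graph(p$atoms, p$bonds, "external_tool")
  }
  g <- attempt("-h")
  if (is.null(g)) g <- attempt(c("-p", "7.4"))
  if (is.null(g))
    stop("external bond assignment failed for ", basename(path),
         " (tried -h, then -p 7.4)")
  g
}
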
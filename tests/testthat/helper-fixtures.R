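# Shared builders for the test suite. Everything is generated in code at
# test time; no stored binary fixtures.

toy_atoms <- function(elements, xyz, hydrogens = elements == "H") {
  data.frame(serial = seq_along(elements),
             name = paste0(elements, seq_along(elements)),
             element = elements,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             chain = "", resid = 1L, resname = "LIG",
             is_hydrogen = hydrogens, stringsAsFactors = FALSE)
}

toy_graph <- function(elements, xyz, bonds, provenance = "sdf_block") {
  molecular_graph(toy_atoms(elements, xyz), bonds, provenance)
}

toy_pose <- function(elements, xyz, bonds = NULL, format = "PDBQT") {
  structure(list(atoms = toy_atoms(elements, xyz), bonds = bonds,
                 pose_index = 1L, source_path = "<toy>", format = format),
            class = "PoseRecord")
}

# a four-residue-atom glycine in standard PDB fixed columns
write_toy_receptor_pdb <- function(path) {
  writeLines(c(
    "REMARK  toy receptor",
    "ATOM      1  N   GLY A 863      -1.200   0.800   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A 863       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A 863       1.300   0.700   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A 863       1.900   1.800   0.000  1.00  0.00           O",
    "END"), path)
  path
}

# the same CA atom as a PDBQT line with charge + AutoDock type columns
write_toy_receptor_pdbqt <- function(path) {
  writeLines(c(
    "ATOM      1  N   GLY A 863      -1.200   0.800   0.000  1.00  0.00     0.100 N ",
    "ATOM      2  CA  GLY A 863       0.000   0.000   0.000  1.00  0.00     0.050 C ",
    "ATOM      3  C   GLY A 863       1.300   0.700   0.000  1.00  0.00     0.200 C ",
    "ATOM      4  O   GLY A 863       1.900   1.800   0.000  1.00  0.00    -0.300 OA"), path)
  path
}

write_filters_json <- function(path, json) {
  writeLines(json, path)
  path
}

simple_coordinate_filter <- function(smarts = "[#7,#8]", cutoff = 5.5,
                                     coord = c(0, 0, 0), exclude = FALSE) {
  tf <- tempfile(fileext = ".json")
  writeLines(sprintf(
    '[{"smarts": "%s", "coordinate": [%g, %g, %g], "distance": %g%s}]',
    smarts, coord[1], coord[2], coord[3], cutoff,
    if (exclude) ', "exclude": true' else ""), tf)
  resolve_query_point(load_filters(tf)[[1]])
}

# graphs engineered so substructure presence and cutoff position are
# controlled exactly: query point at origin, matched atom is the O
engine_case_graph <- function(has_substructure, within) {
  d <- if (within) 4.9 else 8.0
  if (has_substructure) {
    toy_graph(c("C", "O"), rbind(c(d + 1.43, 0, 0), c(d, 0, 0)),
              data.frame(i = 1L, j = 2L, order = "single"))
  } else {
    toy_graph(c("C", "C"), rbind(c(d + 1.54, 0, 0), c(d, 0, 0)),
              data.frame(i = 1L, j = 2L, order = "single"))
  }
}

# independent brute-force evaluator for 1- and 2-atom patterns: direct
# element/bond scans plus an all-atom distance sweep, no shared code with
# the engine's matcher
brute_force_filter_verdict <- function(graph, smarts, query_point, cutoff,
                                       exclude = FALSE) {
  elems <- graph$atoms$element
  arom_atoms <- unique(c(
    graph$bonds$i[graph$bonds$order == "aromatic"],
    graph$bonds$j[graph$bonds$order == "aromatic"]))
  matched <- if (smarts == "[#7,#8]") {
    which(elems %in% c("N", "O"))
  } else if (smarts == "cc") {
    ab <- graph$bonds[graph$bonds$order == "aromatic" &
                        elems[graph$bonds$i] == "C" &
                        elems[graph$bonds$j] == "C", , drop = FALSE]
    unique(c(ab$i, ab$j))
  } else if (smarts == "[#8]") {
    which(elems == "O")
  } else stop("brute-force oracle only handles 1-2 atom patterns")
  if (length(matched) == 0L) return(exclude)
  d <- apply(graph$atoms[matched, c("x", "y", "z"), drop = FALSE], 1,
             function(p) sqrt(sum((p - query_point)^2)))
  within <- min(d) <= cutoff
  if (exclude) !within else within
}

# converter stubs for the external-tool contract
make_stub_converter <- function(behaviour = c("ok", "retry", "fail"),
                                good_sdf = NULL, bad_sdf = NULL) {
  behaviour <- match.arg(behaviour)
  stub <- tempfile(fileext = ".sh")
  body <- switch(behaviour,
    ok = c("#!/bin/sh",
           'out=""; prev=""',
           'for a in "$@"; do if [ "$prev" = "-O" ]; then out="$a"; fi; prev="$a"; done',
           sprintf('cat "%s" > "$out"', good_sdf)),
    retry = c("#!/bin/sh",
              'out=""; prev=""; mode=""',
              'for a in "$@"; do',
              '  if [ "$prev" = "-O" ]; then out="$a"; fi',
              '  if [ "$a" = "-h" ]; then mode=h; fi',
              '  if [ "$a" = "-p" ]; then mode=p; fi',
              '  prev="$a"',
              'done',
              sprintf('if [ "$mode" = "h" ]; then cat "%s" > "$out"; else cat "%s" > "$out"; fi',
                      bad_sdf, good_sdf)),
    fail = c("#!/bin/sh", "exit 1"))
  writeLines(body, stub)
  Sys.chmod(stub, "0755")
  stub
}
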
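# The screening engine: apply every resolved filter to every pose of
# every compound file, combine filters by Boolean AND, and report the
# compounds with at least one fully passing pose. Per-compound problems
# are skip records, never fatal; only receptor/filter configuration
# errors abort a run.

#' Minimum distance from matched substructure atoms to a query point
#'
#' Euclidean minimum over the union of all atoms in all embeddings.
#'
#' @param atom_sets list of integer atom-index vectors (embeddings).
#' @param graph the `MolecularGraph` the indices refer to.
#' @param query_point numeric `[x, y, z]`.
#' @return distance in Angstrom.
#' @export
min_distance <- function(atom_sets, graph, query_point) {
  stopifnot(length(atom_sets) > 0)
  idx <- unique(unlist(atom_sets))
  xyz <- as.matrix(graph$atoms[idx, c("x", "y", "z"), drop = FALSE])
  sqrt(min(rowSums(sweep(xyz, 2, query_point)^2)))
}

#' Evaluate one filter against one pose graph
#'
#' Implements the six-row pass/fail truth table over (has substructure,
#' exclude flag, any substructure atom within cutoff):
#' \tabular{llll}{
#'   has substructure \tab exclude \tab within cutoff \tab result \cr
#'   no  \tab no  \tab n/a \tab Fail \cr
#'   no  \tab yes \tab n/a \tab Pass \cr
#'   yes \tab no  \tab no  \tab Fail \cr
#'   yes \tab no  \tab yes \tab Pass \cr
#'   yes \tab yes \tab no  \tab Pass \cr
#'   yes \tab yes \tab yes \tab Fail
#' }
#' "Within cutoff" is inclusive (`min_distance <= cutoff`).
#'
#' @param pose_graph a `MolecularGraph` with bonds assigned.
#' @param f a `ResolvedFilter`.
#' @return `FilterVerdict`: list with `filter_label`, `has_substructure`,
#'   `within_cutoff` (`NA` when no substructure), `min_distance` (`NA`
#'   when no substructure), `passed`.
#' @export
evaluate_filter <- function(pose_graph, f) {
  stopifnot(inherits(f, "ResolvedFilter"))
  sets <- match_substructure(pose_graph, f$pattern)
  has <- length(sets) > 0L
  if (!has) {
    verdict <- f$exclude       # rows 1-2: absent substructure
    return(structure(list(filter_label = f$label, has_substructure = FALSE,
                          within_cutoff = NA, min_distance = NA_real_,
                          passed = verdict),
                     class = "FilterVerdict"))
  }
  d <- min_distance(sets, pose_graph, f$query_point)
  within <- d <= f$cutoff
  passed <- if (f$exclude) !within else within   # rows 3-6
  structure(list(filter_label = f$label, has_substructure = TRUE,
                 within_cutoff = within, min_distance = d, passed = passed),
            class = "FilterVerdict")
}

#' Evaluate a pose against all filters (Boolean AND)
#'
#' @param pose_graph a `MolecularGraph`.
#' @param filters list of `ResolvedFilter`.
#' @return list with `passed` (TRUE iff every filter passes; vacuously
#'   TRUE for an empty filter list) and `verdicts`.
#' @export
evaluate_pose <- function(pose_graph, filters) {
  verdicts <- lapply(filters, function(f) evaluate_filter(pose_graph, f))
  passed <- all(vapply(verdicts, `[[`, logical(1), "passed"))
  list(passed = passed, verdicts = verdicts)
}

.pose_extensions <- c("pdb", "pdbqt", "sdf")

#' List the compound files of a directory
#'
#' Pose files are discovered by extension, case-insensitively; `.smi`
#' companions are never treated as poses. Mixed-format directories are
#' allowed.
#' @param dir compound directory.
#' @return character vector of paths, sorted by file name.
#' @keywords internal
list_compound_files <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  ext <- tolower(tools::file_ext(files))
  files <- files[ext %in% .pose_extensions]
  files[order(basename(files), method = "radix")]
}

# SMILES companion per published convention: same file name + ".smi"
read_smiles_companion <- function(pose_path) {
  smi <- paste0(pose_path, ".smi")
  if (!file.exists(smi)) return(NULL)
  ln <- trimws(readLines(smi, warn = FALSE))
  ln <- ln[nzchar(ln)]
  if (length(ln) == 0L) return(NULL)
  strsplit(ln[1], "[ \t]")[[1]][1]
}

screen_one_file <- function(path, filters, mode, radii, babel_exec) {
  poses <- read_poses(path)
  passing <- integer()
  detail <- list()
  smiles <- if (identical(mode, "SMILES")) read_smiles_companion(path)
  else NULL
  shared_graph <- NULL
  for (p in poses) {
    # connectivity is a property of the molecule, not the conformer:
    # template/external assignment is computed once per file and the
    # resulting bond list reused for every pose (same atom order)
    g <- if (!is.null(shared_graph) &&
               nrow(shared_graph$atoms) == nrow(p$atoms) &&
               identical(shared_graph$atoms$element, p$atoms$element)) {
      molecular_graph(p$atoms, shared_graph$bonds, shared_graph$provenance)
    } else {
      graph_from_pose(p, mode = mode, smiles = smiles, radii = radii,
                      babel_exec = babel_exec)
    }
    if (identical(mode, "SMILES") && is.null(shared_graph)) shared_graph <- g
    res <- evaluate_pose(g, filters)
    if (res$passed) passing <- c(passing, p$pose_index)
    detail[[length(detail) + 1L]] <- data.frame(
      file = basename(path), pose_index = p$pose_index,
      filter_label = vapply(res$verdicts, `[[`, character(1), "filter_label"),
      min_distance = vapply(res$verdicts, `[[`, numeric(1), "min_distance"),
      verdict = ifelse(vapply(res$verdicts, `[[`, logical(1), "passed"),
                       "Pass", "Fail"),
      stringsAsFactors = FALSE)
  }
  list(file = basename(path), passed = length(passing) > 0L,
       passing_poses = passing,
       detail = if (length(detail)) do.call(rbind, detail) else NULL)
}

#' Screen a directory of docked compounds against a filters file
#'
#' The full pipeline: load the receptor (if any filter needs one), load
#' and resolve the filters, then evaluate every parseable pose of every
#' compound file. A compound passes when at least one of its poses passes
#' all filters — all docked poses are considered, not just the top-scoring
#' one. Passing compound file names are written one per line in
#' lexicographic order. Files that cannot be parsed (or whose bond
#' assignment fails in OPENBABEL mode) are recorded as skipped with a
#' warning and the screen continues.
#'
#' @param receptor_path PDB/PDBQT receptor file, or `NULL` when every
#'   filter uses a literal coordinate.
#' @param compounds_dir directory of `.pdbqt`/`.pdb`/`.sdf` pose files
#'   (with optional `<name>.<ext>.smi` SMILES companions for SMILES mode).
#' @param filters_path JSON filters file ([load_filters()]).
#' @param mode bond-assignment mode: `"NONE"` (default), `"SMILES"`, or
#'   `"OPENBABEL"`.
#' @param out optional path for the passing-compounds text file.
#' @param sidecar optional path for a TSV of per-pose, per-filter verdicts
#'   (`file`, `pose_index`, `filter_label`, `min_distance`, `verdict`).
#' @param jobs number of worker processes; results are merged
#'   deterministically, so any value yields byte-identical output. Forked
#'   parallelism is unavailable on Windows, where execution degrades to
#'   serial.
#' @param babel_exec converter executable for OPENBABEL mode.
#' @param radii `CovalentRadiusTable` for geometric perception.
#' @return `ScreenResult`: list with `passed` (named list, file ->
#'   passing pose indices), `skipped` (data.frame `file`, `reason`),
#'   `counts` (`seen`, `passed`, `failed`, `skipped`), `detail`
#'   (verdict data.frame), `out_lines` (the passing file names, sorted).
#' @examples
#' \donttest{
#' fx <- make_pose_fixtures(fixture_spec(seed = 1, n_compounds = 6))
#' res <- run_screen(fx$receptor_path, fx$compounds_dir, fx$filters_path)
#' res$counts
#' }
#' @export
run_screen <- function(receptor_path, compounds_dir, filters_path,
                       mode = "NONE", out = NULL, sidecar = NULL,
                       jobs = 1L, babel_exec = NULL,
                       radii = covalent_radius_table()) {
  mode <- match.arg(mode, c("NONE", "SMILES", "OPENBABEL"))
  if (!dir.exists(compounds_dir))
    stop("compound directory not found: ", compounds_dir)
  defs <- load_filters(filters_path)
  needs_receptor <- any(vapply(defs, function(f)
    is.null(f$coordinate), logical(1)))
  receptor <- if (!is.null(receptor_path)) read_receptor(receptor_path)
  else if (needs_receptor)
    stop("filters use receptorAtom query points but no receptor was given")
  else NULL
  filters <- lapply(defs, resolve_query_point, receptor = receptor)
  files <- list_compound_files(compounds_dir)
  formats_present <- unique(toupper(tools::file_ext(files)))
  for (f in defs) validate_smarts_for_mode(f, mode, formats_present)
  worker <- function(path) {
    tryCatch(screen_one_file(path, filters, mode, radii, babel_exec),
             error = function(e)
               list(file = basename(path), skip = conditionMessage(e)))
  }
  jobs <- max(1L, as.integer(jobs))
  results <- if (jobs > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(files, worker, mc.cores = jobs)
  } else {
    lapply(files, worker)
  }
  passed <- list(); skipped <- list(); details <- list()
  for (r in results) {
    if (!is.null(r$skip)) {
      warning("skipping ", r$file, ": ", r$skip, call. = FALSE)
      skipped[[length(skipped) + 1L]] <-
        data.frame(file = r$file, reason = r$skip, stringsAsFactors = FALSE)
    } else {
      if (r$passed) passed[[r$file]] <- r$passing_poses
      if (!is.null(r$detail)) details[[length(details) + 1L]] <- r$detail
    }
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped)
  else data.frame(file = character(), reason = character(),
                  stringsAsFactors = FALSE)
  n_seen <- length(files)
  counts <- c(seen = n_seen, passed = length(passed),
              failed = n_seen - length(passed) - nrow(skipped),
              skipped = nrow(skipped))
  out_lines <- sort(as.character(names(passed)), method = "radix")
  if (!is.null(out)) writeLines(out_lines, out)
  detail <- if (length(details)) do.call(rbind, details) else NULL
  if (!is.null(sidecar) && !is.null(detail)) {
    detail <- detail[order(detail$file, detail$pose_index,
                           detail$filter_label, method = "radix"), ]
    utils::write.table(detail, sidecar, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  structure(list(passed = passed, skipped = skipped, counts = counts,
                 detail = detail, out_lines = out_lines),
            class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat(sprintf(
    "ScreenResult: %d files seen; %d passed, %d failed, %d skipped\n",
    x$counts["seen"], x$counts["passed"], x$counts["failed"],
    x$counts["skipped"]))
  invisible(x)
}
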
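# Deterministic synthetic fixtures: receptors, multi-pose docked-compound
# files in all three formats (with SMILES companions), filter files, and
# ranked libraries — each with a ground-truth verdict table constructed
# geometrically, independently of the screening engine. Molecules come
# from a small template library with near-ideal bond lengths so geometric
# bond inference is unambiguous; placements keep every substructure atom
# at least 0.2 Angstrom away from any pass/fail distance boundary so no
# verdict hinges on floating-point edge behaviour.

.tet_half <- (180 - 109.47) / 2 * pi / 180   # zigzag half-angle

# planar zigzag chain with tetrahedral angles
zigzag_coords <- function(lengths) {
  n <- length(lengths) + 1L
  xyz <- matrix(0, n, 3)
  for (k in seq_along(lengths)) {
    ang <- if (k %% 2 == 1) .tet_half else -.tet_half
    xyz[k + 1L, ] <- xyz[k, ] + lengths[k] * c(cos(ang), sin(ang), 0)
  }
  xyz
}

ring_coords <- function(n, side) {
  r <- side / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(r * cos(ang), r * sin(ang), 0)
}

chain_bonds <- function(n, order = "single") {
  if (n < 2L) return(empty_bond_table())
  data.frame(i = seq_len(n - 1L), j = 2:n, order = order,
             stringsAsFactors = FALSE)
}

ring_bonds <- function(n, order = "single") {
  data.frame(i = seq_len(n), j = c(2:n, 1L), order = order,
             stringsAsFactors = FALSE)
}

feature <- function(smarts, atoms, needs_aromatic = FALSE) {
  list(smarts = smarts, atoms = atoms, needs_aromatic = needs_aromatic)
}

# each template: heavy-atom elements/coords, true bonds, SMILES, and the
# substructure features it contains (with the atom indices the engine's
# matcher would return, annotated by hand)
fixture_templates <- function() {
  list(
    ethanolamine = list(
      elements = c("N", "C", "C", "O"),
      coords = zigzag_coords(c(1.47, 1.54, 1.43)),
      bonds = chain_bonds(4), smiles = "NCCO",
      features = list(feature("[#7,#8]", c(1L, 4L)),
                      feature("[N,O]CCO", 1:4),
                      feature("CCO", 2:4))),
    ethanol = list(
      elements = c("C", "C", "O"),
      coords = zigzag_coords(c(1.54, 1.43)),
      bonds = chain_bonds(3), smiles = "CCO",
      features = list(feature("[#7,#8]", 3L), feature("CCO", 1:3))),
    propane = list(
      elements = c("C", "C", "C"),
      coords = zigzag_coords(c(1.54, 1.54)),
      bonds = chain_bonds(3), smiles = "CCC",
      features = list()),
    benzene = list(
      elements = rep("C", 6),
      coords = ring_coords(6, 1.39),
      bonds = ring_bonds(6, "aromatic"), smiles = "c1ccccc1",
      features = list(feature("cc", 1:6, needs_aromatic = TRUE))),
    tetrahydropyran = list(
      elements = c("O", "C", "C", "C", "C", "C"),
      coords = ring_coords(6, 1.50),
      bonds = ring_bonds(6), smiles = "C1OCCCC1",
      features = list(feature("[#7,#8]", 1L), feature("C1OCCCC1", 1:6),
                      feature("CCO", c(1L, 2L, 3L, 5L, 6L))))
  )
}

template_diameter <- function(tmpl) {
  max(stats::dist(tmpl$coords))
}

template_has_feature <- function(tmpl, smarts) {
  any(vapply(tmpl$features, function(ft) identical(ft$smarts, smarts),
             logical(1)))
}

# is the feature visible to the engine under this mode/format?
feature_visible <- function(ft, mode, format) {
  !ft$needs_aromatic || identical(format, "SDF") ||
    identical(mode, "SMILES")
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed: uniform over O(3) is fine here
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Fixture-generation parameters
#'
#' @param seed RNG seed; identical seeds give byte-identical fixtures.
#' @param n_compounds number of compound files.
#' @param poses_per_compound poses per file, between 1 and 18 (the
#'   practical per-compound ceiling when a docking run produces up to nine
#'   poses for each of up to two tautomer/protomer variants).
#' @param fraction_pass fraction of compounds designed to pass all
#'   filters.
#' @param formats formats to cycle through, subset of
#'   `c("PDBQT", "PDB", "SDF")`.
#' @param filters list of `FilterDefinition`; default is a single
#'   receptor-anchored hydrogen-bond-style filter (`"[#7,#8]"` within
#'   5.5 Angstrom of the fixture receptor's glycine-863 alpha carbon).
#' @param geometry_noise per-atom Gaussian jitter sd in Angstrom; jitter
#'   that would push a verdict within 0.15 Angstrom of a boundary is
#'   rejected and regenerated.
#' @param mode the bond-assignment mode the ground truth is computed for.
#' @return `FixtureSpec` list.
#' @export
fixture_spec <- function(seed = 7L, n_compounds = 100L,
                         poses_per_compound = 3L, fraction_pass = 0.4,
                         formats = c("PDBQT", "PDB", "SDF"),
                         filters = NULL, geometry_noise = 0.05,
                         mode = "NONE") {
  stopifnot(fraction_pass >= 0, fraction_pass <= 1,
            poses_per_compound >= 1L, poses_per_compound <= 18L)
  formats <- match.arg(formats, c("PDBQT", "PDB", "SDF"),
                       several.ok = TRUE)
  mode <- match.arg(mode, c("NONE", "SMILES", "OPENBABEL"))
  structure(list(seed = as.integer(seed),
                 n_compounds = as.integer(n_compounds),
                 poses_per_compound = as.integer(poses_per_compound),
                 fraction_pass = fraction_pass, formats = formats,
                 filters = filters, geometry_noise = geometry_noise,
                 mode = mode),
            class = "FixtureSpec")
}

default_fixture_filters <- function() {
  json <- paste0('[{"smarts": "[#7,#8]", "receptorAtom": ',
                 '{"chain": "A", "resid": 863, "atomname": "CA"}, ',
                 '"distance": 5.5}]')
  tf <- tempfile(fileext = ".json")
  writeLines(json, tf)
  on.exit(unlink(tf))
  load_filters(tf)
}

#' Write a small synthetic receptor with named anchor atoms
#'
#' The receptor provides well-known anchors for receptorAtom filters: the
#' glycine-863 alpha carbon of chain A sits exactly at the origin and a
#' tyrosine-907 CZ at (8, 0, 0); a second chain is optional. Requesting
#' duplicate (chain, resid, atomname) triples is refused, mirroring the
#' loader's invariant.
#'
#' @param path output file (`.pdb` or `.pdbqt`).
#' @param two_chains also emit a chain-B residue.
#' @param extra_atoms optional data.frame of additional atoms in the atom
#'   table layout.
#' @return `path`, invisibly.
#' @export
make_receptor_fixture <- function(path, two_chains = FALSE,
                                  extra_atoms = NULL) {
  atoms <- data.frame(
    serial = 1:7,
    name = c("N", "CA", "C", "O", "CA", "CZ", "OH"),
    element = c("N", "C", "C", "O", "C", "C", "O"),
    x = c(-1.2, 0.0, 1.3, 1.9, 6.5, 8.0, 9.2),
    y = c(0.8, 0.0, 0.7, 1.8, 0.5, 0.0, 0.6),
    z = c(0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0),
    chain = "A",
    resid = c(863L, 863L, 863L, 863L, 907L, 907L, 907L),
    resname = c(rep("GLY", 4), rep("TYR", 3)),
    is_hydrogen = FALSE, stringsAsFactors = FALSE)
  if (two_chains) {
    atoms <- rbind(atoms, data.frame(
      serial = 8L, name = "CA", element = "C", x = 20, y = 20, z = 20,
      chain = "B", resid = 1L, resname = "ALA", is_hydrogen = FALSE,
      stringsAsFactors = FALSE))
  }
  if (!is.null(extra_atoms)) atoms <- rbind(atoms, extra_atoms)
  key <- paste(atoms$chain, atoms$resid, atoms$name, sep = "|")
  if (anyDuplicated(key))
    stop("fixture receptor would contain duplicate (chain, resid, ",
         "atomname) triples: ", paste(key[duplicated(key)], collapse = ", "))
  fmt <- toupper(tools::file_ext(path))
  if (!fmt %in% c("PDB", "PDBQT")) stop("receptor path must be .pdb/.pdbqt")
  lines <- vapply(seq_len(nrow(atoms)), function(k)
    format_pdb_atom_line(atoms, k, record = "ATOM",
                         pdbqt = identical(fmt, "PDBQT")), character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# direct-arithmetic truth evaluation of one placed molecule against the
# resolved filters; independent of the engine's matcher
fixture_truth_verdict <- function(xyz, tmpl, filters, mode, format) {
  margins <- numeric(length(filters))
  pass <- logical(length(filters))
  for (k in seq_along(filters)) {
    f <- filters[[k]]
    ft <- NULL
    for (cand in tmpl$features)
      if (identical(cand$smarts, f$smarts) &&
            feature_visible(cand, mode, format)) { ft <- cand; break }
    if (is.null(ft)) {
      pass[k] <- f$exclude
      margins[k] <- Inf
    } else {
      d <- sqrt(min(rowSums(
        sweep(xyz[ft$atoms, , drop = FALSE], 2, f$query_point)^2)))
      within <- d <= f$cutoff
      pass[k] <- if (f$exclude) !within else within
      margins[k] <- abs(d - f$cutoff)
    }
  }
  list(pass_all = all(pass), pass = pass, margin = min(margins))
}

place_pose <- function(tmpl, filters, want_pass, mode, format,
                       noise_sd, max_tries = 300L) {
  diam <- template_diameter(tmpl)
  governing <- filters[[1L]]
  gov_ft <- NULL
  for (cand in tmpl$features)
    if (identical(cand$smarts, governing$smarts) &&
          feature_visible(cand, mode, format)) { gov_ft <- cand; break }
  for (try in seq_len(max_tries)) {
    rot <- random_rotation()
    xyz <- tmpl$coords %*% t(rot)
    if (is.null(gov_ft)) {
      # governing substructure absent: location barely matters; drop the
      # molecule a safe distance from every query point
      centre <- governing$query_point +
        (governing$cutoff + diam + 3) * rand_unit()
      xyz <- sweep(xyz, 2, centre - colMeans(xyz), "+")
    } else {
      inside_wanted <- want_pass != governing$exclude
      d <- if (inside_wanted) {
        lo <- 0.3; hi <- governing$cutoff - 0.3
        if (hi < lo)
          stop("infeasible fixture geometry: cutoff ", governing$cutoff,
               " A leaves no room inside the pass margin")
        stats::runif(1, lo, hi)
      } else {
        stats::runif(1, governing$cutoff + 0.5 + diam,
                     governing$cutoff + 3 + diam)
      }
      anchor <- gov_ft$atoms[1L]
      shift <- governing$query_point + d * rand_unit() - xyz[anchor, ]
      xyz <- sweep(xyz, 2, shift, "+")
    }
    if (noise_sd > 0) {
      jit <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_sd),
                          nrow(xyz))
    } else jit <- xyz
    v <- fixture_truth_verdict(jit, tmpl, filters, mode, format)
    if (v$pass_all == want_pass && v$margin >= 0.2) return(jit)
    v0 <- fixture_truth_verdict(xyz, tmpl, filters, mode, format)
    if (v0$pass_all == want_pass && v0$margin >= 0.2) return(xyz)
  }
  stop("could not construct a ", if (want_pass) "passing" else "failing",
       " pose for template '", tmpl$smiles, "' after ", max_tries,
       " attempts (infeasible filter geometry?)")
}

#' Generate a directory of docked-pose fixtures with known ground truth
#'
#' Builds one multi-pose compound file per compound, cycling through the
#' requested formats, each with a `.smi` SMILES companion. A designed
#' fraction of compounds passes all filters; pass compounds get a seeded
#' subset of passing pose indices (often excluding pose 1, so that
#' "only a lower-ranked pose passes" cases are represented), fail
#' compounds fail either by lacking the substructure or by geometry.
#' The ground-truth table is computed by direct arithmetic on the placed
#' coordinates, independently of the screening engine.
#'
#' @param spec a `FixtureSpec`.
#' @param dir output directory (created; default a fresh tempdir).
#' @return list with `receptor_path`, `compounds_dir`, `filters_path`,
#'   `truth` (data.frame `file`, `format`, `template`, `expected_pass`,
#'   `passing_poses` as comma-joined indices), `spec`.
#' @export
make_pose_fixtures <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"))
  if (is.null(dir)) dir <- tempfile("fixtures")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  compounds_dir <- file.path(dir, "compounds")
  dir.create(compounds_dir, showWarnings = FALSE)
  receptor_path <- file.path(dir, "receptor.pdb")
  make_receptor_fixture(receptor_path)
  defs <- if (is.null(spec$filters)) default_fixture_filters()
  else spec$filters
  filters_path <- file.path(dir, "filters.json")
  write_filters(defs, filters_path)
  receptor <- read_receptor(receptor_path)
  filters <- lapply(defs, resolve_query_point, receptor = receptor)
  templates <- fixture_templates()
  include_smarts <- vapply(
    filters[!vapply(filters, `[[`, logical(1), "exclude")],
    `[[`, character(1), "smarts")
  pass_pool <- names(templates)[vapply(templates, function(t)
    all(vapply(include_smarts, function(s) template_has_feature(t, s),
               logical(1))), logical(1))]
  if (length(pass_pool) == 0L)
    stop("no fixture template contains all required substructures: ",
         paste(include_smarts, collapse = ", "))
  set.seed(spec$seed)
  n <- spec$n_compounds
  n_pass <- round(spec$fraction_pass * n)
  pass_flags <- rep(FALSE, n)
  if (n_pass > 0) pass_flags[sample.int(n, n_pass)] <- TRUE
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fmt <- spec$formats[((i - 1L) %% length(spec$formats)) + 1L]
    want_pass <- pass_flags[i]
    tname <- if (want_pass) {
      pass_pool[sample.int(length(pass_pool), 1L)]
    } else {
      # fail by absence when a lacking template exists and a coin says so,
      # otherwise fail by geometry
      lack <- setdiff(names(templates), pass_pool)
      if (length(lack) && stats::runif(1) < 0.5)
        lack[sample.int(length(lack), 1L)]
      else pass_pool[sample.int(length(pass_pool), 1L)]
    }
    tmpl <- templates[[tname]]
    np <- spec$poses_per_compound
    pass_poses <- integer()
    if (want_pass) {
      k <- sample.int(np, 1L)            # how many poses pass
      pass_poses <- sort(sample.int(np, k))
      if (np > 1L && length(pass_poses) < np && stats::runif(1) < 0.5) {
        # force the "only a non-top pose passes" shape
        k2 <- min(length(pass_poses), np - 1L)
        pass_poses <- sort((2:np)[sample.int(np - 1L, k2)])
      }
    }
    poses <- vector("list", np)
    for (p in seq_len(np)) {
      pose_pass <- p %in% pass_poses
      xyz <- place_pose(tmpl, filters, pose_pass, spec$mode, fmt,
                        spec$geometry_noise)
      atoms <- data.frame(
        serial = seq_along(tmpl$elements),
        name = paste0(tmpl$elements, seq_along(tmpl$elements)),
        element = tmpl$elements,
        x = round(xyz[, 1], 3), y = round(xyz[, 2], 3),
        z = round(xyz[, 3], 3),
        chain = "", resid = 1L, resname = "LIG",
        is_hydrogen = FALSE, stringsAsFactors = FALSE)
      poses[[p]] <- new_pose_record(atoms, tmpl$bonds, p, "", fmt)
    }
    fname <- sprintf("cmpd_%04d.%s", i, tolower(fmt))
    fpath <- file.path(compounds_dir, fname)
    write_poses(poses, fpath, format = fmt)
    if (fmt %in% c("PDB", "PDBQT"))
      writeLines(tmpl$smiles, paste0(fpath, ".smi"))
    rows[[i]] <- data.frame(
      file = fname, format = fmt, template = tname,
      expected_pass = want_pass,
      passing_poses = paste(pass_poses, collapse = ","),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  utils::write.table(truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(receptor_path = receptor_path, compounds_dir = compounds_dir,
       filters_path = filters_path, truth = truth, spec = spec)
}

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a labelled ranked library
#'
#' Deterministic synthetic library for the metrics module, sized by
#' default like a typical benchmark screen (1561 compounds, 46 positive
#' controls).
#'
#' @param seed RNG seed.
#' @param T library size.
#' @param P_T number of positive controls.
#' @param placement `"random"` (uniform positive ranks), `"rescue"` (the
#'   top ranks are decoys that fail the filters while the positives sit
#'   just below and pass, so filter-to-bottom re-ranking provably raises
#'   the early enrichment), or an integer vector of the ranks the
#'   positives occupy.
#' @param pass_fraction for `"random"` placement, probability that a
#'   compound passes the filters.
#' @return `RankedLibrary`.
#' @export
make_ranked_library_fixture <- function(seed = 1L, T = 1561L, P_T = 46L,
                                        placement = "random",
                                        pass_fraction = 1) {
  stopifnot(P_T <= T, P_T >= 1L)
  set.seed(as.integer(seed))
  ids <- sprintf("cmpd%05d", seq_len(T))
  score <- -15 + 0.005 * seq_len(T)      # already in rank order
  pos <- rep(FALSE, T)
  passed <- rep(TRUE, T)
  if (is.numeric(placement)) {
    placement <- as.integer(placement)
    if (length(placement) != P_T || any(placement < 1L | placement > T))
      stop("positive placement must give P_T ranks within [1, T]")
    pos[placement] <- TRUE
    if (pass_fraction < 1) passed <- stats::runif(T) < pass_fraction
  } else if (identical(placement, "random")) {
    pos[sample.int(T, P_T)] <- TRUE
    if (pass_fraction < 1) passed <- stats::runif(T) < pass_fraction
  } else if (identical(placement, "rescue")) {
    n_block <- min(10L, T - P_T)
    pos[(n_block + 1L):(n_block + P_T)] <- TRUE
    passed[seq_len(n_block)] <- FALSE
  } else stop("unknown placement: ", placement)
  ranked_library(ids, score, pos, passed)
}
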
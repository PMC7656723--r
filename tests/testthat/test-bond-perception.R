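test_that("geometric inference follows the covalent-radius rule", {
  # C radius 0.76, tolerance 0.45: threshold 1.97 for a C-C pair
  near <- toy_pose(c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)))
  g <- infer_bonds_geometric(near)
  expect_equal(nrow(g$bonds), 1L)
  expect_equal(g$bonds$order, "single")
  expect_identical(g$provenance, "geometric")
  far <- toy_pose(c("C", "C"), rbind(c(0, 0, 0), c(3.00, 0, 0)))
  expect_equal(nrow(infer_bonds_geometric(far)$bonds), 0L)
  lone <- toy_pose("C", matrix(0, 1, 3))
  expect_equal(nrow(infer_bonds_geometric(lone)$bonds), 0L)
})

test_that("coincident atoms are artifacts, not bonds", {
  p <- toy_pose(c("C", "C"), rbind(c(0, 0, 0), c(0.1, 0, 0)))
  expect_equal(nrow(infer_bonds_geometric(p)$bonds), 0L)
})

test_that("unknown elements draw a warning and get no bonds", {
  p <- toy_pose(c("C", "Xx"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_warning(g <- infer_bonds_geometric(p), "covalent radius")
  expect_equal(nrow(g$bonds), 0L)
})

test_that("geometric inference is invariant under atom permutation", {
  tpl <- fixture_templates()$tetrahydropyran
  set.seed(42)
  for (rep in 1:5) {
    perm <- sample(length(tpl$elements))
    g0 <- infer_bonds_geometric(toy_pose(tpl$elements, tpl$coords))
    gp <- infer_bonds_geometric(toy_pose(tpl$elements[perm],
                                         tpl$coords[perm, , drop = FALSE]))
    canon <- function(g, map = seq_len(nrow(g$atoms))) {
      e <- cbind(map[g$bonds$i], map[g$bonds$j])
      sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    }
    inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
    # mapping permuted indices back must recover the original edge set
    expect_equal(canon(gp, map = perm), canon(g0))
  }
})

test_that("scaling coordinates by 10 destroys all inferred bonds", {
  tpl <- fixture_templates()$ethanolamine
  g <- infer_bonds_geometric(toy_pose(tpl$elements, tpl$coords))
  expect_gt(nrow(g$bonds), 0L)
  g10 <- infer_bonds_geometric(toy_pose(tpl$elements, tpl$coords * 10))
  expect_equal(nrow(g10$bonds), 0L)
})

test_that("SMILES template maps bond orders onto pose heavy atoms", {
  bz <- fixture_templates()$benzene
  pose <- toy_pose(bz$elements, bz$coords)
  g <- bonds_from_smiles_template(pose, "c1ccccc1")
  expect_identical(g$provenance, "smiles_template")
  expect_equal(sum(g$bonds$order == "aromatic"), 6L)
  eth <- fixture_templates()$ethanol
  g2 <- bonds_from_smiles_template(toy_pose(eth$elements, eth$coords), "CCO")
  expect_equal(sort(g2$bonds$order), c("single", "single"))
})

test_that("template failures fall back to geometric bonds with a warning", {
  eth <- fixture_templates()$ethanol
  pose <- toy_pose(eth$elements, eth$coords)
  expect_warning(g <- bonds_from_smiles_template(pose, "CCCCC"),
                 "mismatch")
  expect_identical(g$provenance, "geometric")
  expect_warning(g2 <- bonds_from_smiles_template(pose, "C1CC"),
                 "failed to parse")
  expect_identical(g2$provenance, "geometric")
})

test_that("single-bond molecules get identical graphs from both routes", {
  for (nm in c("ethanol", "ethanolamine", "propane", "tetrahydropyran")) {
    tpl <- fixture_templates()[[nm]]
    pose <- toy_pose(tpl$elements, tpl$coords)
    geo <- infer_bonds_geometric(pose)
    smi <- bonds_from_smiles_template(pose, tpl$smiles)
    canon <- function(g) {
      b <- g$bonds
      sort(paste(pmin(b$i, b$j), pmax(b$i, b$j), b$order))
    }
    expect_identical(smi$provenance, "smiles_template")
    expect_equal(canon(smi), canon(geo), info = nm)
  }
})

test_that("SDF poses never pass through geometric inference", {
  bz <- fixture_templates()$benzene
  pose <- toy_pose(bz$elements, bz$coords, bz$bonds, format = "SDF")
  for (mode in c("NONE", "SMILES", "OPENBABEL")) {
    g <- graph_from_pose(pose, mode = mode)
    expect_identical(g$provenance, "sdf_block", info = mode)
    expect_equal(sum(g$bonds$order == "aromatic"), 6L, info = mode)
  }
})

test_that("external-tool contract: success, heavy-atom retry, and failure", {
  eth <- fixture_templates()$ethanol
  pose_file <- tempfile(fileext = ".pdbqt")
  write_poses(toy_pose(eth$elements, eth$coords), pose_file)
  good <- tempfile(fileext = ".sdf")
  write_poses(toy_pose(eth$elements, eth$coords, eth$bonds, format = "SDF"),
              good)
  bad <- tempfile(fileext = ".sdf")    # wrong heavy atoms
  write_poses(toy_pose(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                       data.frame(i = 1L, j = 2L, order = "single"),
                       format = "SDF"), bad)

  g <- bonds_from_external_tool(pose_file,
                                make_stub_converter("ok", good_sdf = good))
  expect_identical(g$provenance, "external_tool")
  expect_equal(nrow(g$bonds), 2L)

  g2 <- bonds_from_external_tool(
    pose_file, make_stub_converter("retry", good_sdf = good, bad_sdf = bad))
  expect_identical(g2$provenance, "external_tool")
  expect_equal(sort(g2$atoms$element), sort(eth$elements))

  expect_error(
    bonds_from_external_tool(pose_file, make_stub_converter("fail")),
    "failed")
})

test_that("molecular_graph enforces its invariants", {
  atoms <- toy_atoms(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_error(molecular_graph(
    atoms, data.frame(i = 1L, j = 1L, order = "single"), "geometric"),
    "self-bond")
  expect_error(molecular_graph(
    atoms, data.frame(i = c(1L, 2L), j = c(2L, 1L),
                      order = "single"), "geometric"),
    "duplicate")
  expect_error(molecular_graph(
    atoms, data.frame(i = 1L, j = 2L, order = "double"), "geometric"),
    "single")
})
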
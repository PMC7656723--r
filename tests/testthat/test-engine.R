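test_that("evaluate_filter reproduces the six-row truth table exactly", {
  cutoff <- 5.5
  cases <- expand.grid(has = c(FALSE, TRUE), exclude = c(FALSE, TRUE),
                       within = c(FALSE, TRUE))
  # expected results: absent substructure ignores 'within'
  expected <- function(has, exclude, within) {
    if (!has) return(exclude)          # rows 1-2
    if (!exclude) return(within)       # rows 3-4
    !within                            # rows 5-6
  }
  for (k in seq_len(nrow(cases))) {
    cs <- cases[k, ]
    f <- simple_coordinate_filter("[#8]", cutoff, c(0, 0, 0),
                                  exclude = cs$exclude)
    v <- evaluate_filter(engine_case_graph(cs$has, cs$within), f)
    expect_identical(v$passed, expected(cs$has, cs$exclude, cs$within),
                     info = sprintf("has=%s exclude=%s within=%s",
                                    cs$has, cs$exclude, cs$within))
    expect_identical(v$has_substructure, cs$has)
    if (cs$has) {
      expect_identical(v$within_cutoff, cs$within)
      expect_equal(v$min_distance, if (cs$within) 4.9 else 8.0,
                   tolerance = 1e-9)
    } else {
      expect_true(is.na(v$within_cutoff))
    }
  }
})

test_that("exclude is the logical dual when the substructure is present", {
  for (within in c(TRUE, FALSE)) {
    g <- engine_case_graph(TRUE, within)
    keep <- evaluate_filter(g, simple_coordinate_filter("[#8]", 5.5))
    drop <- evaluate_filter(g, simple_coordinate_filter("[#8]", 5.5,
                                                        exclude = TRUE))
    expect_identical(drop$passed, !keep$passed)
  }
  # absent substructure: both rows stated explicitly, not a negation pair
  g0 <- engine_case_graph(FALSE, TRUE)
  expect_false(evaluate_filter(g0, simple_coordinate_filter("[#8]", 5.5))$passed)
  expect_true(evaluate_filter(
    g0, simple_coordinate_filter("[#8]", 5.5, exclude = TRUE))$passed)
})

test_that("passing is monotone in the cutoff (reversed for exclude)", {
  g <- engine_case_graph(TRUE, TRUE)   # matched O at 4.9
  cutoffs <- c(3, 4.8, 5.0, 6, 10, 50)
  keep <- vapply(cutoffs, function(cf)
    evaluate_filter(g, simple_coordinate_filter("[#8]", cf))$passed,
    logical(1))
  expect_identical(keep, cutoffs >= 4.9)
  drop <- vapply(cutoffs, function(cf)
    evaluate_filter(g, simple_coordinate_filter("[#8]", cf,
                                                exclude = TRUE))$passed,
    logical(1))
  expect_identical(drop, !keep)
})

test_that("min_distance equals an exhaustive scan on random atoms", {
  set.seed(99)
  xyz <- matrix(stats::runif(150, -10, 10), 50, 3)
  g <- toy_graph(rep("O", 50), xyz, empty_bond_table())
  q <- c(1, -2, 3)
  sets <- match_substructure(g, "[#8]")
  expect_length(sets, 50L)
  brute <- min(sqrt(rowSums(sweep(xyz, 2, q)^2)))
  expect_equal(min_distance(sets, g, q), brute, tolerance = 1e-12)
  # coincident and two-atom cases
  g1 <- toy_graph("O", matrix(q, 1, 3), empty_bond_table())
  expect_equal(min_distance(list(1L), g1, q), 0)
  g2 <- toy_graph(c("O", "O"), rbind(q + c(4.9, 0, 0), q + c(6.2, 0, 0)),
                  empty_bond_table())
  expect_equal(min_distance(list(1L, 2L), g2, q), 4.9)
})

test_that("the empty filter list passes every parseable compound", {
  g <- engine_case_graph(FALSE, FALSE)
  expect_true(evaluate_pose(g, list())$passed)
})

test_that("conjunction: one failing filter fails the pose", {
  g <- engine_case_graph(TRUE, TRUE)
  pass_f <- simple_coordinate_filter("[#8]", 5.5)
  fail_f <- simple_coordinate_filter("[#7]", 5.5)   # no N present
  expect_true(evaluate_pose(g, list(pass_f, pass_f))$passed)
  expect_false(evaluate_pose(g, list(pass_f, fail_f, pass_f))$passed)
})

test_that("engine verdicts equal the brute-force evaluator on seeded poses", {
  fx <- make_pose_fixtures(fixture_spec(seed = 21, n_compounds = 70,
                                        poses_per_compound = 3))
  filt <- resolve_query_point(load_filters(fx$filters_path)[[1]],
                              read_receptor(fx$receptor_path))
  files <- list.files(fx$compounds_dir, full.names = TRUE)
  files <- files[!grepl("\\.smi$", files)]
  n_checked <- 0L
  for (f in files) {
    for (pose in read_poses(f)) {
      if (n_checked >= 200L) break
      g <- graph_from_pose(pose, mode = "NONE")
      engine <- evaluate_filter(g, filt)$passed
      oracle <- brute_force_filter_verdict(g, filt$smarts,
                                           filt$query_point, filt$cutoff,
                                           filt$exclude)
      expect_identical(engine, oracle, info = basename(f))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 200L)
})

test_that("run_screen recovers designed verdicts and logs corrupt files as skips", {
  fx <- make_pose_fixtures(fixture_spec(seed = 5, n_compounds = 20,
                                        poses_per_compound = 2,
                                        fraction_pass = 0.5))
  # salt the directory with corrupt files
  writeLines("%%% not a molecule %%%", file.path(fx$compounds_dir, "bad1.pdbqt"))
  writeLines("garbage", file.path(fx$compounds_dir, "bad2.sdf"))
  out <- tempfile()
  warns <- capture_warnings(
    res <- run_screen(fx$receptor_path, fx$compounds_dir, fx$filters_path,
                      out = out))
  expect_equal(sum(grepl("skipping", warns)), 2L)
  expect_equal(res$counts[["seen"]], 22L)
  expect_equal(res$counts[["skipped"]], 2L)
  expect_setequal(res$skipped$file, c("bad1.pdbqt", "bad2.sdf"))
  expect_identical(readLines(out),
                   sort(fx$truth$file[fx$truth$expected_pass]))
  expect_equal(res$counts[["seen"]],
               res$counts[["passed"]] + res$counts[["failed"]] +
                 res$counts[["skipped"]])
})

test_that("per-pose passing indices match the designed ground truth", {
  fx <- make_pose_fixtures(fixture_spec(seed = 9, n_compounds = 15,
                                        poses_per_compound = 4,
                                        fraction_pass = 0.6))
  res <- run_screen(fx$receptor_path, fx$compounds_dir, fx$filters_path)
  tp <- fx$truth[fx$truth$expected_pass, ]
  for (k in seq_len(nrow(tp))) {
    expect_identical(paste(res$passed[[tp$file[k]]], collapse = ","),
                     tp$passing_poses[k], info = tp$file[k])
  }
  # at least one compound passes only through a non-top pose
  only_lower <- !grepl("^1(,|$)", tp$passing_poses)
  expect_true(any(only_lower))
})

test_that("worker count does not change the output (determinism contract)", {
  fx <- make_pose_fixtures(fixture_spec(seed = 13, n_compounds = 12))
  o1 <- tempfile(); o4 <- tempfile()
  run_screen(fx$receptor_path, fx$compounds_dir, fx$filters_path,
             out = o1, jobs = 1)
  run_screen(fx$receptor_path, fx$compounds_dir, fx$filters_path,
             out = o4, jobs = 4)
  expect_identical(readLines(o1), readLines(o4))
  expect_identical(readLines(o1), sort(readLines(o1), method = "radix"))
})

test_that("the verbose sidecar reports per-pose per-filter distances", {
  fx <- make_pose_fixtures(fixture_spec(seed = 2, n_compounds = 6))
  sc <- tempfile(fileext = ".tsv")
  run_screen(fx$receptor_path, fx$compounds_dir, fx$filters_path,
             sidecar = sc)
  det <- read.delim(sc)
  expect_setequal(names(det), c("file", "pose_index", "filter_label",
                                "min_distance", "verdict"))
  expect_true(all(det$verdict %in% c("Pass", "Fail")))
  expect_equal(nrow(det), 6 * 3)   # 6 files x 3 poses x 1 filter
})
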
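test_that("enrichment factor closed forms hold", {
  lib <- make_ranked_library_fixture(seed = 1, T = 200, P_T = 10,
                                     placement = "random")
  # EF at n = T is exactly 1, whatever the placement
  expect_equal(enrichment_factor(lib, 200), 1)
  # top n all positives: EF_n = T / P_T
  top <- make_ranked_library_fixture(seed = 1, T = 200, P_T = 10,
                                     placement = 1:10)
  expect_equal(enrichment_factor(top, 10), 200 / 10)
  expect_equal(enrichment_factor(top, 5), 200 / 10)   # P_n = n cancels
  expect_error(enrichment_factor(top, 0), "n must be")
  expect_error(enrichment_factor(top, 201), "n must be")
})

test_that("EF matches direct arithmetic at benchmark-screen scale", {
  # 5 of 46 positives in the top 10 of a 1561-compound screen
  lib <- make_ranked_library_fixture(seed = 1, T = 1561, P_T = 46,
                                     placement = c(1:5, 100:140))
  expect_equal(top_n_hits(lib, 10), 5L)
  expect_equal(enrichment_factor(lib, 10), 5 / (10 * 46 / 1561))
  expect_equal(enrichment_factor(lib, 10), 16.96739, tolerance = 1e-6)
})

test_that("top_n_hits is a direct scan with the documented bounds", {
  set.seed(7)
  for (rep in 1:20) {
    T_tot <- sample(50:300, 1)
    P_T <- sample(5:20, 1)
    ranks <- sort(sample(T_tot, P_T))
    lib <- make_ranked_library_fixture(seed = rep, T = T_tot, P_T = P_T,
                                       placement = ranks)
    n <- sample(T_tot, 1)
    expect_equal(top_n_hits(lib, n), sum(ranks <= n))
    expect_lte(top_n_hits(lib, n), min(n, P_T))
  }
})

test_that("percentile ranks follow the 100*r/T convention", {
  lib <- make_ranked_library_fixture(seed = 1, T = 100, P_T = 5,
                                     placement = 1:5)
  pct <- percentile_ranks(lib)
  expect_equal(unname(pct[1]), 1)
  expect_equal(unname(pct[100]), 100)
  expect_equal(unname(pct[50]), 50)
  odd <- make_ranked_library_fixture(seed = 1, T = 99, P_T = 5,
                                     placement = 1:5)
  expect_equal(unname(percentile_ranks(odd)[50]), 100 * 50 / 99)
})

test_that("filter-to-bottom re-ranking is a stable partition", {
  # alternating pass/fail of 6: passers first in order, then failers
  lib <- ranked_library(letters[1:6], 1:6, rep(FALSE, 6),
                        passed_filters = c(TRUE, FALSE, TRUE, FALSE, TRUE,
                                           FALSE))
  out <- apply_filter_to_ranking(lib)
  expect_equal(out$compound_id, c("a", "c", "e", "b", "d", "f"))
  # all pass: identity
  lib2 <- ranked_library(letters[1:6], 1:6, rep(FALSE, 6))
  expect_equal(apply_filter_to_ranking(lib2)$compound_id, letters[1:6])
})

test_that("re-ranking conserves compounds and is idempotent (property)", {
  set.seed(123)
  for (rep in 1:200) {
    T_tot <- sample(20:120, 1)
    P_T <- sample(2:10, 1)
    lib <- make_ranked_library_fixture(seed = rep, T = T_tot, P_T = P_T,
                                       placement = "random",
                                       pass_fraction = runif(1, 0.2, 0.9))
    out <- apply_filter_to_ranking(lib)
    expect_setequal(out$compound_id, lib$compound_id)
    expect_equal(attr(out, "T"), attr(lib, "T"))
    expect_equal(attr(out, "P_T"), attr(lib, "P_T"))
    again <- apply_filter_to_ranking(out)
    expect_identical(again$compound_id, out$compound_id)
    # survivors keep their relative order
    surv <- lib$compound_id[lib$passed_filters]
    expect_identical(out$compound_id[seq_along(surv)], surv)
  }
})

test_that("mean EF over shuffled libraries converges to 1", {
  efs <- vapply(1:300, function(s) {
    lib <- make_ranked_library_fixture(seed = s, T = 150, P_T = 15,
                                       placement = "random")
    enrichment_factor(lib, 15)
  }, numeric(1))
  # se of the mean ~ sqrt(var/n); EF_15 has sd ~ 0.25 here
  expect_lt(abs(mean(efs) - 1), 0.1)
})

test_that("a designed rescue library improves early enrichment after filtering", {
  lib <- make_ranked_library_fixture(seed = 4, T = 300, P_T = 12,
                                     placement = "rescue")
  before <- enrichment_factor(lib, 10)
  after <- enrichment_factor(apply_filter_to_ranking(lib), 10)
  expect_gt(after, before)
})

test_that("ranked libraries round-trip through TSV", {
  lib <- make_ranked_library_fixture(seed = 2, T = 40, P_T = 4,
                                     placement = "random",
                                     pass_fraction = 0.7)
  f <- tempfile(fileext = ".tsv")
  write.table(as.data.frame(lib), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_ranked_library(f)
  expect_equal(back$compound_id, lib$compound_id)
  expect_equal(attr(back, "P_T"), attr(lib, "P_T"))
  expect_equal(back$passed_filters, lib$passed_filters)
})

test_that("score ties break lexicographically by compound id", {
  lib <- ranked_library(c("zeta", "alpha", "mid"), c(1, 1, 0),
                        c(FALSE, TRUE, FALSE))
  expect_equal(lib$compound_id, c("mid", "alpha", "zeta"))
})

test_that("metrics table reports before/after-filter columns", {
  lib <- make_ranked_library_fixture(seed = 4, T = 300, P_T = 12,
                                     placement = "rescue")
  tab <- vs_metrics_table(lib)
  expect_equal(tab$depth, c(10L, 20L, 40L))
  expect_true(all(c("ef", "ef_filtered") %in% names(tab)))
  expect_gt(tab$ef_filtered[1], tab$ef[1])
})
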
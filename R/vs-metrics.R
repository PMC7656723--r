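# Virtual-screening performance measures on ranked, labelled compound
# libraries: enrichment factors EF_n = P_n / (n * P_T / T), top-n hit
# counts, percentile ranks, and the filter-to-bottom re-ranking used to
# score a screen after pose filtering.

#' Construct a ranked compound library
#'
#' Compounds are ordered best-score-first. Scores follow the docking
#' convention that more negative is better; ties are broken
#' lexicographically by `compound_id` so rankings are reproducible.
#'
#' @param compound_id character vector of unique compound names.
#' @param score numeric docking scores (lower = better).
#' @param is_positive logical: known-ligand (positive-control) flag.
#' @param passed_filters logical: did the compound pass the pose filters
#'   (default `TRUE`, i.e. an unfiltered screen).
#' @return `RankedLibrary`: data.frame sorted best-first, with attributes
#'   `T` (library size) and `P_T` (number of positives).
#' @export
ranked_library <- function(compound_id, score, is_positive,
                           passed_filters = TRUE) {
  stopifnot(length(score) == length(compound_id),
            length(is_positive) == length(compound_id))
  if (anyDuplicated(compound_id)) stop("compound ids must be unique")
  df <- data.frame(compound_id = as.character(compound_id),
                   score = as.numeric(score),
                   is_positive = as.logical(is_positive),
                   passed_filters = rep_len(as.logical(passed_filters),
                                            length(compound_id)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$score, df$compound_id, method = "radix"), ]
  rownames(df) <- NULL
  structure(df, class = c("RankedLibrary", "data.frame"),
            T = nrow(df), P_T = sum(df$is_positive))
}

#' @export
print.RankedLibrary <- function(x, ...) {
  cat(sprintf("RankedLibrary: %d compounds, %d positives\n",
              attr(x, "T"), attr(x, "P_T")))
  NextMethod()
}

#' Read a ranked library from TSV/CSV
#'
#' Expects columns `compound_id`, `score`, `is_positive` and optionally
#' `passed_filters` (tab- or comma-separated, chosen by extension).
#' @param path input file.
#' @return `RankedLibrary`.
#' @export
read_ranked_library <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("compound_id", "score", "is_positive")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ranked_library(df$compound_id, df$score, as.logical(df$is_positive),
                 if ("passed_filters" %in% names(df))
                   as.logical(df$passed_filters) else TRUE)
}

#' Enrichment factor of the top-n ranked compounds
#'
#' `EF_n = P_n / (n * P_T / T)`: the number of positive controls among the
#' top n, divided by the number expected under random ordering. `EF_T` is
#' always exactly 1; when the top n are all positives (and `n <= P_T`),
#' `EF_n = T / P_T`, the maximum attainable value.
#'
#' @param lib a `RankedLibrary`.
#' @param n number of top-ranked compounds to consider, `1 <= n <= T`.
#' @return dimensionless enrichment factor.
#' @examples
#' lib <- ranked_library(sprintf("c%04d", 1:100), 1:100,
#'                       c(rep(TRUE, 5), rep(FALSE, 95)))
#' enrichment_factor(lib, 10)  # 5 positives in top 10 of 100: EF = 10
#' @export
enrichment_factor <- function(lib, n) {
  stopifnot(inherits(lib, "RankedLibrary"))
  T_tot <- attr(lib, "T"); P_T <- attr(lib, "P_T")
  if (P_T == 0L) stop("library has no positive controls")
  n <- as.integer(n)
  if (n < 1L || n > T_tot) stop("n must be in [1, ", T_tot, "]")
  P_n <- sum(lib$is_positive[seq_len(n)])
  P_n / (n * P_T / T_tot)
}

#' Count positive controls in the top n
#'
#' @inheritParams enrichment_factor
#' @return integer in `[0, min(n, P_T)]`.
#' @export
top_n_hits <- function(lib, n) {
  stopifnot(inherits(lib, "RankedLibrary"))
  n <- as.integer(n)
  if (n < 1L || n > attr(lib, "T"))
    stop("n must be in [1, ", attr(lib, "T"), "]")
  sum(lib$is_positive[seq_len(n)])
}

#' Percentile ranks of all compounds
#'
#' Rank r (1-based, best = 1) maps to `100 * r / T`: the percentage of the
#' library at or above that rank, so "ranked in the top 40%" means a
#' percentile rank of at most 40.
#'
#' @param lib a `RankedLibrary`.
#' @return named numeric vector, compound_id -> percentile.
#' @export
percentile_ranks <- function(lib) {
  stopifnot(inherits(lib, "RankedLibrary"))
  T_tot <- attr(lib, "T")
  stats::setNames(100 * seq_len(T_tot) / T_tot, lib$compound_id)
}

#' Move compounds that failed the pose filters to the bottom
#'
#' A stable partition on `passed_filters`: survivors keep their relative
#' order at the top of the ranking, non-passing compounds follow (whether
#' positive controls or decoys), also in their original relative order.
#' `T` and `P_T` are unchanged, and the operation is idempotent.
#'
#' @param lib a `RankedLibrary` with `passed_filters` populated.
#' @return re-ordered `RankedLibrary`.
#' @export
apply_filter_to_ranking <- function(lib) {
  stopifnot(inherits(lib, "RankedLibrary"))
  df <- rbind(lib[lib$passed_filters, , drop = FALSE],
              lib[!lib$passed_filters, , drop = FALSE])
  rownames(df) <- NULL
  structure(df, class = c("RankedLibrary", "data.frame"),
            T = attr(lib, "T"), P_T = attr(lib, "P_T"))
}

#' Summary metrics table for a ranked library
#'
#' Computes EF and hit counts at the conventional reporting depths
#' (top 10, 20, 40 by default), before and — when `passed_filters` is
#' informative — after filter-to-bottom re-ranking.
#'
#' @param lib a `RankedLibrary`.
#' @param depths integer vector of ranking depths.
#' @return data.frame with columns `depth`, `hits`, `ef`, and (when any
#'   compound failed the filters) `hits_filtered`, `ef_filtered`.
#' @export
vs_metrics_table <- function(lib, depths = c(10L, 20L, 40L)) {
  stopifnot(inherits(lib, "RankedLibrary"))
  depths <- depths[depths <= attr(lib, "T")]
  out <- data.frame(
    depth = depths,
    hits = vapply(depths, function(n) top_n_hits(lib, n), integer(1)),
    ef = vapply(depths, function(n) enrichment_factor(lib, n), numeric(1)))
  if (any(!lib$passed_filters)) {
    flib <- apply_filter_to_ranking(lib)
    out$hits_filtered <- vapply(depths, function(n) top_n_hits(flib, n),
                                integer(1))
    out$ef_filtered <- vapply(depths, function(n)
      enrichment_factor(flib, n), numeric(1))
  }
  out
}
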
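# Statistical core: one-sided hypergeometric over-representation of the
# query (predicted regulators) in each catalog set, with fold/percent and
# Bonferroni / Benjamini-Hochberg correction over the tested family.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at least
#' `k` marked elements when `n` elements are drawn without replacement from a
#' population of `N` containing `K` marked ones. Computed through the
#' survival function so values down to ~1e-300 are representable; never
#' returns exactly 0 (floored at the smallest positive double).
#'
#' @param N Population (universe) size.
#' @param K Number of marked elements (set size within the universe).
#' @param n Number of draws (query size).
#' @param k Observed overlap. Vectorized with recycling.
#' @return Probability in (0, 1].
#' @export
#' @examples
#' hypergeom_upper_tail(10, 4, 3, 2)
hypergeom_upper_tail <- function(N, K, n, k) {
  len <- max(length(N), length(K), length(n), length(k))
  if (len == 0L) return(numeric(0))
  N <- rep_len(as.numeric(N), len)
  K <- rep_len(as.numeric(K), len)
  n <- rep_len(as.numeric(n), len)
  k <- rep_len(as.numeric(k), len)
  ok <- !is.na(N) & !is.na(K) & !is.na(n) & !is.na(k) &
    N == floor(N) & K == floor(K) & n == floor(n) & k == floor(k) &
    K >= 0 & K <= N & n >= 0 & n <= N & k >= 0 & k <= pmin(n, K) & N >= 0
  if (any(!ok)) {
    mirsets_abort(
      "hypergeometric bounds violated: need 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(n, K)",
      class = "mirsets_domain_error"
    )
  }
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pmin(1, pmax(p, .Machine$double.xmin))
}

#' Enrichment statistics for one miRNA set
#'
#' Intersects both the query and the set with the background universe, then
#' computes the overlap `count` (k), `set_size` (K), `percent` (100 k / K),
#' `expected` (n K / N), `fold` (k / expected; undefined when the expected
#' count is 0) and the upper-tail hypergeometric `p_value`. Correction
#' columns are left to [run_enrichment()], which knows the tested family.
#'
#' @param query Character vector of miRNA ids (the predicted regulators).
#' @param set_members Character vector of miRNA ids in the tested set.
#' @param universe Character vector: the background population.
#' @param set_name,category Labels copied into the record.
#' @return One-row tibble, or a zero-row tibble (with a warning) when the
#'   set has no members inside the universe and is therefore untestable.
#' @export
enrichment_record <- function(query, set_members, universe,
                              set_name = "set", category = NA_character_) {
  universe <- unique(universe)
  N <- length(universe)
  if (N < 1L) {
    mirsets_abort("`universe` must be non-empty", class = "mirsets_domain_error")
  }
  q <- intersect(unique(query), universe)
  members <- intersect(unique(set_members), universe)
  n <- length(q)
  K <- length(members)
  if (K == 0L) {
    rlang::warn(sprintf(
      "set '%s' skipped: no members inside the universe", set_name
    ))
    return(empty_records())
  }
  k <- length(intersect(q, members))
  expected <- n * K / N
  tibble::tibble(
    category = category,
    set_name = set_name,
    count = k,
    set_size = K,
    percent = 100 * k / K,
    expected = expected,
    fold = if (expected > 0) k / expected else NA_real_,
    p_value = hypergeom_upper_tail(N, K, n, k)
  )
}

empty_records <- function() {
  tibble::tibble(
    category = character(0), set_name = character(0),
    count = integer(0), set_size = integer(0),
    percent = numeric(0), expected = numeric(0), fold = numeric(0),
    p_value = numeric(0), bonferroni = numeric(0), fdr = numeric(0),
    advisory = character(0)
  )
}

#' Bonferroni correction
#'
#' `min(1, m * p)` for each p, with `m` the size of the tested family
#' (which may exceed the length of `p_values` when untestable results were
#' part of the family).
#'
#' @param p_values Probabilities in \[0, 1\].
#' @param m Family size, at least `length(p_values)`.
#' @return Corrected p-values, order preserved.
#' @export
bonferroni_correct <- function(p_values, m = length(p_values)) {
  check_probs(p_values)
  if (m < length(p_values)) {
    mirsets_abort("`m` must be at least length(p_values)",
                  class = "mirsets_parameter_error")
  }
  if (length(p_values) == 0L) return(numeric(0))
  p.adjust(p_values, method = "bonferroni", n = m)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: in ascending order, `q_(i) = min_(j >= i) m p_(j) / j`,
#' capped at 1 and mapped back to the input order; tied p-values share their
#' adjusted value.
#'
#' @param p_values Probabilities in \[0, 1\].
#' @return Adjusted p-values, order preserved.
#' @export
bh_fdr <- function(p_values) {
  check_probs(p_values)
  if (length(p_values) == 0L) return(numeric(0))
  p.adjust(p_values, method = "BH")
}

check_probs <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    mirsets_abort("p-values must lie in [0, 1]", class = "mirsets_domain_error")
  }
  invisible(p)
}

#' Enrichment of a query miRNA set against every catalog set
#'
#' The workhorse behind all analysis modes. Query miRNAs outside the
#' universe are dropped (with a logged count) so the hypergeometric model
#' stays coherent; sets with no member inside the universe are skipped but
#' logged. The multiple-testing family size m is the number of sets actually
#' tested within the correction scope: per category (the default, since
#' results are ranked and discussed within categories) or globally across
#' all categories. Function-category records carry a fixed advisory noting
#' that patterns there can be reversed by the inverse miRNA-target
#' regulatory relationship.
#'
#' @param query Character vector of miRNA ids.
#' @param catalog A `mir_catalog` from [build_catalog()].
#' @param universe Background miRNA population; defaults to the catalog
#'   universe. Analyses built on a target map pass the intersection of the
#'   prediction source's miRNAs with the catalog universe.
#' @param correction_scope `"per_category"` or `"global"`.
#' @return Tibble of all tested sets (including zero-overlap ones) with
#'   columns `category, set_name, count, set_size, percent, expected, fold,
#'   p_value, bonferroni, fdr, advisory`, sorted by category then set name.
#' @export
run_enrichment <- function(query, catalog, universe = NULL,
                           correction_scope = c("per_category", "global")) {
  stopifnot(inherits(catalog, "mir_catalog"))
  correction_scope <- rlang::arg_match(correction_scope)
  if (is.null(universe)) universe <- catalog$universe
  universe <- unique(universe)
  if (length(universe) == 0L) {
    mirsets_abort("background universe is empty", class = "mirsets_domain_error")
  }
  q <- unique(query)
  outside <- setdiff(q, universe)
  if (length(outside)) {
    rlang::inform(sprintf(
      "dropping %d query miRNA(s) outside the background universe",
      length(outside)
    ))
    q <- intersect(q, universe)
  }
  if (length(q) == 0L) {
    rlang::warn("query is empty after universe intersection; no enrichment computed")
    return(empty_records())
  }
  sets <- catalog$sets
  members <- lapply(sets$members, intersect, y = universe)
  K <- lengths(members)
  skipped <- K == 0L
  if (any(skipped)) {
    rlang::inform(sprintf(
      "skipping %d set(s) with no members inside the universe: %s",
      sum(skipped),
      paste(utils::head(sets$name[skipped], 5L), collapse = ", ")
    ))
  }
  idx <- which(!skipped)
  if (length(idx) == 0L) {
    rlang::warn("no testable sets after universe intersection")
    return(empty_records())
  }
  N <- length(universe)
  n <- length(q)
  k <- vapply(members[idx], function(m) length(intersect(m, q)), integer(1))
  K <- K[idx]
  expected <- n * K / N
  records <- tibble::tibble(
    category = sets$category[idx],
    set_name = sets$name[idx],
    count = k,
    set_size = as.integer(K),
    percent = 100 * k / K,
    expected = expected,
    fold = ifelse(expected > 0, k / expected, NA_real_),
    p_value = hypergeom_upper_tail(N, K, n, k)
  )
  records <- records[order(records$category, records$set_name), ]
  if (correction_scope == "per_category") {
    records <- dplyr::mutate(
      dplyr::group_by(records, .data$category),
      bonferroni = bonferroni_correct(.data$p_value),
      fdr = bh_fdr(.data$p_value)
    )
    records <- dplyr::ungroup(records)
  } else {
    records$bonferroni <- bonferroni_correct(records$p_value)
    records$fdr <- bh_fdr(records$p_value)
  }
  records$advisory <- ifelse(
    records$category == "Function",
    "pattern may be reversed (miRNAs repress their targets)", ""
  )
  attr(records, "universe_size") <- N
  attr(records, "query_size") <- n
  attr(records, "dropped_query") <- length(outside)
  attr(records, "correction_scope") <- correction_scope
  records
}
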
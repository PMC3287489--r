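# Independent oracles. These never call the package's own statistics: the
# tail probability is recomputed from binomial coefficients (exact in
# doubles for N <= 25) or by brute-force subset enumeration, and the
# correction procedures are written directly from their textbook
# definitions (O(m^2) step-up, not the cummin trick p.adjust uses).

# P(X >= k) as a ratio of exact combinatorial sums
hyper_tail_sum <- function(N, K, n, k) {
  j <- seq(from = k, to = min(n, K))
  if (length(j) == 0) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# P(X >= k) by enumerating every n-subset of 1..N with 1..K marked
hyper_tail_enum <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Bonferroni from the definition
bonf_ref <- function(p, m = length(p)) pmin(1, p * m)

# Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{j >= i} m p_(j) / j, capped at 1; ties share a value.
bh_ref <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  s <- sort(p)
  q <- vapply(seq_len(m), function(i) {
    min(1, min(m * s[i:m] / (i:m)))
  }, numeric(1))
  q[rank(p, ties.method = "min")]
}

# Independent per-gene recomputation of a pathway highlight map, straight
# from the raw fixture tables (pairs + set memberships), using the
# combinatorial machinery above only through stats::dhyper-free routes is
# impractical at N = 200, so the tail is an explicit dhyper sum.
dhyper_tail <- function(N, K, n, k) {
  j <- seq(from = k, to = min(n, K))
  if (length(j) == 0) return(0)
  sum(stats::dhyper(j, K, N - K, n))
}

recompute_highlights <- function(sim, pathway_name, cutoff = 0.05,
                                 scope = "per_category") {
  tables <- sim$tables
  pw_genes <- tables$pathways$genes[[match(pathway_name,
                                           tables$pathways$name)]]
  universe <- intersect(sort(unique(tables$pairs$mirna)),
                        sort(unique(unlist(tables$sets$members))))
  N <- length(universe)
  hits <- list()
  for (g in pw_genes) {
    regs <- intersect(unique(tables$pairs$mirna[tables$pairs$gene_symbol == g]),
                      universe)
    n <- length(regs)
    if (n == 0) next
    members <- lapply(tables$sets$members, intersect, y = universe)
    testable <- lengths(members) > 0
    df <- data.frame(
      category = tables$sets$category[testable],
      set_name = tables$sets$name[testable],
      k = vapply(members[testable],
                 function(m) length(intersect(m, regs)), integer(1)),
      K = lengths(members[testable])
    )
    df$p <- mapply(function(K, k) dhyper_tail(N, K, n, k), df$K, df$k)
    df$fdr <- if (scope == "per_category") {
      stats::ave(df$p, df$category, FUN = bh_ref)
    } else {
      bh_ref(df$p)
    }
    sig <- df[df$fdr <= cutoff & df$k >= 1, ]
    for (i in seq_len(nrow(sig))) {
      key <- paste(sig$category[i], sig$set_name[i], sep = "/")
      hits[[key]] <- sort(unique(c(hits[[key]], g)))
    }
  }
  hits[sort(names(hits))]
}
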
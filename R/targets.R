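# miRNA -> target-gene prediction tables, the seven-namespace gene
# identifier cross-reference, and the query-building steps (regulator
# lookup, multi-gene threshold filter).

TARGET_SOURCES <- c("targetscan", "microcosm", "diana_microt")
GENE_NAMESPACES <- c("symbol", "entrez", "ensembl_gene", "ensembl_transcript",
                     "ucsc", "refseq_mrna", "genbank")

#' Supported gene identifier namespaces
#'
#' Queries may use the official gene symbol, Entrez gene id, Ensembl gene or
#' transcript id, UCSC gene id, RefSeq mRNA id, or GenBank accession; all are
#' resolved to the official symbol, the canonical namespace.
#'
#' @return Character vector of the seven namespace names.
#' @export
gene_namespaces <- function() GENE_NAMESPACES

new_target_map <- function(pairs, source) {
  pairs <- dplyr::distinct(tibble::tibble(
    mirna = pairs$mirna, gene_symbol = pairs$gene_symbol
  ))
  pairs <- pairs[order(pairs$mirna, pairs$gene_symbol), ]
  structure(
    list(
      source = source,
      pairs = pairs,
      mirna_universe = sort(unique(pairs$mirna))
    ),
    class = "target_map"
  )
}

#' Read a miRNA-to-target prediction table
#'
#' Predictions are consumed as a binary relation exported from one of the
#' standard prediction tools; scores are not ingested. TSV with a header
#' containing at least `mirna` and `gene_symbol`, one pair per row. miRNA
#' ids are normalized, gene symbols trimmed (case preserved), and duplicate
#' pairs collapsed.
#'
#' @param path Path to the TSV file.
#' @param source One of `"targetscan"`, `"microcosm"`, `"diana_microt"`.
#' @return A `target_map`: list with `source`, `pairs` (tibble of distinct
#'   mirna/gene_symbol pairs) and `mirna_universe`.
#' @export
read_target_map <- function(path, source = TARGET_SOURCES) {
  source <- rlang::arg_match(source, TARGET_SOURCES)
  if (!file.exists(path)) {
    mirsets_abort(sprintf("file not found: %s", path), "mirsets_io_error")
  }
  df <- tryCatch(
    read.delim(path, sep = "\t", stringsAsFactors = FALSE,
               check.names = FALSE, colClasses = "character"),
    error = function(e) {
      mirsets_abort(sprintf("cannot parse target map %s: %s",
                            path, conditionMessage(e)),
                    class = "mirsets_parse_error")
    }
  )
  missing <- setdiff(c("mirna", "gene_symbol"), names(df))
  if (length(missing)) {
    mirsets_abort(
      sprintf("target map %s lacks column(s): %s",
              path, paste(missing, collapse = ", ")),
      class = "mirsets_parse_error"
    )
  }
  if (nrow(df) == 0L) {
    mirsets_abort(sprintf("target map %s contains no pairs", path),
                  class = "mirsets_validation_error")
  }
  new_target_map(
    tibble::tibble(
      mirna = normalize_mirna_id(df$mirna),
      gene_symbol = trimws(df$gene_symbol)
    ),
    source = source
  )
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf(
    "target map [%s]: %d miRNA-gene pairs, %d miRNAs, %d genes\n",
    x$source, nrow(x$pairs), length(x$mirna_universe),
    length(unique(x$pairs$gene_symbol))
  ))
  invisible(x)
}

build_gene_xref <- function(wide) {
  missing <- setdiff(GENE_NAMESPACES, names(wide))
  if (length(missing)) {
    mirsets_abort(
      sprintf("gene xref lacks column(s): %s", paste(missing, collapse = ", ")),
      class = "mirsets_parse_error"
    )
  }
  symbol <- trimws(wide$symbol)
  if (any(!nzchar(symbol))) {
    mirsets_abort("gene xref has an empty canonical symbol",
                  class = "mirsets_validation_error")
  }
  if (anyDuplicated(symbol)) {
    mirsets_abort("canonical symbols in the gene xref must be unique",
                  class = "mirsets_validation_error")
  }
  long <- dplyr::bind_rows(lapply(GENE_NAMESPACES, function(ns) {
    cells <- if (ns == "symbol") symbol else trimws(as.character(wide[[ns]]))
    cells[is.na(cells)] <- ""
    aliases <- strsplit(cells, "|", fixed = TRUE)
    n <- lengths(aliases)
    out <- tibble::tibble(
      namespace = ns,
      alias = trimws(unlist(aliases, use.names = FALSE)),
      symbol = rep(symbol, n)
    )
    out[nzchar(out$alias), ]
  }))
  clash <- dplyr::distinct(long[c("namespace", "alias", "symbol")])
  dup <- duplicated(paste(clash$namespace, clash$alias, sep = "\r"))
  if (any(dup)) {
    bad <- clash[dup, ]
    mirsets_abort(
      sprintf("alias maps to multiple canonical symbols: %s",
              paste(unique(paste0(bad$namespace, ":", bad$alias)),
                    collapse = ", ")),
      class = "mirsets_validation_error"
    )
  }
  structure(
    list(table = long, symbols = symbol),
    class = "gene_xref"
  )
}

#' Read the gene identifier cross-reference
#'
#' TSV with header `symbol, entrez, ensembl_gene, ensembl_transcript, ucsc,
#' refseq_mrna, genbank`; empty cells allowed; multiple aliases within one
#' cell separated by `|`. Canonical symbols must be unique and every alias
#' must map to exactly one canonical symbol within its namespace.
#'
#' @param path Path to the TSV file.
#' @return A `gene_xref` lookup object.
#' @export
read_gene_xref <- function(path) {
  if (!file.exists(path)) {
    mirsets_abort(sprintf("file not found: %s", path), "mirsets_io_error")
  }
  wide <- tryCatch(
    read.delim(path, sep = "\t", stringsAsFactors = FALSE,
               check.names = FALSE, colClasses = "character"),
    error = function(e) {
      mirsets_abort(sprintf("cannot parse gene xref %s: %s",
                            path, conditionMessage(e)),
                    class = "mirsets_parse_error")
    }
  )
  build_gene_xref(wide)
}

#' @export
print.gene_xref <- function(x, ...) {
  cat(sprintf("gene xref: %d canonical symbols, %d aliases in %d namespaces\n",
              length(x$symbols), nrow(x$table),
              length(unique(x$table$namespace))))
  invisible(x)
}

#' Resolve a gene identifier to its official symbol
#'
#' Searches all seven namespaces. Matching is exact after trimming;
#' case-insensitive for symbols, case-sensitive for accession-style
#' namespaces.
#'
#' @param query A single gene identifier (any supported namespace).
#' @param xref A `gene_xref` from [read_gene_xref()].
#' @return The canonical gene symbol.
#' @export
resolve_gene <- function(query, xref) {
  stopifnot(inherits(xref, "gene_xref"))
  if (!is.character(query) || length(query) != 1L || is.na(query)) {
    mirsets_abort("`query` must be a single gene identifier",
                  class = "mirsets_parameter_error")
  }
  q <- trimws(query)
  if (!nzchar(q)) {
    mirsets_abort("`query` is empty", class = "mirsets_parameter_error")
  }
  tab <- xref$table
  hit <- (tab$namespace == "symbol" & tolower(tab$alias) == tolower(q)) |
    (tab$namespace != "symbol" & tab$alias == q)
  found <- unique(tab$symbol[hit])
  if (length(found) == 0L) {
    mirsets_abort(sprintf("gene identifier not found: '%s'", q),
                  class = "mirsets_unknown_gene", query = q)
  }
  if (length(found) > 1L) {
    mirsets_abort(
      sprintf("gene identifier '%s' is ambiguous; candidates: %s",
              q, paste(sort(found), collapse = ", ")),
      class = "mirsets_ambiguous_gene", candidates = sort(found)
    )
  }
  found
}

#' Predicted miRNA regulators of each gene
#'
#' @param genes Character vector of canonical gene symbols.
#' @param tmap A `target_map`.
#' @return Named list mapping each gene to the sorted distinct miRNAs paired
#'   with it. Genes with no predicted regulator map to `character(0)` and
#'   are kept, not dropped.
#' @export
regulators_of <- function(genes, tmap) {
  stopifnot(inherits(tmap, "target_map"))
  if (length(genes) == 0L) {
    mirsets_abort("`genes` must contain at least one gene",
                  class = "mirsets_parameter_error")
  }
  pairs <- tmap$pairs
  out <- lapply(genes, function(g) {
    sort(unique(pairs$mirna[pairs$gene_symbol == g]))
  })
  names(out) <- genes
  out
}

#' Filter regulators by how many input genes they regulate
#'
#' In multi-gene mode only the miRNAs that regulate no less than `threshold`
#' of the input genes enter the enrichment query; `threshold = 1` returns
#' the union of all regulator sets.
#'
#' @param reg Named list from [regulators_of()].
#' @param threshold Positive integer, at most `length(reg)`.
#' @return Sorted character vector of retained miRNA ids.
#' @export
threshold_filter <- function(reg, threshold) {
  if (length(reg) == 0L) {
    mirsets_abort("`reg` must be non-empty", class = "mirsets_parameter_error")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold != as.integer(threshold) || threshold < 1 ||
      threshold > length(reg)) {
    mirsets_abort(
      sprintf("`threshold` must be an integer in [1, %d]", length(reg)),
      class = "mirsets_parameter_error"
    )
  }
  counts <- table(unlist(lapply(reg, unique), use.names = FALSE))
  sort(names(counts)[counts >= threshold])
}

#' Read pathway definitions (GMT)
#'
#' One pathway per line: `pathway_name<TAB>description<TAB>gene1<TAB>...`.
#' Gene symbols are trimmed and deduplicated; no miRNA normalization.
#'
#' @param path Path to a GMT file of gene memberships.
#' @return Tibble with columns `name`, `description`, and list column `genes`.
#' @export
read_pathway_collection <- function(path) {
  gmt <- read_gmt(path, normalize = identity, what = "pathway")
  tibble::tibble(name = gmt$name, description = gmt$description,
                 genes = gmt$members)
}
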
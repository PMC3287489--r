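# User-facing analyses: single gene, gene list with regulation threshold,
# and pathway (per-gene or pooled), plus ranking and report finalization.

RANK_KEYS <- c("p_value", "count", "percent", "fold", "bonferroni", "fdr")
DESC_KEYS <- c("count", "percent", "fold")

#' Bundle the loaded resources for analysis
#'
#' Combines a set catalog, a target map, a gene cross-reference and
#' (optionally) pathway definitions, and fixes the enrichment background:
#' the miRNAs of the prediction source intersected with the catalog
#' universe, so that "expected" counts reflect what the chosen source could
#' possibly have matched. Both component universe sizes are logged.
#'
#' @param catalog A `mir_catalog`.
#' @param target_map A `target_map`.
#' @param xref A `gene_xref`.
#' @param pathways Optional tibble from [read_pathway_collection()].
#' @param digests Optional named character vector of input-file digests,
#'   echoed into report metadata.
#' @return A `mir_resources` object.
#' @export
mir_resources <- function(catalog, target_map, xref, pathways = NULL,
                          digests = NULL) {
  stopifnot(inherits(catalog, "mir_catalog"),
            inherits(target_map, "target_map"),
            inherits(xref, "gene_xref"))
  universe <- intersect(target_map$mirna_universe, catalog$universe)
  rlang::inform(sprintf(
    "background universe: %d miRNAs (target map %d, catalog %d)",
    length(universe), length(target_map$mirna_universe),
    length(catalog$universe)
  ))
  if (length(universe) == 0L) {
    mirsets_abort(
      "target map and catalog share no miRNAs; check identifier conventions",
      class = "mirsets_validation_error"
    )
  }
  structure(
    list(catalog = catalog, target_map = target_map, xref = xref,
         pathways = pathways, universe = sort(universe), digests = digests),
    class = "mir_resources"
  )
}

#' Load all resources from files
#'
#' @param catalog_files Named vector: category -> GMT path.
#' @param target_map_file TSV of miRNA/gene pairs.
#' @param source Prediction source name (see [read_target_map()]).
#' @param xref_file Gene cross-reference TSV.
#' @param pathway_file Optional pathway GMT.
#' @return A `mir_resources` object carrying md5 digests of every input file.
#' @export
load_resources <- function(catalog_files, target_map_file, source,
                           xref_file, pathway_file = NULL) {
  files <- c(unlist(catalog_files), target_map = target_map_file,
             xref = xref_file,
             if (!is.null(pathway_file)) c(pathways = pathway_file))
  digests <- vapply(files, function(f) unname(tools::md5sum(f)), "")
  mir_resources(
    catalog = build_catalog(catalog_files),
    target_map = read_target_map(target_map_file, source),
    xref = read_gene_xref(xref_file),
    pathways = if (!is.null(pathway_file))
      read_pathway_collection(pathway_file),
    digests = digests
  )
}

#' @export
print.mir_resources <- function(x, ...) {
  cat(sprintf(
    "analysis resources [%s]: background universe %d miRNAs\n",
    x$target_map$source, length(x$universe)
  ))
  print(x$catalog)
  if (!is.null(x$pathways)) {
    cat(sprintf("  %d pathway definitions\n", nrow(x$pathways)))
  }
  invisible(x)
}

#' Rank enrichment records by one of the six report keys
#'
#' Descending for `count`, `percent`, `fold`; ascending for `p_value`,
#' `bonferroni`, `fdr`. Ties are broken by p-value (ascending) and then set
#' name, so ordering is deterministic. Undefined folds sort last.
#'
#' @param records Tibble of enrichment records.
#' @param key One of `"count"`, `"percent"`, `"fold"`, `"p_value"`,
#'   `"bonferroni"`, `"fdr"`.
#' @return The records, reordered.
#' @export
rank_records <- function(records, key = "p_value") {
  if (!is.character(key) || length(key) != 1L || !key %in% RANK_KEYS) {
    mirsets_abort(
      sprintf("`key` must be one of: %s", paste(RANK_KEYS, collapse = ", ")),
      class = "mirsets_parameter_error"
    )
  }
  if (nrow(records) == 0L) return(records)
  primary <- records[[key]]
  if (key %in% DESC_KEYS) primary <- -primary
  records[order(primary, records$p_value, records$set_name,
                na.last = TRUE), ]
}

# Shared back half of every mode: enrich, keep sets with at least one match
# (the family size m still counts zero-overlap sets, which were tested),
# rank for the report.
finalize_records <- function(records, rank_key) {
  carry <- intersect(c("universe_size", "query_size", "dropped_query",
                       "correction_scope"), names(attributes(records)))
  meta <- attributes(records)[carry]
  shown <- rank_records(records[records$count >= 1L, ], rank_key)
  attr(shown, "n_tested") <- nrow(records)
  for (a in carry) attr(shown, a) <- meta[[a]]
  shown
}

enrich_regulators <- function(regulators, resources, correction_scope,
                              rank_key) {
  records <- run_enrichment(regulators, resources$catalog,
                            universe = resources$universe,
                            correction_scope = correction_scope)
  finalize_records(records, rank_key)
}

report_meta <- function(resources, records, threshold = NULL,
                        rank_key, fdr_cutoff = NULL) {
  list(
    tool = "mirsets",
    version = as.character(packageVersion("mirsets")),
    prediction_source = resources$target_map$source,
    universe_size = attr(records, "universe_size") %||% length(resources$universe),
    query_size = attr(records, "query_size") %||% 0L,
    n_tested_sets = attr(records, "n_tested") %||% 0L,
    dropped_query = attr(records, "dropped_query") %||% 0L,
    correction_scope = attr(records, "correction_scope"),
    threshold = threshold,
    rank_key = rank_key,
    fdr_cutoff = fdr_cutoff,
    input_digests = as.list(resources$digests)
  )
}

#' Single-gene analysis
#'
#' Resolves the query to an official symbol, collects its predicted miRNA
#' regulators, and tests every catalog set for enrichment. Only sets with
#' at least one matched miRNA appear in the report; the correction family
#' still counts every tested set.
#'
#' @param gene_query Gene identifier in any supported namespace.
#' @param resources A `mir_resources` object.
#' @param correction_scope `"per_category"` (default) or `"global"`.
#' @param rank_key Report ordering; see [rank_records()].
#' @return A `gene_report`: list with `gene`, `regulators`, `records` and
#'   `meta`.
#' @export
analyze_single_gene <- function(gene_query, resources,
                                correction_scope = c("per_category", "global"),
                                rank_key = "p_value") {
  stopifnot(inherits(resources, "mir_resources"))
  correction_scope <- rlang::arg_match(correction_scope)
  gene <- resolve_gene(gene_query, resources$xref)
  regulators <- regulators_of(gene, resources$target_map)[[1L]]
  if (length(regulators) == 0L) {
    rlang::warn(sprintf("gene '%s' has no predicted miRNA regulators", gene))
    records <- finalize_records(empty_records(), rank_key)
  } else {
    records <- enrich_regulators(regulators, resources, correction_scope,
                                 rank_key)
  }
  structure(
    list(
      gene = gene,
      regulators = regulators,
      records = records,
      meta = report_meta(resources, records, rank_key = rank_key)
    ),
    class = "gene_report"
  )
}

#' Gene-list analysis with a regulation threshold
#'
#' Resolves each input identifier (unresolvable rows are skipped with a
#' message, not fatal), collapses duplicates, and builds the query from the
#' miRNAs that regulate at least `threshold` of the resolved genes; the
#' enrichment step is then identical to the single-gene analysis.
#'
#' @param gene_queries Character vector of gene identifiers.
#' @param resources A `mir_resources` object.
#' @param threshold Minimum number of input genes a miRNA must regulate to
#'   enter the query (inclusive); at most the number of resolved genes.
#' @param correction_scope,rank_key As in [analyze_single_gene()].
#' @return A `gene_list_report`: list with `genes`, `skipped`, `threshold`,
#'   `regulators`, `query`, `records`, `meta`.
#' @export
analyze_gene_list <- function(gene_queries, resources, threshold = 1,
                              correction_scope = c("per_category", "global"),
                              rank_key = "p_value") {
  stopifnot(inherits(resources, "mir_resources"))
  correction_scope <- rlang::arg_match(correction_scope)
  if (length(gene_queries) == 0L) {
    mirsets_abort("`gene_queries` is empty", class = "mirsets_parameter_error")
  }
  resolved <- character(0)
  skipped <- character(0)
  for (q in gene_queries) {
    sym <- tryCatch(
      resolve_gene(q, resources$xref),
      mirsets_unknown_gene = function(e) NA_character_,
      mirsets_ambiguous_gene = function(e) NA_character_
    )
    if (is.na(sym)) skipped <- c(skipped, q) else resolved <- c(resolved, sym)
  }
  if (length(skipped)) {
    rlang::inform(sprintf("skipped %d unresolvable gene identifier(s): %s",
                          length(skipped),
                          paste(utils::head(skipped, 5L), collapse = ", ")))
  }
  genes <- unique(resolved)
  if (length(genes) == 0L) {
    mirsets_abort("none of the input gene identifiers could be resolved",
                  class = "mirsets_unknown_gene")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold != as.integer(threshold) || threshold < 1 ||
      threshold > length(genes)) {
    mirsets_abort(
      sprintf("`threshold` must be an integer in [1, %d] (number of resolved genes)",
              length(genes)),
      class = "mirsets_parameter_error"
    )
  }
  regulators <- regulators_of(genes, resources$target_map)
  query <- threshold_filter(regulators, threshold)
  if (length(query) == 0L) {
    rlang::warn(sprintf(
      "no miRNA regulates at least %d of the %d input genes",
      threshold, length(genes)
    ))
    records <- finalize_records(empty_records(), rank_key)
  } else {
    records <- enrich_regulators(query, resources, correction_scope, rank_key)
  }
  structure(
    list(
      genes = genes,
      skipped = skipped,
      threshold = as.integer(threshold),
      regulators = regulators,
      query = query,
      records = records,
      meta = report_meta(resources, records, threshold = as.integer(threshold),
                        rank_key = rank_key)
    ),
    class = "gene_list_report"
  )
}

#' Pathway analysis (per-gene or pooled)
#'
#' In `"individual"` mode every pathway gene is analyzed as its own query,
#' corrected within its own test family, and a highlight map records which
#' genes each miRNA set significantly regulates (per-gene FDR at or below
#' `fdr_cutoff`). In `"whole"` mode the member genes are pooled through the
#' gene-list pipeline with threshold 1.
#'
#' @param pathway A pathway name (looked up in `resources$pathways`) or a
#'   list with elements `name` and `genes`.
#' @param resources A `mir_resources` object.
#' @param mode `"individual"` or `"whole"`.
#' @param fdr_cutoff Significance cutoff for highlighting (default 0.05).
#' @param correction_scope,rank_key As in [analyze_single_gene()].
#' @return A `pathway_report`: list with `pathway`, `mode`, `skipped`, and
#'   either `gene_reports` + `highlight_map` (individual) or `whole_report`.
#'   Highlight-map keys are `"category/set_name"`.
#' @export
analyze_pathway <- function(pathway, resources,
                            mode = c("individual", "whole"),
                            fdr_cutoff = 0.05,
                            correction_scope = c("per_category", "global"),
                            rank_key = "p_value") {
  stopifnot(inherits(resources, "mir_resources"))
  mode <- rlang::arg_match(mode)
  correction_scope <- rlang::arg_match(correction_scope)
  if (!is.numeric(fdr_cutoff) || length(fdr_cutoff) != 1L ||
      is.na(fdr_cutoff) || fdr_cutoff <= 0 || fdr_cutoff > 1) {
    mirsets_abort("`fdr_cutoff` must lie in (0, 1]",
                  class = "mirsets_parameter_error")
  }
  if (is.character(pathway) && length(pathway) == 1L) {
    if (is.null(resources$pathways)) {
      mirsets_abort("no pathway definitions loaded",
                    class = "mirsets_config_error")
    }
    hit <- which(resources$pathways$name == pathway)
    if (length(hit) != 1L) {
      mirsets_abort(sprintf("pathway not found: '%s'", pathway),
                    class = "mirsets_unknown_pathway")
    }
    pathway <- list(name = pathway,
                    genes = resources$pathways$genes[[hit]])
  }
  if (!is.list(pathway) || is.null(pathway$name) ||
      length(pathway$genes) == 0L) {
    mirsets_abort("`pathway` must name a loaded pathway or carry `name` and `genes`",
                  class = "mirsets_parameter_error")
  }
  resolved <- character(0)
  skipped <- character(0)
  for (g in unique(pathway$genes)) {
    sym <- tryCatch(
      resolve_gene(g, resources$xref),
      mirsets_unknown_gene = function(e) NA_character_,
      mirsets_ambiguous_gene = function(e) NA_character_
    )
    if (is.na(sym)) skipped <- c(skipped, g) else resolved <- c(resolved, sym)
  }
  if (length(skipped)) {
    rlang::inform(sprintf(
      "pathway '%s': skipped %d unresolvable gene(s): %s",
      pathway$name, length(skipped),
      paste(utils::head(skipped, 5L), collapse = ", ")
    ))
  }
  genes <- unique(resolved)
  if (length(genes) == 0L) {
    mirsets_abort(
      sprintf("pathway '%s' has no resolvable genes", pathway$name),
      class = "mirsets_validation_error"
    )
  }
  out <- list(
    pathway = list(name = pathway$name, genes = genes),
    mode = mode,
    skipped = skipped,
    fdr_cutoff = fdr_cutoff
  )
  if (mode == "whole") {
    out$whole_report <- analyze_gene_list(genes, resources, threshold = 1,
                                          correction_scope = correction_scope,
                                          rank_key = rank_key)
  } else {
    all_regs <- regulators_of(genes, resources$target_map)
    out$gene_reports <- lapply(genes, function(g) {
      regulators <- all_regs[[g]]
      if (length(regulators) == 0L) {
        records <- finalize_records(empty_records(), rank_key)
      } else {
        records <- enrich_regulators(regulators, resources, correction_scope,
                                     rank_key)
      }
      structure(
        list(gene = g, regulators = regulators, records = records,
             meta = report_meta(resources, records, rank_key = rank_key,
                                fdr_cutoff = fdr_cutoff)),
        class = "gene_report"
      )
    })
    names(out$gene_reports) <- genes
    out$highlight_map <- build_highlight_map(out$gene_reports, fdr_cutoff)
  }
  structure(out, class = "pathway_report")
}

# set (keyed "category/set_name") -> sorted genes whose per-gene FDR for
# that set is at or below the cutoff.
build_highlight_map <- function(gene_reports, fdr_cutoff) {
  hits <- dplyr::bind_rows(lapply(gene_reports, function(rep) {
    sig <- rep$records[rep$records$fdr <= fdr_cutoff, c("category", "set_name")]
    if (nrow(sig) == 0L) return(NULL)
    tibble::tibble(key = paste(sig$category, sig$set_name, sep = "/"),
                   gene = rep$gene)
  }))
  if (is.null(hits) || nrow(hits) == 0L) {
    return(structure(list(), names = character(0)))
  }
  split_genes <- split(hits$gene, hits$key)
  lapply(split_genes[sort(names(split_genes))], function(g) sort(unique(g)))
}

#' @export
print.gene_report <- function(x, ...) {
  cat(sprintf("gene report: %s (%d predicted regulators, %d enriched-set records)\n",
              x$gene, length(x$regulators), nrow(x$records)))
  if (nrow(x$records)) print(utils::head(x$records, 10L))
  invisible(x)
}

#' @export
print.gene_list_report <- function(x, ...) {
  cat(sprintf(
    "gene-list report: %d genes (threshold %d), query of %d miRNAs, %d records\n",
    length(x$genes), x$threshold, length(x$query), nrow(x$records)
  ))
  if (nrow(x$records)) print(utils::head(x$records, 10L))
  invisible(x)
}

#' @export
print.pathway_report <- function(x, ...) {
  cat(sprintf("pathway report: %s (%d genes, mode %s)\n",
              x$pathway$name, length(x$pathway$genes), x$mode))
  if (x$mode == "individual") {
    cat(sprintf("  %d set/gene highlight keys at FDR <= %g\n",
                length(x$highlight_map), x$fdr_cutoff))
  } else {
    print(x$whole_report)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
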
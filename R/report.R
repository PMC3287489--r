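# Report serialization. Identical inputs and configuration must produce
# byte-identical files, so no timestamps and fixed number formatting
# (6 significant digits in the TSV, full precision in the JSON).

REPORT_COLUMNS <- c("category", "set_name", "count", "set_size", "percent",
                    "expected", "fold", "p_value", "bonferroni", "fdr",
                    "advisory")
REPORT_FLOAT_COLUMNS <- c("percent", "expected", "fold", "p_value",
                          "bonferroni", "fdr")

records_of <- function(x) {
  if (inherits(x, "gene_report") || inherits(x, "gene_list_report")) {
    return(x$records)
  }
  if (inherits(x, "pathway_report")) {
    if (x$mode == "whole") return(x$whole_report$records)
    mirsets_abort(
      "individual-mode pathway reports have one record table per gene; write them per gene",
      class = "mirsets_parameter_error"
    )
  }
  x
}

#' Write an enrichment report as TSV
#'
#' Columns `category, set_name, count, set_size, percent, expected, fold,
#' p_value, bonferroni, fdr, advisory`; floats with 6 significant digits;
#' rows in the report's configured rank order. Deterministic: identical
#' inputs yield byte-identical files.
#'
#' @param report A `gene_report`, `gene_list_report`, whole-mode
#'   `pathway_report`, or a bare records tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  records <- records_of(report)
  out <- as.data.frame(records[intersect(REPORT_COLUMNS, names(records))])
  for (col in intersect(REPORT_FLOAT_COLUMNS, names(out))) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         formatC(out[[col]], digits = 6, format = "g"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' Write an enrichment report as JSON with run metadata
#'
#' The JSON carries the records at full precision plus a metadata block
#' (prediction source, universe size N, query size n, family size m,
#' correction scope, threshold, tool version, input-file digests)
#' sufficient to reproduce the run.
#'
#' @param report A report object as in [write_report_tsv()]; pathway reports
#'   in individual mode are written whole (per-gene tables plus highlight
#'   map).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- if (inherits(report, "pathway_report") &&
                 report$mode == "individual") {
    list(
      pathway = report$pathway,
      mode = report$mode,
      fdr_cutoff = report$fdr_cutoff,
      skipped = report$skipped,
      highlight_map = report$highlight_map,
      gene_reports = lapply(report$gene_reports, function(rep) {
        list(gene = rep$gene, regulators = rep$regulators,
             records = as.data.frame(rep$records), meta = rep$meta)
      })
    )
  } else if (inherits(report, "pathway_report")) {
    list(pathway = report$pathway, mode = report$mode,
         skipped = report$skipped,
         records = as.data.frame(report$whole_report$records),
         query = report$whole_report$query,
         meta = report$whole_report$meta)
  } else if (inherits(report, "gene_report")) {
    list(gene = report$gene, regulators = report$regulators,
         records = as.data.frame(report$records), meta = report$meta)
  } else if (inherits(report, "gene_list_report")) {
    list(genes = report$genes, skipped = report$skipped,
         threshold = report$threshold, query = report$query,
         records = as.data.frame(report$records), meta = report$meta)
  } else {
    list(records = as.data.frame(report))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
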
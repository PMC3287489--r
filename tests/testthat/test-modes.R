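test_that("single-gene analysis populates all six statistics", {
  res <- tiny_resources()
  rep <- suppressMessages(analyze_single_gene("27", res))
  expect_identical(rep$gene, "ABL2")
  expect_length(rep$regulators, 10L)
  # ABL2 is regulated by the whole universe: every set saturates, p = 1
  expect_true(all(rep$records$p_value == 1))
  expect_true(all(rep$records$count <= length(rep$regulators)))
  expect_true(all(c("count", "set_size", "percent", "expected", "fold",
                    "p_value", "bonferroni", "fdr") %in%
                    names(rep$records)))
  # only sets with at least one match are shown, but m counts all tested
  rep2 <- suppressMessages(analyze_single_gene("WEE1", res))
  expect_true(all(rep2$records$count >= 1L))
  expect_equal(attr(rep2$records, "n_tested"), 4L)
  expect_lt(nrow(rep2$records), 4L)  # cl_b has no WEE1 regulator
  expect_error(suppressMessages(analyze_single_gene("NOSUCHGENE", res)),
               class = "mirsets_unknown_gene")
})

test_that("a gene with no predicted regulators yields an empty report", {
  res <- tiny_resources()
  # TP53 row removed from the map: craft a map lacking WEE1
  pairs <- res$target_map$pairs[res$target_map$pairs$gene_symbol != "WEE1", ]
  res2 <- suppressMessages(mir_resources(
    res$catalog, mirsets:::new_target_map(pairs, "targetscan"), res$xref
  ))
  expect_warning(rep <- suppressMessages(analyze_single_gene("WEE1", res2)),
                 "no predicted miRNA regulators")
  expect_equal(nrow(rep$records), 0L)
})

test_that("gene-list analysis applies the threshold and reports skips", {
  res <- tiny_resources()
  expect_message(
    rep <- analyze_gene_list(c("ABL2", "TP53", "GHOST", "abl2"), res,
                             threshold = 2),
    "skipped 1"
  )
  # duplicate collapsed: ABL2 counted once toward the threshold
  expect_identical(rep$genes, c("ABL2", "TP53"))
  expect_identical(rep$skipped, "GHOST")
  expect_setequal(rep$query, sprintf("hsa-mir-%d", c(1, 2, 5)))
  # threshold = 3 on 2 genes is a parameter error
  expect_error(
    suppressMessages(analyze_gene_list(c("ABL2", "TP53"), res, threshold = 3)),
    class = "mirsets_parameter_error"
  )
  expect_error(
    suppressMessages(analyze_gene_list(c("GHOST1", "GHOST2"), res)),
    class = "mirsets_unknown_gene"
  )
})

test_that("gene-list with one gene at threshold 1 equals the single-gene run", {
  res <- tiny_resources()
  single <- suppressMessages(analyze_single_gene("TP53", res))
  listed <- suppressMessages(analyze_gene_list("TP53", res, threshold = 1))
  expect_equal(as.data.frame(listed$records), as.data.frame(single$records))
})

test_that("whole-pathway analysis equals the pooled gene-list run", {
  res <- tiny_resources()
  pw <- suppressMessages(analyze_pathway("tiny_path", res, mode = "whole"))
  pooled <- suppressMessages(
    analyze_gene_list(c("ABL2", "TP53", "WEE1"), res, threshold = 1)
  )
  expect_equal(as.data.frame(pw$whole_report$records),
               as.data.frame(pooled$records))
  # byte-identical reports
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_report_tsv(pw, f1)
  write_report_tsv(pooled, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("individual-mode pathway reports highlight exactly the significant pairs", {
  sim <- demo_fixture()
  pw <- suppressMessages(
    analyze_pathway("cell_cycle", sim$resources, mode = "individual")
  )
  # soundness + completeness against per-gene records
  expected <- list()
  for (g in names(pw$gene_reports)) {
    recs <- pw$gene_reports[[g]]$records
    sig <- recs[recs$fdr <= 0.05, ]
    for (i in seq_len(nrow(sig))) {
      key <- paste(sig$category[i], sig$set_name[i], sep = "/")
      expected[[key]] <- sort(unique(c(expected[[key]], g)))
    }
  }
  expect_identical(pw$highlight_map, expected[sort(names(expected))])
  # the planted pattern: Function/cell_cycle highlights the three planted genes
  expect_identical(pw$highlight_map[["Function/cell_cycle"]],
                   c("GENE0001", "GENE0002", "GENE0003"))
  # every highlighted gene is a pathway member
  expect_true(all(unlist(pw$highlight_map) %in% pw$pathway$genes))
})

test_that("pathway input validation", {
  res <- tiny_resources()
  expect_error(suppressMessages(analyze_pathway("no_such_path", res)),
               class = "mirsets_unknown_pathway")
  expect_error(
    suppressMessages(analyze_pathway("tiny_path", res, fdr_cutoff = 0)),
    class = "mirsets_parameter_error"
  )
  expect_error(
    suppressMessages(
      analyze_pathway(list(name = "p", genes = c("GHOST1", "GHOST2")), res)
    ),
    class = "mirsets_validation_error"
  )
})

test_that("ranking orders each key correctly with deterministic ties", {
  records <- tibble::tibble(
    category = "Cluster",
    set_name = c("beta", "alpha", "gamma"),
    count = c(2L, 5L, 5L),
    set_size = c(10L, 10L, 20L),
    percent = c(20, 50, 25),
    expected = c(1, 2, 2),
    fold = c(2.0, 2.5, 0.0),
    p_value = c(0.2, 0.01, 0.01),
    bonferroni = c(0.6, 0.03, 0.03),
    fdr = c(0.2, 0.015, 0.015),
    advisory = ""
  )
  expect_identical(rank_records(records, "p_value")$set_name,
                   c("alpha", "gamma", "beta"))
  # equal count 5: tie broken by p then name; both have p = 0.01
  expect_identical(rank_records(records, "count")$set_name,
                   c("alpha", "gamma", "beta"))
  expect_identical(rank_records(records, "fold")$set_name,
                   c("alpha", "beta", "gamma"))
  expect_error(rank_records(records, "banana"),
               class = "mirsets_parameter_error")
})

test_that("report writing is deterministic and JSON carries run metadata", {
  res <- tiny_resources()
  rep <- suppressMessages(analyze_single_gene("TP53", res))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_report_tsv(rep, f1)
  write_report_tsv(rep, f2)
  expect_identical(readLines(f1), readLines(f2))
  header <- strsplit(readLines(f1)[1], "\t")[[1]]
  expect_identical(header, c("category", "set_name", "count", "set_size",
                             "percent", "expected", "fold", "p_value",
                             "bonferroni", "fdr", "advisory"))
  j <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, j)
  parsed <- jsonlite::read_json(j)
  expect_identical(parsed$gene, "TP53")
  expect_identical(parsed$meta$prediction_source, "targetscan")
  expect_equal(parsed$meta$universe_size, 10L)
  expect_equal(parsed$meta$query_size, 3L)
  expect_identical(parsed$meta$correction_scope, "per_category")
})
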
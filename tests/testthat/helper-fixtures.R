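# Tiny hand-built fixtures, written to tempfiles at test time.

write_gmt_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_tsv_lines <- function(lines, fileext = ".tsv") {
  path <- withr::local_tempfile(fileext = fileext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Minimal xref with ABL2 <-> entrez 27 plus two plain genes
tiny_xref <- function() {
  header <- paste(c("symbol", "entrez", "ensembl_gene", "ensembl_transcript",
                    "ucsc", "refseq_mrna", "genbank"), collapse = "\t")
  rows <- c(
    "ABL2\t27\tENSG00000143322\tENST00000367623\tuc001ggn.1\tNM_005158\tAB000001",
    "TP53\t7157\tENSG00000141510\tENST00000269305\tuc010cne.1\tNM_000546|NM_001126112\tAB000002",
    "WEE1\t7465\tENSG00000166483\tENST00000299613\tuc001mnl.1\tNM_003390\tAB000003"
  )
  path <- write_tsv_lines(c(header, rows))
  mirsets::read_gene_xref(path)
}

# A fully hand-checkable resource bundle:
# universe = hsa-mir-1 .. hsa-mir-10 (catalog covers all, target map covers all)
tiny_resources <- function() {
  sets <- tibble::tibble(
    category = c("Cluster", "Cluster", "Family", "Function"),
    name = c("cl_a", "cl_b", "fam_a", "fn_a"),
    description = "d",
    members = list(
      sprintf("hsa-mir-%d", 1:4),   # cl_a
      sprintf("hsa-mir-%d", 5:8),   # cl_b
      sprintf("hsa-mir-%d", 9:10),  # fam_a
      sprintf("hsa-mir-%d", c(1, 5, 9))  # fn_a
    )
  )
  pairs <- tibble::tibble(
    mirna = c(sprintf("hsa-mir-%d", 1:10),        # all regulate ABL2
              sprintf("hsa-mir-%d", c(1, 2, 5)),  # some regulate TP53
              sprintf("hsa-mir-%d", c(1, 9))),    # some regulate WEE1
    gene_symbol = c(rep("ABL2", 10), rep("TP53", 3), rep("WEE1", 2))
  )
  suppressMessages(mirsets::mir_resources(
    catalog = mirsets:::new_mir_catalog(sets),
    target_map = mirsets:::new_target_map(pairs, "targetscan"),
    xref = tiny_xref(),
    pathways = tibble::tibble(
      name = "tiny_path", description = "d",
      genes = list(c("ABL2", "TP53", "WEE1"))
    )
  ))
}
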
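# Synthetic resource generator. Emulates, at desk scale, the four resource
# files the pipeline consumes (categorized miRNA set collections, a target-
# prediction table, the gene identifier cross-reference, pathway
# definitions), with optional planted enrichments: designated genes draw
# their regulators with elevated odds toward one miRNA set, which is the
# ground truth for recovery and type-I studies. All randomness is governed
# by the spec's seed; a fixed seed yields byte-identical files.

#' Describe a planted enrichment
#'
#' @param genes Gene symbol(s) whose regulators are oversampled toward the
#'   set. Planted genes are excluded from the uniform background pairing;
#'   their regulator sets are exactly `n_regulators` weighted draws.
#' @param category,set_name The miRNA set the regulators are biased toward.
#' @param odds Sampling odds of a set member relative to a non-member
#'   (at least 1; 1 = no enrichment).
#' @param n_regulators Number of distinct regulators drawn per planted gene.
#' @param set_size Optional exact size for the named set, overriding the
#'   spec's set-size range.
#' @return A planting rule for [fixture_spec()].
#' @export
planted_rule <- function(genes, category, set_name, odds = 8,
                         n_regulators = 25, set_size = NULL) {
  check_category(category)
  if (!is.numeric(odds) || odds < 1) {
    mirsets_abort("`odds` must be >= 1", class = "mirsets_parameter_error")
  }
  if (!is.numeric(n_regulators) || n_regulators < 1) {
    mirsets_abort("`n_regulators` must be >= 1",
                  class = "mirsets_parameter_error")
  }
  list(genes = genes, category = category, set_name = set_name,
       odds = odds, n_regulators = as.integer(n_regulators),
       set_size = if (!is.null(set_size)) as.integer(set_size))
}

#' Specify a synthetic resource universe
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package's validation: a universe of 200 miRNAs, 100 genes, six sets per
#' category with 10-20 members, and 4-12 predicted targets per miRNA.
#'
#' @param seed Integer RNG seed; fixed seed implies byte-identical output.
#' @param n_mirnas,n_genes Universe sizes.
#' @param n_sets_per_category Named integer vector (all five categories).
#' @param set_size_range,pairs_per_mirna_range Inclusive integer ranges.
#' @param planted List of [planted_rule()]s.
#' @param set_names Optional list: category -> character vector of set names
#'   (overrides `n_sets_per_category` for that category).
#' @param gene_names Optional character vector of gene symbols (overrides
#'   `n_genes`).
#' @param pathways List of `list(name =, n_genes =)` or `list(name =,
#'   genes =)` entries.
#' @param xref_overrides List: symbol -> named list of namespace overrides.
#' @param source Prediction source label stamped on the target map.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(seed = 1L,
                         n_mirnas = 200L,
                         n_genes = 100L,
                         n_sets_per_category = c(
                           Cluster = 6L, Family = 6L, Function = 6L,
                           HMDD = 6L, TissueSpecific = 6L
                         ),
                         set_size_range = c(10L, 20L),
                         pairs_per_mirna_range = c(4L, 12L),
                         planted = list(),
                         set_names = NULL,
                         gene_names = NULL,
                         pathways = list(list(name = "pathway_1",
                                              n_genes = 8L)),
                         xref_overrides = list(),
                         source = "targetscan") {
  if (any(c(n_mirnas, n_genes, set_size_range, pairs_per_mirna_range) < 1)) {
    mirsets_abort("all fixture sizes must be >= 1",
                  class = "mirsets_parameter_error")
  }
  if (!all(MIRNA_SET_CATEGORIES %in% names(n_sets_per_category))) {
    mirsets_abort("`n_sets_per_category` must name all five categories",
                  class = "mirsets_parameter_error")
  }
  if (set_size_range[1] > set_size_range[2] ||
      pairs_per_mirna_range[1] > pairs_per_mirna_range[2]) {
    mirsets_abort("ranges must be (lo, hi) with lo <= hi",
                  class = "mirsets_parameter_error")
  }
  structure(
    list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
         n_genes = as.integer(n_genes),
         n_sets_per_category = n_sets_per_category,
         set_size_range = as.integer(set_size_range),
         pairs_per_mirna_range = as.integer(pairs_per_mirna_range),
         planted = planted, set_names = set_names, gene_names = gene_names,
         pathways = pathways, xref_overrides = xref_overrides,
         source = source),
    class = "fixture_spec"
  )
}

# Deterministic, already-normalized miRNA names; a fraction carry a mature
# arm suffix so the normalizer's arm-preservation contract is exercised.
make_mirna_names <- function(n) {
  base <- sprintf("hsa-mir-%d", seq_len(n))
  arm <- rep("", n)
  arm[seq_len(n) %% 5L == 0L] <- "-5p"
  arm[seq_len(n) %% 7L == 0L] <- "-3p"
  paste0(base, arm)
}

sample_range <- function(range, n) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate the full resource bundle in memory
#'
#' @param spec A [fixture_spec()].
#' @return A list with `resources` (a ready [mir_resources()] bundle),
#'   `tables` (the raw tibbles behind each file: per-category `sets`,
#'   `pairs`, `xref`, `pathways`), and `manifest` (spec echo plus planted
#'   truths).
#' @export
simulate_resources <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    mirnas <- make_mirna_names(spec$n_mirnas)
    genes <- spec$gene_names %||% sprintf("GENE%04d", seq_len(spec$n_genes))
    genes <- unique(genes)

    # categorized miRNA sets; planted rules may pin a set's exact size
    sets <- dplyr::bind_rows(lapply(MIRNA_SET_CATEGORIES, function(cat_) {
      nm <- spec$set_names[[cat_]] %||%
        sprintf("%s_set_%02d", tolower(cat_),
                seq_len(spec$n_sets_per_category[[cat_]]))
      sizes <- pmin(sample_range(spec$set_size_range, length(nm)),
                    length(mirnas))
      for (rule in spec$planted) {
        if (rule$category == cat_ && !is.null(rule$set_size)) {
          j <- match(rule$set_name, nm)
          if (!is.na(j)) sizes[j] <- min(rule$set_size, length(mirnas))
        }
      }
      tibble::tibble(
        category = cat_,
        name = nm,
        description = sprintf("synthetic %s set", cat_),
        members = lapply(sizes, function(s) sort(sample(mirnas, s)))
      )
    }))
    for (rule in spec$planted) {
      hit <- sets$category == rule$category & sets$name == rule$set_name
      if (!any(hit)) {
        mirsets_abort(
          sprintf("planted rule names unknown set %s/%s",
                  rule$category, rule$set_name),
          class = "mirsets_parameter_error"
        )
      }
    }

    # target pairs: uniform background for non-planted genes, then exactly
    # n_regulators weighted draws per planted gene
    planted_genes <- unique(unlist(lapply(spec$planted, `[[`, "genes")))
    missing <- setdiff(planted_genes, genes)
    if (length(missing)) {
      mirsets_abort(
        sprintf("planted gene(s) not in the gene universe: %s",
                paste(missing, collapse = ", ")),
        class = "mirsets_parameter_error"
      )
    }
    base_genes <- setdiff(genes, planted_genes)
    npairs <- sample_range(spec$pairs_per_mirna_range, length(mirnas))
    npairs <- pmin(npairs, length(base_genes))
    pair_list <- lapply(seq_along(mirnas), function(i) {
      if (npairs[i] == 0L || length(base_genes) == 0L) return(NULL)
      tibble::tibble(mirna = mirnas[i],
                     gene_symbol = sample(base_genes, npairs[i]))
    })
    planted_list <- lapply(spec$planted, function(rule) {
      members <- sets$members[[which(sets$category == rule$category &
                                       sets$name == rule$set_name)]]
      w <- ifelse(mirnas %in% members, rule$odds, 1)
      dplyr::bind_rows(lapply(rule$genes, function(g) {
        tibble::tibble(
          mirna = sample(mirnas, min(rule$n_regulators, length(mirnas)),
                         prob = w),
          gene_symbol = g
        )
      }))
    })
    pairs <- dplyr::bind_rows(c(pair_list, planted_list))

    # cross-reference: aliases are deterministic functions of the symbol index
    i <- seq_along(genes)
    xref <- tibble::tibble(
      symbol = genes,
      entrez = as.character(100000L + i),
      ensembl_gene = sprintf("ENSG%011d", i),
      ensembl_transcript = sprintf("ENST%011d", i),
      ucsc = sprintf("uc%06d.1", i),
      refseq_mrna = sprintf("NM_%06d", i),
      genbank = sprintf("AB%06d", i)
    )
    for (sym in names(spec$xref_overrides)) {
      j <- match(sym, xref$symbol)
      if (is.na(j)) next
      for (ns in names(spec$xref_overrides[[sym]])) {
        xref[[ns]][j] <- spec$xref_overrides[[sym]][[ns]]
      }
    }

    pathway_tbl <- dplyr::bind_rows(lapply(spec$pathways, function(pw) {
      gs <- pw$genes %||% sample(genes, min(pw$n_genes, length(genes)))
      tibble::tibble(name = pw$name, description = "synthetic pathway",
                     genes = list(sort(unique(gs))))
    }))

    manifest <- list(
      seed = spec$seed,
      n_mirnas = spec$n_mirnas,
      n_genes = length(genes),
      source = spec$source,
      planted = lapply(spec$planted, function(rule) {
        list(genes = as.list(rule$genes), category = rule$category,
             set_name = rule$set_name, odds = rule$odds,
             n_regulators = rule$n_regulators)
      })
    )

    resources <- suppressMessages(mir_resources(
      catalog = new_mir_catalog(sets),
      target_map = new_target_map(pairs, source = spec$source),
      xref = build_gene_xref(xref),
      pathways = if (nrow(pathway_tbl)) pathway_tbl
    ))
    list(resources = resources,
         tables = list(sets = sets, pairs = pairs, xref = xref,
                       pathways = pathway_tbl),
         manifest = manifest)
  })
}

#' Write a simulated resource bundle to disk
#'
#' Emits one GMT per category (`cluster.gmt`, ..., `tissuespecific.gmt`),
#' `target_map.tsv`, `gene_xref.tsv`, `pathways.gmt`, a `manifest.yaml`
#' recording the planted truths, and a ready-to-use `run_config.yaml` with
#' paths relative to the output directory.
#'
#' @param sim Result of [simulate_resources()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(sim, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outdir, mode = 2L) != 0L) {
    mirsets_abort(sprintf("cannot write to directory: %s", outdir),
                  class = "mirsets_io_error")
  }
  paths <- character(0)
  catalog_files <- list()
  for (cat_ in MIRNA_SET_CATEGORIES) {
    f <- file.path(outdir, paste0(tolower(cat_), ".gmt"))
    write_set_collection(sim$tables$sets[sim$tables$sets$category == cat_, ], f)
    catalog_files[[cat_]] <- basename(f)
    paths[cat_] <- f
  }
  tm <- file.path(outdir, "target_map.tsv")
  write_tsv_plain(sim$tables$pairs, tm)
  paths["target_map"] <- tm
  xr <- file.path(outdir, "gene_xref.tsv")
  write_tsv_plain(sim$tables$xref, xr)
  paths["xref"] <- xr
  pw <- file.path(outdir, "pathways.gmt")
  pw_tbl <- sim$tables$pathways
  writeLines(vapply(seq_len(nrow(pw_tbl)), function(i) {
    paste(c(pw_tbl$name[i], pw_tbl$description[i], pw_tbl$genes[[i]]),
          collapse = "\t")
  }, ""), pw, useBytes = TRUE)
  paths["pathways"] <- pw
  mf <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(sim$manifest, mf)
  paths["manifest"] <- mf
  cfg <- file.path(outdir, "run_config.yaml")
  yaml::write_yaml(list(
    catalog = catalog_files,
    target_map = "target_map.tsv",
    xref = "gene_xref.tsv",
    pathways = "pathways.gmt",
    source = sim$manifest$source,
    threshold = 1L,
    rank_key = "p_value",
    correction_scope = "per_category",
    fdr_cutoff = 0.05
  ), cfg)
  paths["config"] <- cfg
  invisible(paths)
}

write_tsv_plain <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Generate a fixture directory from a spec
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory.
#' @return Written paths, invisibly.
#' @export
generate_fixture <- function(spec, outdir) {
  write_fixture(simulate_resources(spec), outdir)
}

#' The bundled demo fixture
#'
#' A fixed synthetic universe shaped like the tool's two classic use cases:
#' a gene named ABL2 whose regulators are planted into the Function set
#' "tumor_suppressors", and a pathway named "cell_cycle" in which three
#' member genes are planted into the Function set "cell_cycle". Set names
#' are cancer/tissue flavored so reports read like real analyses; all data
#' are synthetic. ABL2 carries Entrez id 27.
#'
#' @param outdir Optional; when given the fixture files are also written
#'   there.
#' @return The [simulate_resources()] bundle, invisibly.
#' @export
demo_fixture <- function(outdir = NULL) {
  spec <- fixture_spec(
    seed = 42L,
    n_mirnas = 200L,
    gene_names = c("ABL2", sprintf("GENE%04d", seq_len(119L))),
    set_names = list(
      Cluster = c("mir-302a", "mir-181c", "mir-106b", "mir-17",
                  "mir-15a", "mir-371"),
      Family = c("let-7", "mir-30", "mir-17", "mir-15", "mir-181",
                 "mir-302"),
      Function = c("tumor_suppressors", "anti_cell_proliferation",
                   "cell_cycle", "apoptosis", "immune_response",
                   "onco_mirnas"),
      HMDD = c("melanoma", "leukemia", "lymphoma", "heart_failure",
               "schizophrenia", "digestive_cancer"),
      TissueSpecific = c("heart", "brain", "liver", "lung", "kidney",
                         "muscle")
    ),
    planted = list(
      planted_rule("ABL2", "Function", "tumor_suppressors",
                   odds = 8, n_regulators = 25, set_size = 20),
      planted_rule(c("GENE0001", "GENE0002", "GENE0003"),
                   "Function", "cell_cycle",
                   odds = 8, n_regulators = 25, set_size = 20)
    ),
    pathways = list(list(
      name = "cell_cycle",
      genes = c(sprintf("GENE%04d", 1:6), "ABL2")
    )),
    xref_overrides = list(ABL2 = list(entrez = "27"))
  )
  sim <- simulate_resources(spec)
  if (!is.null(outdir)) write_fixture(sim, outdir)
  invisible(sim)
}

#' Read a gene-list file
#'
#' One identifier per line, one column; CRLF and LF line endings both
#' accepted; blank lines ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    mirsets_abort(sprintf("file not found: %s", path), "mirsets_io_error")
  }
  lines <- trimws(sub("\r$", "", readLines(path, warn = FALSE)))
  lines[nzchar(lines)]
}
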
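# Categorized miRNA set collections: GMT I/O, identifier normalization,
# and the catalog container used as one half of the enrichment background.

# Closed vocabulary: report grouping depends on these five names being stable.
MIRNA_SET_CATEGORIES <- c("Cluster", "Family", "Function", "HMDD", "TissueSpecific")

#' The five miRNA set categories
#'
#' Predefined miRNA sets are grouped into five fixed categories: genomic
#' cluster, sequence family, curated function, associated disease (HMDD),
#' and tissue specificity. Unknown category names are rejected everywhere
#' rather than passed through, so that report grouping stays stable.
#'
#' @return Character vector of the five category names.
#' @export
#' @examples
#' set_categories()
set_categories <- function() MIRNA_SET_CATEGORIES

check_category <- function(category) {
  if (!is.character(category) || length(category) != 1L ||
      !category %in% MIRNA_SET_CATEGORIES) {
    mirsets_abort(
      sprintf(
        "`category` must be one of: %s",
        paste(MIRNA_SET_CATEGORIES, collapse = ", ")
      ),
      class = "mirsets_validation_error"
    )
  }
  category
}

#' Normalize a miRNA identifier
#'
#' Lowercases and trims a miRNA name so that identifiers join consistently
#' across set collections and target-prediction tables. The species prefix
#' and any mature-arm suffix (`-5p`/`-3p`) are retained; no precursor/mature
#' expansion is attempted. Normalization is idempotent.
#'
#' @param raw Character vector of miRNA names.
#' @return Character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_mirna_id("hsa-miR-302a")
#' normalize_mirna_id(" hsa-let-7a-5p ")
normalize_mirna_id <- function(raw) {
  if (!is.character(raw)) {
    mirsets_abort("miRNA identifiers must be character", "mirsets_invalid_id")
  }
  out <- tolower(trimws(raw))
  if (length(out) && any(!nzchar(out) | is.na(out))) {
    mirsets_abort(
      "empty or whitespace-only miRNA identifier",
      class = "mirsets_invalid_id"
    )
  }
  if (length(out) && any(grepl("[[:space:]]", out))) {
    mirsets_abort(
      "miRNA identifier contains internal whitespace",
      class = "mirsets_invalid_id"
    )
  }
  out
}

# Shared GMT line reader. Returns a tibble(name, description, members) where
# members is a list column of character vectors; `normalize` is applied to
# every member (identity for gene-level pathway files).
read_gmt <- function(path, normalize = identity, what = "set") {
  if (!file.exists(path)) {
    mirsets_abort(
      sprintf("file not found: %s", path),
      class = "mirsets_io_error"
    )
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    mirsets_abort(
      sprintf("no %s records in %s", what, path),
      class = "mirsets_validation_error"
    )
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 3L)) {
    bad <- lineno[which(nfield < 3L)[1L]]
    mirsets_abort(
      sprintf(
        "malformed GMT line %d in %s: fewer than 3 tab-separated fields",
        bad, path
      ),
      class = "mirsets_parse_error"
    )
  }
  name <- trimws(vapply(fields, `[[`, "", 1L))
  description <- vapply(fields, `[[`, "", 2L)
  members <- lapply(seq_along(fields), function(i) {
    m <- normalize(trimws(fields[[i]][-(1:2)]))
    m <- m[nzchar(m)]
    if (anyDuplicated(m)) {
      rlang::warn(sprintf(
        "duplicate members collapsed in %s '%s' (%s line %d)",
        what, name[i], path, lineno[i]
      ))
      m <- unique(m)
    }
    m
  })
  if (anyDuplicated(name)) {
    dup <- unique(name[duplicated(name)])
    mirsets_abort(
      sprintf(
        "duplicate %s name(s) in %s: %s",
        what, path, paste(dup, collapse = ", ")
      ),
      class = "mirsets_validation_error"
    )
  }
  empty <- lengths(members) == 0L
  if (any(empty)) {
    mirsets_abort(
      sprintf(
        "%s '%s' in %s has no members",
        what, name[which(empty)[1L]], path
      ),
      class = "mirsets_validation_error"
    )
  }
  tibble::tibble(name = name, description = description, members = members)
}

#' Read one categorized miRNA set collection (GMT)
#'
#' One set per line: `set_name<TAB>description<TAB>member1<TAB>member2...`.
#' Lines starting with `#` are ignored. Members are normalized with
#' [normalize_mirna_id()]; duplicate members within a line are collapsed
#' with a warning; a duplicated set name within the file is an error.
#'
#' @param path Path to a GMT file.
#' @param category One of [set_categories()].
#' @return A tibble with columns `category`, `name`, `description`, and the
#'   list column `members`.
#' @export
read_set_collection <- function(path, category) {
  check_category(category)
  sets <- read_gmt(path, normalize = normalize_mirna_id, what = "miRNA set")
  tibble::tibble(
    category = category,
    name = sets$name,
    description = sets$description,
    members = sets$members
  )
}

#' Write miRNA sets back to GMT
#'
#' Inverse of [read_set_collection()] for one category's sets: re-reading the
#' written file yields identical set names and members.
#'
#' @param sets Tibble as returned by [read_set_collection()] (one category).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_set_collection <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$name[i], sets$description[i], sets$members[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

new_mir_catalog <- function(sets) {
  stopifnot(all(c("category", "name", "members") %in% names(sets)))
  dup <- duplicated(paste(sets$category, sets$name, sep = "\r"))
  if (any(dup)) {
    mirsets_abort(
      sprintf(
        "duplicate set name within a category: %s",
        paste(unique(paste0(sets$category[dup], "/", sets$name[dup])),
              collapse = ", ")
      ),
      class = "mirsets_validation_error"
    )
  }
  structure(
    list(
      sets = sets,
      universe = sort(unique(unlist(sets$members, use.names = FALSE)))
    ),
    class = "mir_catalog"
  )
}

#' Build a miRNA set catalog from per-category GMT files
#'
#' @param collections Named character vector or named list mapping each
#'   category name (see [set_categories()]) to a GMT file path. At least one
#'   collection is required.
#' @return A `mir_catalog`: list with `sets` (tibble of all sets) and
#'   `universe` (sorted distinct miRNA ids across all sets).
#' @export
build_catalog <- function(collections) {
  collections <- unlist(collections)
  if (length(collections) == 0L) {
    mirsets_abort("at least one set collection is required",
                  class = "mirsets_config_error")
  }
  if (is.null(names(collections)) || any(!nzchar(names(collections)))) {
    mirsets_abort("`collections` must be named by category",
                  class = "mirsets_config_error")
  }
  if (anyDuplicated(names(collections))) {
    mirsets_abort("duplicate category in `collections`",
                  class = "mirsets_config_error")
  }
  sets <- dplyr::bind_rows(lapply(names(collections), function(cat) {
    read_set_collection(collections[[cat]], cat)
  }))
  new_mir_catalog(sets)
}

#' @export
print.mir_catalog <- function(x, ...) {
  cat(sprintf(
    "miRNA set catalog: %d sets in %d categories, universe of %d miRNAs\n",
    nrow(x$sets), length(unique(x$sets$category)), length(x$universe)
  ))
  tab <- table(x$sets$category)
  for (cat_ in names(tab)) {
    cat(sprintf("  %-15s %d sets\n", cat_, tab[[cat_]]))
  }
  invisible(x)
}
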
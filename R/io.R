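#' Read a featureCounts gene-level count table
#'
#' Parses the tab- or whitespace-delimited gene-level output of featureCounts:
#' an optional leading `#` comment line, then a header with the six annotation
#' columns `Geneid, Chr, Start, End, Strand, Length` followed by one column
#' per sample. Only `Geneid` and `Length` are used; the positional annotation
#' columns are ignored. Sample column names that look like file paths (the
#' featureCounts default of naming columns after BAM files) are normalized to
#' their basename.
#'
#' @param path Path to a featureCounts-style count table.
#' @return A tibble with columns `gene_id`, `length` (bp) and one nonnegative
#'   integer count column per sample, in file order.
#' @export
read_featurecounts <- function(path) {
  if (!file.exists(path)) abort(sprintf("Count file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) abort(sprintf("No header line in %s", path))
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ""
  df <- read.table(text = lines, header = TRUE, sep = sep,
                   check.names = FALSE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  anno <- c("Geneid", "Chr", "Start", "End", "Strand", "Length")
  if (!identical(names(df)[seq_along(anno)], anno)) {
    abort(paste0("Malformed featureCounts header: expected columns ",
                 paste(anno, collapse = ", "),
                 " followed by sample columns."))
  }
  sample_cols <- names(df)[-seq_along(anno)]
  if (length(sample_cols) == 0L) abort("No sample columns found.")
  if (anyDuplicated(df$Geneid)) {
    dups <- unique(df$Geneid[duplicated(df$Geneid)])
    abort(sprintf("Duplicate Geneid(s): %s", paste(head(dups, 5L), collapse = ", ")))
  }
  counts <- as.matrix(df[sample_cols])
  if (!is.numeric(counts)) abort("Non-numeric count cell found.")
  assert_integral(counts)
  if (any(counts < 0)) abort("Negative count cell found.")
  if (any(!is.finite(df$Length)) || any(df$Length <= 0) ||
      any(df$Length != round(df$Length))) {
    abort("Length column must contain positive integers.")
  }
  out <- tibble::tibble(gene_id = as.character(df$Geneid),
                        length = as.integer(df$Length))
  counts <- round(counts)
  colnames(counts) <- basename(sample_cols)
  if (anyDuplicated(colnames(counts))) {
    abort("Duplicate sample column names after basename normalization.")
  }
  dplyr::bind_cols(out, tibble::as_tibble(counts))
}

#' Write a count table in the featureCounts dialect
#'
#' Writes a tab-separated gene-level table readable by [read_featurecounts()]:
#' a `#` comment line, then `Geneid, Chr, Start, End, Strand, Length` plus one
#' column per sample. Positional annotation columns are filled with
#' placeholders (they are ignored on read).
#'
#' @param counts Wide count tibble (`gene_id`, `length`, sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_featurecounts <- function(counts, path) {
  validate_counts(counts)
  cols <- value_cols(counts)
  out <- tibble::tibble(Geneid = counts$gene_id, Chr = ".",
                        Start = 1L, End = as.integer(counts$length),
                        Strand = "+", Length = as.integer(counts$length))
  out <- dplyr::bind_cols(out, counts[cols])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# Program:entroseq gene-level counts", con)
  writeLines(paste(names(out), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a condition metadata table
#'
#' Tab-separated with columns `condition_id`, `sample_ids` (comma-joined
#' member sample/accession IDs), `description`, `category`. Categories must be
#' one of `Metabolism`, `Development`, `Light Response`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `condition_id`, `sample_ids` (list-column of
#'   character vectors), `description`, `category`.
#' @export
read_condition_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Condition table not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("condition_id", "sample_ids", "description", "category")
  if (!all(need %in% names(df))) {
    abort(sprintf("Condition table must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  ct <- tibble::tibble(
    condition_id = df$condition_id,
    sample_ids = lapply(strsplit(df$sample_ids, ","), trimws),
    description = df$description,
    category = df$category
  )
  validate_condition_table(ct)
}

#' Build a condition table in memory
#'
#' @param condition_id Character vector of condition IDs.
#' @param sample_ids List of character vectors, member samples per condition.
#' @param description Optional descriptions (default empty strings).
#' @param category Category per condition, each one of `Metabolism`,
#'   `Development`, `Light Response`.
#' @return A validated condition tibble.
#' @export
condition_table <- function(condition_id, sample_ids,
                            description = rep("", length(condition_id)),
                            category = rep("Metabolism", length(condition_id))) {
  ct <- tibble::tibble(condition_id = as.character(condition_id),
                       sample_ids = lapply(sample_ids, as.character),
                       description = as.character(description),
                       category = as.character(category))
  validate_condition_table(ct)
}

condition_categories <- c("Metabolism", "Development", "Light Response")

validate_condition_table <- function(ct) {
  if (anyDuplicated(ct$condition_id)) abort("Duplicate condition_id values.")
  members <- unlist(ct$sample_ids)
  if (anyDuplicated(members)) {
    dups <- unique(members[duplicated(members)])
    abort(sprintf("Sample(s) assigned to more than one condition: %s",
                  paste(head(dups, 5L), collapse = ", ")))
  }
  bad <- setdiff(unique(ct$category), condition_categories)
  if (length(bad)) {
    abort(sprintf("Unknown category value(s): %s (must be one of %s)",
                  paste(bad, collapse = ", "),
                  paste(condition_categories, collapse = ", ")))
  }
  ct
}

#' Write a condition table
#'
#' @param ct Condition tibble as returned by [read_condition_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_condition_table <- function(ct, path) {
  out <- tibble::tibble(
    condition_id = ct$condition_id,
    sample_ids = vapply(ct$sample_ids, paste, "", collapse = ","),
    description = ct$description,
    category = ct$category
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Merge replicate samples into condition columns
#'
#' Gene-level read counts are additive over reads, so summing replicate count
#' columns is exactly equivalent to merging replicate alignments before
#' counting. Each output column is the sum of the member samples' counts.
#'
#' @param counts Wide count tibble (`gene_id`, `length`, one column per sample).
#' @param conditions Condition tibble; every sample column of `counts` must
#'   appear as a member of exactly one condition.
#' @return A count tibble with one column per condition, gene order unchanged.
#'   Conditions with no member present in `counts` are dropped with a warning.
#' @export
merge_replicates <- function(counts, conditions) {
  validate_counts(counts)
  samples <- value_cols(counts)
  members <- unlist(conditions$sample_ids)
  unmapped <- setdiff(samples, members)
  if (length(unmapped)) {
    abort(sprintf("Sample(s) in counts but not in the condition table: %s",
                  paste(unmapped, collapse = ", ")))
  }
  m <- value_matrix(counts)
  cols <- lapply(conditions$sample_ids, function(ids) {
    present <- intersect(ids, samples)
    if (length(present) == 0L) return(NULL)
    rowSums(m[, present, drop = FALSE])
  })
  empty <- vapply(cols, is.null, TRUE)
  if (any(empty)) {
    warn(sprintf("Dropping condition(s) with no sample column present: %s",
                 paste(conditions$condition_id[empty], collapse = ", ")))
  }
  merged <- do.call(cbind, cols[!empty])
  colnames(merged) <- conditions$condition_id[!empty]
  dplyr::bind_cols(counts[c("gene_id", "length")], tibble::as_tibble(merged))
}

#' Read an identifier map
#'
#' Two-column TSV (header or not) mapping one gene identifier namespace to
#' another, e.g. NCU accession numbers to assembly gene IDs. No source ID may
#' map to two targets.
#'
#' @param path Path to the two-column TSV.
#' @return A tibble with columns `from`, `to`.
#' @export
read_id_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("ID map not found: %s", path))
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "#")
  if (ncol(df) < 2L) abort("ID map must have two tab-separated columns.")
  names(df)[1:2] <- c("from", "to")
  if (identical(tolower(df$from[1L]), "from")) df <- df[-1L, ]
  conflicts <- tapply(df$to, df$from, function(x) length(unique(x)))
  if (any(conflicts > 1L)) {
    abort(sprintf("Source ID(s) map to multiple targets: %s",
                  paste(head(names(conflicts)[conflicts > 1L], 5L), collapse = ", ")))
  }
  tibble::as_tibble(unique(df[c("from", "to")]))
}

#' Read a gene-set list
#'
#' One gene identifier per line; blank lines are ignored and duplicates are
#' removed (and reported). If an ID map is supplied, identifiers are
#' translated and untranslatable IDs are reported in the result, never
#' silently dropped.
#'
#' @param path Path to the plain-text list.
#' @param name Label for the set (default: the file's base name).
#' @param id_map Optional tibble with columns `from`, `to` (see
#'   [read_id_map()]).
#' @return An object of class `gene_set`: a list with `name`, `gene_ids`,
#'   `duplicates` (IDs that appeared more than once) and `unmapped`
#'   (IDs the map could not translate).
#' @export
read_gene_set <- function(path, name = NULL, id_map = NULL) {
  if (!file.exists(path)) abort(sprintf("Gene-set file not found: %s", path))
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids)]
  gene_set(ids, name = name %||% tools::file_path_sans_ext(basename(path)),
           id_map = id_map)
}

#' Construct a gene set from identifiers
#'
#' @param ids Character vector of gene identifiers.
#' @inheritParams read_gene_set
#' @return A `gene_set` object.
#' @export
gene_set <- function(ids, name = "gene_set", id_map = NULL) {
  ids <- as.character(ids)
  duplicates <- unique(ids[duplicated(ids)])
  ids <- unique(ids)
  unmapped <- character()
  if (!is.null(id_map)) {
    idx <- match(ids, id_map$from)
    unmapped <- ids[is.na(idx)]
    ids <- id_map$to[idx[!is.na(idx)]]
  }
  if (length(ids) == 0L) {
    abort(sprintf("Gene set '%s' is empty after filtering.", name))
  }
  structure(list(name = name, gene_ids = ids, duplicates = duplicates,
                 unmapped = unmapped),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s': %d genes>\n", x$name, length(x$gene_ids)))
  if (length(x$duplicates)) {
    cat(sprintf("  %d duplicated input ID(s) removed\n", length(x$duplicates)))
  }
  if (length(x$unmapped)) {
    cat(sprintf("  %d unmapped ID(s): %s\n", length(x$unmapped),
                paste(head(x$unmapped, 5L), collapse = ", ")))
  }
  invisible(x)
}

#' Merge gene sets
#'
#' @param ... `gene_set` objects.
#' @param name Name for the merged set.
#' @return A `gene_set` containing the union of member IDs.
#' @export
union_gene_sets <- function(..., name = "combined") {
  sets <- list(...)
  gene_set(unique(unlist(lapply(sets, `[[`, "gene_ids"))), name = name)
}

#' Write an entropy table to TSV
#'
#' Columns `gene_id`, `entropy`, `normalized_entropy`, `class`; undefined
#' scores (genes with zero counts in every condition) are written as `NA` with
#' class `excluded`. Scores are written at full double precision so a
#' write-then-read round trip reproduces them to well below 1e-9.
#'
#' @param table An `entropy_tbl` (see [compute_entropy_table()]) or a
#'   compatible data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_entropy_table <- function(table, path) {
  need <- c("gene_id", "entropy", "normalized_entropy", "class")
  if (!all(need %in% names(table))) {
    abort(sprintf("Entropy table must have columns: %s", paste(need, collapse = ", ")))
  }
  readr::write_tsv(tibble::as_tibble(table)[need], path, progress = FALSE)
  invisible(path)
}

#' Read an entropy table written by [write_entropy_table()]
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_id`, `entropy`, `normalized_entropy`,
#'   `class`; carries class `entropy_tbl` so downstream benchmarking functions
#'   accept it.
#' @export
read_entropy_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Entropy table not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", entropy = "d", normalized_entropy = "d", class = "c"
  ), progress = FALSE)
  class(df) <- c("entropy_tbl", class(df))
  df
}
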
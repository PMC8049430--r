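#' Look up specificity scores for a gene set
#'
#' Every member of the set is accounted for: genes absent from the table and
#' genes with undefined (excluded) scores are reported with a status, never
#' silently dropped.
#'
#' @param table An `entropy_tbl`.
#' @param gs A `gene_set` (see [gene_set()] / [read_gene_set()]).
#' @return A tibble with one row per set member: `gene_id`, `entropy` (`NA`
#'   unless scored) and `status` in `scored`, `excluded`, `missing`; the set
#'   name is carried in attribute `set_name`. Errors if no member is scored.
#' @export
geneset_scores <- function(table, gs) {
  if (!inherits(gs, "gene_set")) abort("`gs` must be a gene_set.")
  idx <- match(gs$gene_ids, table$gene_id)
  status <- dplyr::case_when(
    is.na(idx) ~ "missing",
    table$class[idx] == "excluded" ~ "excluded",
    TRUE ~ "scored"
  )
  out <- tibble::tibble(gene_id = gs$gene_ids,
                        entropy = ifelse(status == "scored",
                                         table$entropy[idx], NA_real_),
                        status = status)
  if (!any(status == "scored")) {
    abort(sprintf("Gene set '%s' has no scored members.", gs$name))
  }
  attr(out, "set_name") <- gs$name
  out
}

kde_bandwidth <- function(x, rule) {
  if (is.numeric(rule)) {
    check_scalar_number(rule, "bandwidth", lo = 1e-12)
    return(rule)
  }
  switch(match.arg(rule, c("scott", "silverman")),
         scott = sd(x) * length(x)^(-1 / 5),
         silverman = stats::bw.nrd0(x))
}

#' Gaussian kernel density estimate of a score distribution
#'
#' A smoothed histogram of specificity scores, evaluated on a 512-point grid
#' spanning the data plus three bandwidths on either side, so the curve
#' integrates to one. Deterministic: identical inputs give identical output.
#'
#' @param scores Numeric scores in bits, or a tibble from [geneset_scores()]
#'   (its `scored` rows are used).
#' @param bandwidth `"scott"` (default; sd * n^(-1/5)), `"silverman"`
#'   (Silverman's rule of thumb), or a fixed positive number.
#' @return A `score_kde` object: list with `grid` (tibble of `score`,
#'   `density`), `rug` (the raw scores), `bandwidth` and `name`. Plot with
#'   [autoplot()].
#' @export
score_kde <- function(scores, bandwidth = "scott") {
  name <- "scores"
  if (is.data.frame(scores)) {
    name <- attr(scores, "set_name") %||% name
    scores <- scores$entropy[scores$status == "scored"]
  }
  scores <- as.numeric(scores)
  if (length(scores) < 2L) abort("KDE needs at least 2 scores.")
  if (sd(scores) == 0) {
    abort("Scores are constant; the density is degenerate - use a rug-only plot.")
  }
  bw <- kde_bandwidth(scores, bandwidth)
  d <- density(scores, bw = bw, kernel = "gaussian", n = 512L, cut = 3)
  structure(list(grid = tibble::tibble(score = d$x, density = d$y),
                 rug = scores, bandwidth = bw, name = name),
            class = "score_kde")
}

#' @export
print.score_kde <- function(x, ...) {
  cat(sprintf("<score_kde '%s': n = %d, bandwidth = %.4g, mode at %.3f bits>\n",
              x$name, length(x$rug), x$bandwidth, kde_mode(x)))
  invisible(x)
}

#' Location of the density maximum
#'
#' @param kde A `score_kde`.
#' @return Grid point (bits) where the estimated density is highest.
#' @export
kde_mode <- function(kde) {
  kde$grid$score[which.max(kde$grid$density)]
}

#' @rdname score_kde
#' @param object A `score_kde`.
#' @param ... Unused.
#' @export
autoplot.score_kde <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$score, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_rug(data = tibble::tibble(score = object$rug),
                      ggplot2::aes(x = .data$score), inherit.aes = FALSE,
                      sides = "b", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(title = object$name, x = "Entropy specificity (bits)",
                  y = "Density") +
    ggplot2::theme_minimal()
}

#' Entropy-ranked log2-TPM heatmap data for a gene set
#'
#' Builds the numeric matrix behind a benchmarking heatmap: rows are the set's
#' scored genes sorted by specificity score ascending (ties broken by gene ID
#' so output is reproducible), cells are `log2(TPM + pseudocount)`, and
#' columns carry the condition category annotation when a condition table is
#' supplied. Excluded genes are omitted. Rendering (palettes, sidebars) is a
#' plotting concern; this object holds only numbers.
#'
#' @param tpm TPM tibble from [compute_tpm()].
#' @param table An `entropy_tbl` over the same genes.
#' @param gs A `gene_set`; needs at least one scored member.
#' @param conditions Optional condition tibble annotating the TPM columns.
#' @param pseudocount Added to TPM before the log2 transform (default 1, so a
#'   TPM of zero maps to a cell value of zero).
#' @return A `heatmap_data` object: list with `values` (tibble: `gene_id`,
#'   `entropy`, one log2 column per condition), `row_scores` (non-decreasing),
#'   `column_categories` (or `NA`s) and `name`.
#' @export
ranked_heatmap <- function(tpm, table, gs, conditions = NULL, pseudocount = 1.0) {
  check_scalar_number(pseudocount, "pseudocount", lo = 1e-12)
  scores <- geneset_scores(table, gs)
  scored <- dplyr::filter(scores, .data$status == "scored")
  scored <- dplyr::arrange(scored, .data$entropy, .data$gene_id)
  idx <- match(scored$gene_id, tpm$gene_id)
  if (anyNA(idx)) {
    abort("Scored gene(s) missing from the TPM matrix.")
  }
  conds <- value_cols(tpm)
  m <- log2(value_matrix(tpm)[idx, , drop = FALSE] + pseudocount)
  cats <- rep(NA_character_, length(conds))
  if (!is.null(conditions)) {
    cats <- conditions$category[match(conds, conditions$condition_id)]
  }
  values <- dplyr::bind_cols(
    tibble::tibble(gene_id = scored$gene_id, entropy = scored$entropy),
    tibble::as_tibble(m)
  )
  structure(list(values = values, row_scores = scored$entropy,
                 column_categories = tibble::tibble(condition_id = conds,
                                                    category = cats),
                 name = gs$name),
            class = "heatmap_data")
}

#' @export
print.heatmap_data <- function(x, ...) {
  cat(sprintf("<heatmap_data '%s': %d genes x %d conditions, scores %.3f..%.3f>\n",
              x$name, nrow(x$values), nrow(x$column_categories),
              min(x$row_scores), max(x$row_scores)))
  invisible(x)
}

#' @rdname ranked_heatmap
#' @param object A `heatmap_data`.
#' @param ... Unused.
#' @export
autoplot.heatmap_data <- function(object, ...) {
  genes <- object$values$gene_id
  conds <- object$column_categories$condition_id
  n <- length(genes)
  long <- tidyr::pivot_longer(object$values, cols = -c("gene_id", "entropy"),
                              names_to = "condition_id", values_to = "log2_tpm")
  # lowest-entropy gene on the top row, categories in a strip above the matrix
  long$row <- n - match(long$gene_id, genes) + 1L
  long$col <- match(long$condition_id, conds)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row,
                                          fill = .data$log2_tpm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log2(TPM + pc)") +
    ggplot2::scale_y_continuous(breaks = seq_len(n), labels = rev(genes),
                                expand = ggplot2::expansion(add = c(0.5, 2))) +
    ggplot2::scale_x_continuous(breaks = seq_along(conds), labels = conds,
                                position = "top") +
    ggplot2::labs(title = object$name, x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 5),
                   axis.text.y = ggplot2::element_text(size = 5))
  cats <- object$column_categories$category
  if (!all(is.na(cats))) {
    ann <- tibble::tibble(col = seq_along(conds), category = cats)
    p <- p +
      ggplot2::geom_point(data = ann,
                          ggplot2::aes(x = .data$col, y = n + 1.3,
                                       color = .data$category),
                          shape = 15, size = 1.8, inherit.aes = FALSE) +
      ggplot2::scale_color_manual(
        name = "Category",
        values = c(Metabolism = "gold", Development = "forestgreen",
                   `Light Response` = "steelblue"),
        na.value = "grey70"
      )
  }
  p
}

#' Export heatmap data as TSV
#'
#' Writes a `#`-prefixed category annotation line, then one row per gene with
#' its score followed by the log2-transformed values.
#'
#' @param hm A `heatmap_data`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_tsv <- function(hm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("# category", "",
                     as.character(hm$column_categories$category)),
                   collapse = "\t"), con)
  writeLines(paste(names(hm$values), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(hm$values, function(x) {
    if (is.numeric(x)) format(x, digits = 10, trim = TRUE, scientific = FALSE)
    else as.character(x)
  }), sep = "\t"))
  if (length(body)) writeLines(body, con)
  invisible(path)
}

#' Lowest- and highest-scoring genes
#'
#' Selects the k scored genes with the smallest scores and the k with the
#' largest, ties broken by gene ID lexicographically; excluded genes are never
#' selected. The two selections are disjoint (at least 2k scored genes are
#' required).
#'
#' @param table An `entropy_tbl`.
#' @param k Number of genes per tail (default 100).
#' @return A list with tibbles `lowest` (ascending score) and `highest`
#'   (descending score), each with `gene_id` and `entropy`.
#' @export
extreme_genes <- function(table, k = 100L) {
  check_scalar_number(k, "k", lo = 1)
  k <- as.integer(k)
  scored <- tibble::as_tibble(unclass(table)[c("gene_id", "entropy", "class")])
  scored <- dplyr::filter(scored, .data$class != "excluded")
  if (nrow(scored) < 2L * k) {
    abort(sprintf("Need at least 2k = %d scored genes; have %d.",
                  2L * k, nrow(scored)))
  }
  asc <- dplyr::arrange(scored, .data$entropy, .data$gene_id)
  list(lowest = dplyr::select(head(asc, k), "gene_id", "entropy"),
       highest = dplyr::select(dplyr::arrange(tail(asc, k),
                                              dplyr::desc(.data$entropy),
                                              .data$gene_id),
                               "gene_id", "entropy"))
}
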
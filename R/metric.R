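#' Transcripts-per-million normalization
#'
#' For each condition column, each gene's count is divided by its length in
#' base pairs to give a read rate; rates are rescaled so every column sums to
#' one million. Columns with zero counts everywhere yield an all-zero TPM
#' column (with a warning) rather than an error, so degenerate inputs flow
#' through: such columns contribute a zero fraction to every gene and do not
#' perturb specificity scores.
#'
#' @param counts Wide count tibble: `gene_id`, `length` (bp, positive), one
#'   nonnegative integer count column per condition.
#' @return A tibble with `gene_id` and one TPM column per condition; every
#'   column with at least one nonzero count sums to 1e6.
#' @examples
#' cm <- tibble::tibble(gene_id = c("a", "b"), length = c(1000L, 2000L),
#'                      c1 = c(10, 10))
#' compute_tpm(cm)  # 666666.7 and 333333.3
#' @export
compute_tpm <- function(counts) {
  validate_counts(counts)
  assert_integral(as.matrix(counts[value_cols(counts)]))
  m <- value_matrix(counts)
  rate <- m / counts$length
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warn(sprintf("All-zero count column(s) produce all-zero TPM: %s",
                 paste(colnames(m)[tot == 0], collapse = ", ")))
  }
  tpm <- sweep(rate, 2L, ifelse(tot > 0, tot, 1), "/") * 1e6
  dplyr::bind_cols(counts["gene_id"], tibble::as_tibble(tpm))
}

#' Cross-condition expression fractions for one gene
#'
#' Divides a gene's per-condition TPM row by its total, giving the probability
#' vector over conditions that the specificity score is computed from. The
#' profile is undefined (all `NA`) exactly when the gene has zero TPM in every
#' condition.
#'
#' @param tpm_row Nonnegative numeric vector of length N >= 2, one gene's TPM
#'   per condition.
#' @return Numeric vector of fractions summing to 1, or a vector of `NA` when
#'   the row is all zero.
#' @export
condition_fractions <- function(tpm_row) {
  if (length(tpm_row) < 2L) {
    abort("Specificity needs at least 2 conditions.")
  }
  if (any(!is.finite(tpm_row)) || any(tpm_row < 0)) {
    abort("TPM values must be finite and nonnegative.")
  }
  tot <- sum(tpm_row)
  if (tot == 0) return(rep(NA_real_, length(tpm_row)))
  tpm_row / tot
}

#' Entropy-based condition-specificity score
#'
#' The score of a fraction profile p over N conditions is
#' `S = sum_t p_t * log2(p_t * N)`, with `0 * log 0 := 0` — equivalently the
#' Kullback-Leibler divergence from the uniform profile, `log2(N) - H(p)`
#' where H is Shannon entropy in bits. A gene expressed identically in every
#' condition scores 0; a gene expressed in exactly one condition scores
#' `log2(N)`, the analytic maximum. The result is clamped at 0 against
#' floating-point underflow.
#'
#' @param profile Fraction vector from [condition_fractions()]; an undefined
#'   (all-`NA`) profile yields `NA`.
#' @return Score in bits, in `[0, log2(N)]`, or `NA` for undefined profiles.
#' @export
entropy_specificity <- function(profile) {
  if (anyNA(profile)) return(NA_real_)
  n <- length(profile)
  nz <- profile[profile > 0]
  max(0, sum(nz * log2(nz * n)))
}

#' Specificity score scaled to `[0, 1]`
#'
#' [entropy_specificity()] divided by its analytic maximum `log2(N)`, so 0 is
#' perfectly uniform and 1 is single-condition expression regardless of the
#' number of conditions.
#'
#' @inheritParams entropy_specificity
#' @return Score in `[0, 1]`, or `NA` for undefined profiles.
#' @export
normalized_specificity <- function(profile) {
  entropy_specificity(profile) / log2(length(profile))
}

new_entropy_tbl <- function(df, n_conditions, threshold) {
  structure(df,
            n_conditions = n_conditions,
            threshold = threshold,
            class = c("entropy_tbl", class(tibble::tibble())))
}

#' Score and classify every gene in a TPM matrix
#'
#' Computes the entropy-based specificity score for each gene and labels genes
#' `constitutive-like` (score <= `threshold`) or `condition-specific`
#' (score > `threshold`, a strict reading of "above" the cutoff). Genes with
#' zero TPM in every condition have an undefined score and are labeled
#' `excluded`, mirroring the treatment of genes with zero read counts in all
#' conditions.
#'
#' @param tpm TPM tibble from [compute_tpm()] (`gene_id` + condition columns).
#' @param threshold Classification boundary in bits (default 1).
#' @return An `entropy_tbl`: a tibble with `gene_id`, `entropy` (bits, `NA`
#'   when undefined), `normalized_entropy` (score / log2 N) and `class`, with
#'   attributes `n_conditions` and `threshold`. Use [tidy()] / [glance()] to
#'   extract per-gene rows or a one-row summary.
#' @export
compute_entropy_table <- function(tpm, threshold = 1.0) {
  validate_counts(tpm, require_length = FALSE, arg = "tpm")
  check_scalar_number(threshold, "threshold", lo = 0)
  m <- value_matrix(tpm)
  n <- ncol(m)
  if (n < 2L) abort("Specificity needs at least 2 conditions.")
  tot <- rowSums(m)
  p <- m / tot
  terms <- p * log2(p * n)
  terms[m == 0] <- 0
  s <- pmax(0, rowSums(terms))
  s[tot == 0] <- NA_real_
  cls <- dplyr::case_when(
    is.na(s) ~ "excluded",
    s > threshold ~ "condition-specific",
    TRUE ~ "constitutive-like"
  )
  df <- tibble::tibble(gene_id = tpm$gene_id,
                       entropy = s,
                       normalized_entropy = s / log2(n),
                       class = cls)
  new_entropy_tbl(df, n_conditions = n, threshold = threshold)
}

#' Genes whose score is undefined
#'
#' @param table An `entropy_tbl`.
#' @return Character vector of gene IDs with zero expression in every
#'   condition (class `excluded`).
#' @export
excluded_genes <- function(table) {
  table$gene_id[table$class == "excluded"]
}

#' Count scored genes inside a score interval
#'
#' @param table An `entropy_tbl`.
#' @param lo,hi Interval bounds in bits (inclusive on both ends).
#' @return One-row tibble with `count`, `fraction` (denominator = number of
#'   scored, i.e. non-excluded, genes) and `n_scored`.
#' @export
interval_fraction <- function(table, lo, hi) {
  if (lo > hi) abort("`lo` must not exceed `hi`.")
  s <- table$entropy[table$class != "excluded"]
  if (length(s) == 0L) abort("No scored genes in the table.")
  count <- sum(s >= lo & s <= hi)
  tibble::tibble(count = count, fraction = count / length(s),
                 n_scored = length(s))
}

#' @export
print.entropy_tbl <- function(x, ...) {
  n <- attr(x, "n_conditions")
  cat(sprintf("# Entropy specificity table: %d genes over %s conditions (threshold %s bits)\n",
              nrow(x), n %||% "?", attr(x, "threshold") %||% "?"))
  NextMethod()
}

#' @rdname compute_entropy_table
#' @param x An `entropy_tbl`.
#' @param ... Unused.
#' @export
tidy.entropy_tbl <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("gene_id", "entropy", "normalized_entropy", "class")])
}

#' @rdname compute_entropy_table
#' @export
glance.entropy_tbl <- function(x, ...) {
  s <- x$entropy[x$class != "excluded"]
  tibble::tibble(
    n_genes = nrow(x),
    n_scored = length(s),
    n_excluded = sum(x$class == "excluded"),
    n_constitutive = sum(x$class == "constitutive-like"),
    n_specific = sum(x$class == "condition-specific"),
    n_conditions = attr(x, "n_conditions") %||% NA_integer_,
    threshold = attr(x, "threshold") %||% NA_real_,
    min_entropy = if (length(s)) min(s) else NA_real_,
    max_entropy = if (length(s)) max(s) else NA_real_,
    max_possible = if (!is.null(attr(x, "n_conditions"))) log2(attr(x, "n_conditions")) else NA_real_
  )
}

#' Histogram bin counts of scored genes
#'
#' Fixed-width binning of the defined scores, with the same binning used by
#' the pipeline's logged interval summaries; bin counts always sum to the
#' number of scored genes.
#'
#' @param table An `entropy_tbl`.
#' @param binwidth Bin width in bits (default 0.25).
#' @return Tibble with `bin_lo`, `bin_hi`, `count`.
#' @export
entropy_histogram <- function(table, binwidth = 0.25) {
  check_scalar_number(binwidth, "binwidth", lo = 1e-9)
  s <- table$entropy[table$class != "excluded"]
  if (length(s) == 0L) abort("No scored genes in the table.")
  edges <- seq(0, (floor(max(s) / binwidth) + 1) * binwidth, by = binwidth)
  idx <- pmin(findInterval(s, edges, rightmost.closed = TRUE), length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
                 count = counts)
}

#' Histogram of specificity scores
#'
#' @param table An `entropy_tbl`.
#' @param binwidth Bin width in bits.
#' @return A ggplot object.
#' @export
plot_entropy_histogram <- function(table, binwidth = 0.25) {
  bins <- entropy_histogram(table, binwidth)
  ggplot2::ggplot(bins, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                     y = .data$count)) +
    ggplot2::geom_col(width = binwidth, fill = "grey30") +
    ggplot2::labs(x = "Entropy specificity (bits)", y = "Genes") +
    ggplot2::theme_minimal()
}
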
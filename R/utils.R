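# Internal helpers shared across modules.

# Column names of a wide counts/TPM tibble that hold per-condition values.
value_cols <- function(df) {
  setdiff(names(df), c("gene_id", "length"))
}

# Extract the numeric genes x conditions matrix from a wide tibble.
value_matrix <- function(df) {
  cols <- value_cols(df)
  m <- as.matrix(df[cols])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

# Validate a wide count tibble: unique gene ids, positive lengths,
# nonnegative integral counts. `require_length` is FALSE for TPM tibbles.
validate_counts <- function(df, require_length = TRUE, arg = "counts") {
  if (!is.data.frame(df) || !"gene_id" %in% names(df)) {
    abort(sprintf("`%s` must be a data frame with a `gene_id` column.", arg))
  }
  if (anyDuplicated(df$gene_id)) {
    dups <- unique(df$gene_id[duplicated(df$gene_id)])
    abort(sprintf("Duplicate gene_id(s) in `%s`: %s", arg,
                  paste(head(dups, 5L), collapse = ", ")))
  }
  if (require_length) {
    if (!"length" %in% names(df)) {
      abort(sprintf("`%s` must have a `length` column (gene length in bp).", arg))
    }
    if (any(!is.finite(df$length)) || any(df$length <= 0)) {
      abort("All gene lengths must be positive.")
    }
  }
  cols <- value_cols(df)
  if (length(cols) == 0L) {
    abort(sprintf("`%s` has no condition/sample columns.", arg))
  }
  m <- as.matrix(df[cols])
  if (!is.numeric(m)) abort(sprintf("Non-numeric value in `%s` columns.", arg))
  if (any(!is.finite(m)) || any(m < 0)) {
    abort(sprintf("All values in `%s` must be finite and nonnegative.", arg))
  }
  invisible(df)
}

# Integral check used for count cells.
assert_integral <- function(m, what = "count") {
  if (any(abs(m - round(m)) > 1e-8)) {
    abort(sprintf("Non-integer %s value found.", what))
  }
  invisible(m)
}

check_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lo), format(hi)))
  }
  invisible(x)
}
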
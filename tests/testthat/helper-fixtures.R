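# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

# Naive per-gene specificity oracle: term-by-term sum of p * log2(p * N).
ref_specificity <- function(tpm_row) {
  tot <- sum(tpm_row)
  if (tot == 0) return(NA_real_)
  n <- length(tpm_row)
  s <- 0
  for (t in seq_len(n)) {
    p <- tpm_row[t] / tot
    if (p > 0) s <- s + p * log2(p * n)
  }
  s
}

# Naive per-column TPM oracle.
ref_tpm <- function(counts, lengths) {
  out <- counts * 0
  for (c in seq_len(ncol(counts))) {
    rate <- counts[, c] / lengths
    tot <- sum(rate)
    out[, c] <- if (tot > 0) rate / tot * 1e6 else 0
  }
  out
}

# Small wide count tibble with deterministic random counts.
toy_counts <- function(n_genes = 5, samples = c("s1", "s2"), seed = 1,
                       max_count = 50) {
  withr::with_seed(seed, {
    m <- matrix(sample.int(max_count + 1L, n_genes * length(samples),
                           replace = TRUE) - 1L,
                nrow = n_genes, dimnames = list(NULL, samples))
    dplyr::bind_cols(
      tibble::tibble(gene_id = sprintf("g%02d", seq_len(n_genes)),
                     length = sample(500:5000, n_genes, replace = TRUE)),
      tibble::as_tibble(m)
    )
  })
}

# Write a featureCounts-style file (with comment line) for a wide tibble.
write_fc_fixture <- function(counts, path = withr::local_tempfile(
                               fileext = ".tsv", .local_envir = parent.frame())) {
  entroseq::write_featurecounts(counts, path)
  path
}

# Write a plain one-ID-per-line gene-set file.
write_geneset_fixture <- function(ids, path = withr::local_tempfile(
                                    fileext = ".txt", .local_envir = parent.frame())) {
  writeLines(ids, path)
  path
}

# A condition table assigning each sample to its own condition, categories
# cycling through the three allowed values.
identity_condition_table <- function(sample_ids) {
  cats <- rep(c("Metabolism", "Development", "Light Response"),
              length.out = length(sample_ids))
  entroseq::condition_table(condition_id = sample_ids,
                            sample_ids = as.list(sample_ids),
                            category = cats)
}

# Entropy table built directly from given scores (NA = excluded).
table_from_scores <- function(scores, n_conditions = 97, threshold = 1,
                              ids = sprintf("g%04d", seq_along(scores))) {
  tpm_stub <- tibble::tibble(gene_id = ids)
  df <- tibble::tibble(
    gene_id = ids,
    entropy = scores,
    normalized_entropy = scores / log2(n_conditions),
    class = dplyr::case_when(is.na(scores) ~ "excluded",
                             scores > threshold ~ "condition-specific",
                             TRUE ~ "constitutive-like")
  )
  structure(df, n_conditions = n_conditions, threshold = threshold,
            class = c("entropy_tbl", class(tibble::tibble())))
}
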
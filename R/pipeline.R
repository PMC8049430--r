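# Pipeline drivers: each run_* function is a pure function of its input files
# and options, writing deterministic text outputs (and figures) to out_dir.
# A thin command-line wrapper around them ships in inst/cli/entroseq.R.

ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  invisible(dir)
}

write_run_log <- function(out_dir, stem, lines, summary) {
  writeLines(lines, file.path(out_dir, paste0(stem, "_log.txt")))
  jsonlite::write_json(summary, file.path(out_dir, paste0(stem, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the scoring pipeline on a count table
#'
#' Reads a featureCounts-style table, optionally merges replicate samples into
#' conditions, computes TPM and the entropy table, and writes: the scored
#' entropy TSV, the excluded-gene list, the TPM matrix, a plain-text log and a
#' machine-readable JSON summary (gene tallies, score range, and the fraction
#' of scored genes in the low-entropy interval [0.05, 1]).
#'
#' @param counts_path Path to the count table.
#' @param out_dir Output directory (created if needed).
#' @param conditions_path Optional condition-table TSV; when given, replicate
#'   sample columns are summed into condition columns first.
#' @param threshold Classification boundary in bits.
#' @param histogram_binwidth Bin width of the logged score histogram.
#' @return Invisibly, a list with the `entropy_tbl`, the TPM tibble and the
#'   output paths.
#' @export
run_compute <- function(counts_path, out_dir, conditions_path = NULL,
                        threshold = 1.0, histogram_binwidth = 0.25) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  ensure_dir(out_dir)
  counts <- stage("read counts", read_featurecounts(counts_path))
  if (!is.null(conditions_path)) {
    ct <- stage("read conditions", read_condition_table(conditions_path))
    counts <- stage("merge replicates", merge_replicates(counts, ct))
  }
  tpm <- stage("TPM", suppressWarnings(compute_tpm(counts)))
  table <- stage("entropy", compute_entropy_table(tpm, threshold = threshold))

  paths <- list(entropy = file.path(out_dir, "entropy_table.tsv"),
                excluded = file.path(out_dir, "excluded_genes.tsv"),
                tpm = file.path(out_dir, "tpm_matrix.tsv"))
  write_entropy_table(table, paths$entropy)
  readr::write_tsv(tibble::tibble(gene_id = excluded_genes(table)),
                   paths$excluded, progress = FALSE)
  readr::write_tsv(tpm, paths$tpm, progress = FALSE)

  g <- glance(table)
  low <- interval_fraction(table, 0.05, 1)
  bins <- entropy_histogram(table, histogram_binwidth)
  summary <- c(as.list(g),
               list(interval_lo = 0.05, interval_hi = 1,
                    interval_count = low$count, interval_fraction = low$fraction,
                    histogram_binwidth = histogram_binwidth,
                    histogram_counts = list(bins$count)))
  lines <- c(
    sprintf("conditions (N): %d", g$n_conditions),
    sprintf("genes: %d (scored %d, excluded %d)", g$n_genes, g$n_scored, g$n_excluded),
    sprintf("classes: constitutive-like %d, condition-specific %d (threshold %.3g bits)",
            g$n_constitutive, g$n_specific, g$threshold),
    sprintf("score range: %.4f .. %.4f (analytic max %.4f)",
            g$min_entropy, g$max_entropy, g$max_possible),
    sprintf("scored genes in [0.05, 1]: %d/%d (%.1f%%)",
            low$count, low$n_scored, 100 * low$fraction)
  )
  write_run_log(out_dir, "compute", lines, summary)
  invisible(list(table = table, tpm = tpm, paths = paths))
}

read_tpm_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("TPM matrix not found: %s", path))
  readr::read_tsv(path, col_types = readr::cols(gene_id = "c", .default = "d"),
                  progress = FALSE)
}

save_figure <- function(plot, path, width = 7, height = 5) {
  ggplot2::ggsave(path, plot = plot, width = width, height = height,
                  device = switch(tools::file_ext(path), pdf = grDevices::pdf,
                                  tools::file_ext(path)))
  invisible(path)
}

#' Benchmark gene sets against a scored table
#'
#' For each gene set: a KDE-with-rug figure of its members' scores, an
#' entropy-ranked log2-TPM heatmap figure with the condition category strip,
#' and the numeric exports behind both figures (KDE grid TSV, heatmap TSV).
#' Output filenames are derived from set names.
#'
#' @param entropy_path Entropy table TSV from [run_compute()].
#' @param tpm_path TPM matrix TSV from [run_compute()].
#' @param geneset_paths Character vector of gene-set list files.
#' @param out_dir Output directory.
#' @param conditions_path Optional condition table for the category strip.
#' @param id_map_path Optional two-column ID map applied to the gene sets.
#' @param bandwidth KDE bandwidth rule (see [score_kde()]).
#' @param pseudocount Heatmap pseudocount (see [ranked_heatmap()]).
#' @param fig_format One of `"pdf"`, `"png"`, `"svg"`.
#' @return Invisibly, a named list (per set) of `score_kde` and
#'   `heatmap_data` objects.
#' @export
run_benchmark <- function(entropy_path, tpm_path, geneset_paths, out_dir,
                          conditions_path = NULL, id_map_path = NULL,
                          bandwidth = "scott", pseudocount = 1.0,
                          fig_format = "pdf") {
  ensure_dir(out_dir)
  table <- read_entropy_table(entropy_path)
  tpm <- read_tpm_tsv(tpm_path)
  ct <- if (!is.null(conditions_path)) read_condition_table(conditions_path)
  idmap <- if (!is.null(id_map_path)) read_id_map(id_map_path)
  results <- list()
  for (path in geneset_paths) {
    gs <- read_gene_set(path, id_map = idmap)
    stem <- gsub("[^A-Za-z0-9_.-]", "_", gs$name)
    scores <- tryCatch(geneset_scores(table, gs), error = function(e) {
      abort(sprintf("Gene set '%s': %s", gs$name, conditionMessage(e)))
    })
    kde <- score_kde(scores, bandwidth = bandwidth)
    kde$name <- gs$name
    hm <- ranked_heatmap(tpm, table, gs, conditions = ct,
                         pseudocount = pseudocount)
    readr::write_tsv(kde$grid, file.path(out_dir, paste0(stem, "_kde.tsv")),
                     progress = FALSE)
    write_heatmap_tsv(hm, file.path(out_dir, paste0(stem, "_heatmap.tsv")))
    save_figure(autoplot(kde),
                file.path(out_dir, paste0(stem, "_kde.", fig_format)))
    save_figure(autoplot(hm),
                file.path(out_dir, paste0(stem, "_heatmap.", fig_format)),
                width = 9, height = max(3, 0.12 * nrow(hm$values) + 2))
    results[[gs$name]] <- list(kde = kde, heatmap = hm)
  }
  invisible(results)
}

#' Extract and plot the score extremes
#'
#' Writes the lowest-k and highest-k gene lists and their entropy-ranked
#' log2-TPM heatmaps (figures plus numeric TSVs).
#'
#' @inheritParams run_benchmark
#' @param k Genes per tail.
#' @return Invisibly, the [extreme_genes()] list plus both `heatmap_data`.
#' @export
run_extremes <- function(entropy_path, tpm_path, out_dir,
                         conditions_path = NULL, k = 100L, pseudocount = 1.0,
                         fig_format = "pdf") {
  ensure_dir(out_dir)
  table <- read_entropy_table(entropy_path)
  tpm <- read_tpm_tsv(tpm_path)
  ct <- if (!is.null(conditions_path)) read_condition_table(conditions_path)
  ext <- extreme_genes(table, k = k)
  out <- list(extremes = ext)
  for (side in c("lowest", "highest")) {
    ids <- ext[[side]]
    readr::write_tsv(ids, file.path(out_dir, paste0(side, "_", k, "_genes.tsv")),
                     progress = FALSE)
    gs <- gene_set(ids$gene_id, name = sprintf("%s_%d", side, k))
    hm <- ranked_heatmap(tpm, table, gs, conditions = ct,
                         pseudocount = pseudocount)
    write_heatmap_tsv(hm, file.path(out_dir, paste0(side, "_", k, "_heatmap.tsv")))
    save_figure(autoplot(hm),
                file.path(out_dir, paste0(side, "_", k, "_heatmap.", fig_format)),
                width = 9, height = max(3, 0.12 * k + 2))
    out[[paste0(side, "_heatmap")]] <- hm
  }
  invisible(out)
}

#' Generate and write a synthetic data set
#'
#' Draws a count matrix from a [synthetic_spec()] and writes it in the
#' featureCounts dialect alongside the truth table, so the generated files
#' round-trip through the package's own readers.
#'
#' @param spec A `synthetic_spec`, or the path to a YAML spec file.
#' @param out_dir Output directory.
#' @param seed Optional override of the spec's seed.
#' @return Invisibly, the [generate_counts()] result plus output paths.
#' @export
run_simulate <- function(spec, out_dir, seed = NULL) {
  ensure_dir(out_dir)
  if (is.character(spec)) spec <- read_synthetic_spec(spec)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  sim <- generate_counts(spec)
  paths <- list(counts = file.path(out_dir, "synthetic_counts.tsv"),
                truth = file.path(out_dir, "synthetic_truth.tsv"))
  write_featurecounts(sim$counts, paths$counts)
  write_truth_table(sim$truth, paths$truth)
  tally <- table(sim$truth$class)
  write_run_log(out_dir, "simulate",
                c(sprintf("seed: %d", spec$seed),
                  sprintf("genes: %d, conditions: %d", spec$n_genes, spec$n_conditions),
                  sprintf("classes: %s",
                          paste(names(tally), as.integer(tally), sep = "=",
                                collapse = ", "))),
                c(unclass(spec)[c("n_genes", "n_conditions", "base_mean",
                                  "dispersion", "induction_fold",
                                  "n_induced_conditions", "seed")],
                  list(class_counts = as.list(tally))))
  invisible(c(sim, list(paths = paths)))
}
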
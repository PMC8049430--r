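#' Specification for a synthetic count matrix
#'
#' Defines a genes x conditions experiment with four known gene classes:
#' \describe{
#'   \item{constitutive}{identical expected count in every condition;}
#'   \item{induced}{baseline expression everywhere, multiplied by
#'     `induction_fold` in `n_induced_conditions` randomly chosen conditions;}
#'   \item{single_condition}{zero expected count everywhere except one
#'     uniformly chosen condition, where the mean is the induced level — these
#'     genes pin the analytic score maximum `log2(N)`;}
#'   \item{silent}{exactly zero counts everywhere (the excluded class).}
#' }
#' Counts are drawn from a negative binomial (the standard bulk RNA-seq count
#' model) with mean proportional to gene length, so TPM normalization is
#' exercised non-trivially: `mean_gc = base_mean * length_g / mean(length) *
#' class multiplier`.
#'
#' @param n_genes Number of genes.
#' @param n_conditions Number of conditions (>= 2; default 97, the scale of a
#'   large public compendium).
#' @param proportions Named proportions over `constitutive`, `induced`,
#'   `single_condition`, `silent`; must sum to 1.
#' @param base_mean Expected count at baseline for a gene of average length.
#' @param dispersion Negative-binomial size parameter (larger = less noise).
#' @param induction_fold Mean multiplier in induced conditions (> 1).
#' @param n_induced_conditions Conditions induced per induced gene, in
#'   `[1, n_conditions)`.
#' @param length_range Integer range of gene lengths in bp.
#' @param seed Integer seed; the same spec always generates the same matrix.
#' @return A validated `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_genes = 5000L,
                           n_conditions = 97L,
                           proportions = c(constitutive = 0.70,
                                           induced = 0.20,
                                           single_condition = 0.05,
                                           silent = 0.05),
                           base_mean = 100,
                           dispersion = 10,
                           induction_fold = 100,
                           n_induced_conditions = 2L,
                           length_range = c(500L, 5000L),
                           seed = 1L) {
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(n_genes) && length(n_genes) == 1L && n_genes >= 1,
      "n_genes must be a positive integer")
  chk(is.numeric(n_conditions) && length(n_conditions) == 1L && n_conditions >= 2,
      "n_conditions must be an integer >= 2")
  classes <- c("constitutive", "induced", "single_condition", "silent")
  chk(is.numeric(proportions) && setequal(names(proportions), classes) &&
        all(proportions >= 0) && abs(sum(proportions) - 1) <= 1e-9,
      "proportions must be named over the four classes and sum to 1")
  chk(is.numeric(base_mean) && length(base_mean) == 1L && base_mean > 0,
      "base_mean must be positive")
  chk(is.numeric(dispersion) && length(dispersion) == 1L && dispersion > 0,
      "dispersion must be positive")
  chk(is.numeric(induction_fold) && length(induction_fold) == 1L &&
        induction_fold > 1, "induction_fold must exceed 1")
  chk(is.numeric(n_induced_conditions) && length(n_induced_conditions) == 1L &&
        n_induced_conditions >= 1 && n_induced_conditions < n_conditions,
      "n_induced_conditions must be in [1, n_conditions)")
  chk(is.numeric(length_range) && length(length_range) == 2L &&
        length_range[1] >= 1 && length_range[2] >= length_range[1],
      "length_range must be (min bp, max bp) with 1 <= min <= max")
  chk(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
      "seed must be a single integer")
  if (length(problems)) {
    abort(paste0("Invalid synthetic spec:\n",
                 paste("-", problems, collapse = "\n")))
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_conditions = as.integer(n_conditions),
                 proportions = proportions[classes],
                 base_mean = base_mean,
                 dispersion = dispersion,
                 induction_fold = induction_fold,
                 n_induced_conditions = as.integer(n_induced_conditions),
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Read a synthetic spec from a YAML config file
#'
#' Keys match the arguments of [synthetic_spec()]; `proportions` is a mapping
#' from class name to proportion. Absent keys take the defaults.
#'
#' @param path Path to the YAML file.
#' @return A `synthetic_spec`.
#' @export
read_synthetic_spec <- function(path) {
  if (!file.exists(path)) abort(sprintf("Spec file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(synthetic_spec))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(sprintf("Unknown spec key(s): %s", paste(extra, collapse = ", ")))
  }
  if (!is.null(raw$proportions)) raw$proportions <- unlist(raw$proportions)
  if (!is.null(raw$length_range)) raw$length_range <- unlist(raw$length_range)
  do.call(synthetic_spec, raw)
}

#' Write a synthetic spec to YAML
#'
#' @param spec A `synthetic_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_spec <- function(spec, path) {
  x <- unclass(spec)
  x$proportions <- as.list(x$proportions)
  yaml::write_yaml(x, path)
  invisible(path)
}

# Integer class sizes matching the proportions exactly (largest remainder).
class_sizes <- function(n, proportions) {
  raw <- proportions * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    top <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[top] <- sizes[top] + 1L
  }
  as.integer(sizes)
}

#' Generate a synthetic count matrix with known gene classes
#'
#' @param spec A `synthetic_spec`.
#' @return A list with `counts` (wide count tibble: `gene_id`, `length`, one
#'   column per condition) and `truth` (tibble: `gene_id`, `class`,
#'   `induced_conditions` — comma-joined condition IDs for induced and
#'   single-condition genes, empty otherwise).
#' @export
generate_counts <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) abort("`spec` must be a synthetic_spec.")
  withr::with_seed(spec$seed, {
    n <- spec$n_genes
    nc <- spec$n_conditions
    gene_ids <- sprintf("gene_%05d", seq_len(n))
    cond_ids <- sprintf("cond_%03d", seq_len(nc))
    sizes <- class_sizes(n, spec$proportions)
    labels <- sample(rep(names(spec$proportions), times = sizes))
    lengths <- sample(seq(spec$length_range[1], spec$length_range[2]),
                      n, replace = TRUE)
    base <- spec$base_mean * lengths / mean(lengths)

    mu <- matrix(0, nrow = n, ncol = nc)
    induced_at <- vector("list", n)
    for (g in seq_len(n)) {
      mu[g, ] <- switch(labels[g],
        constitutive = base[g],
        induced = {
          induced_at[[g]] <- sort(sample.int(nc, spec$n_induced_conditions))
          row <- rep(base[g], nc)
          row[induced_at[[g]]] <- base[g] * spec$induction_fold
          row
        },
        single_condition = {
          induced_at[[g]] <- sample.int(nc, 1L)
          row <- rep(0, nc)
          row[induced_at[[g]]] <- base[g] * spec$induction_fold
          row
        },
        silent = 0
      )
    }
    counts <- matrix(0L, nrow = n, ncol = nc, dimnames = list(NULL, cond_ids))
    pos <- mu > 0
    counts[pos] <- rnbinom(sum(pos), size = spec$dispersion, mu = mu[pos])

    truth <- tibble::tibble(
      gene_id = gene_ids,
      class = labels,
      induced_conditions = vapply(induced_at, function(i) {
        if (is.null(i)) "" else paste(cond_ids[i], collapse = ",")
      }, "")
    )
    counts_tbl <- dplyr::bind_cols(
      tibble::tibble(gene_id = gene_ids, length = as.integer(lengths)),
      tibble::as_tibble(counts)
    )
    list(counts = counts_tbl, truth = truth)
  })
}

#' Class-recovery summary of a scored synthetic matrix
#'
#' Checks that the specificity score recovers the generator's known gene
#' classes: per-class score medians, the AUROC of the score as a discriminator
#' of conditionally expressed genes (induced or single-condition) versus
#' constitutive ones, and the fraction of silent genes the metric correctly
#' excluded (should be exactly 1).
#'
#' @param table An `entropy_tbl` computed from the generated matrix.
#' @param truth Truth tibble from [generate_counts()], same genes.
#' @return A list with `class_summary` (tibble: `class`, `n`,
#'   `median_entropy`, `n_excluded` — classes absent from the truth get
#'   `n = 0` and `NA` medians), `auroc` (`NA` if either side is absent) and
#'   `silent_excluded` (`NA` if no silent genes).
#' @export
recovery_metrics <- function(table, truth) {
  if (!setequal(table$gene_id, truth$gene_id)) {
    abort("`table` and `truth` must cover the same genes.")
  }
  joined <- dplyr::left_join(truth, tidy(table), by = "gene_id")
  classes <- c("constitutive", "induced", "single_condition", "silent")
  class_summary <- purrr::map_dfr(classes, function(cl) {
    rows <- joined[joined$class.x == cl, ]
    tibble::tibble(class = cl, n = nrow(rows),
                   median_entropy = if (nrow(rows)) median(rows$entropy, na.rm = TRUE) else NA_real_,
                   n_excluded = sum(rows$class.y == "excluded"))
  })
  pos <- joined$entropy[joined$class.x %in% c("induced", "single_condition") &
                          !is.na(joined$entropy)]
  neg <- joined$entropy[joined$class.x == "constitutive" & !is.na(joined$entropy)]
  auroc <- if (length(pos) && length(neg)) auroc_rank(pos, neg) else NA_real_
  silent <- joined[joined$class.x == "silent", ]
  silent_excluded <- if (nrow(silent)) mean(silent$class.y == "excluded") else NA_real_
  list(class_summary = class_summary, auroc = auroc,
       silent_excluded = silent_excluded)
}

# Mann-Whitney rank AUROC: P(score_pos > score_neg) + 0.5 P(tie).
auroc_rank <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Write the truth table of a synthetic matrix
#'
#' @param truth Truth tibble from [generate_counts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}

#' Read a truth table written by [write_truth_table()]
#'
#' @param path Path to the TSV file.
#' @return Truth tibble.
#' @export
read_truth_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", class = "c", induced_conditions = "c"
  ), progress = FALSE) |>
    dplyr::mutate(induced_conditions = dplyr::coalesce(.data$induced_conditions, ""))
}
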
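test_that("compute_tpm reproduces hand-computed values and normalizes columns", {
  # single gene: normalization forces 1e6 whatever the count
  one <- tibble::tibble(gene_id = "g1", length = 1234L, c1 = 7, c2 = 900)
  expect_equal(as.numeric(compute_tpm(one)[1, c("c1", "c2")]), c(1e6, 1e6))

  # two genes, equal counts, 1 kb vs 2 kb: rates 0.01 / 0.005 over 0.015
  two <- tibble::tibble(gene_id = c("a", "b"), length = c(1000L, 2000L),
                        c1 = c(10, 10))
  expect_equal(compute_tpm(two)$c1, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  # every nonempty column sums to one million
  cm <- toy_counts(n_genes = 40, samples = sprintf("s%d", 1:5), seed = 2)
  tpm <- compute_tpm(cm)
  expect_equal(unname(colSums(as.matrix(tpm[-1]))), rep(1e6, 5),
               tolerance = 1e-9)

  # all-zero column passes through as zeros, with a warning
  cm$s3 <- 0
  expect_warning(tpm0 <- compute_tpm(cm), "all-zero TPM")
  expect_true(all(tpm0$s3 == 0))
})

test_that("compute_tpm rejects invalid lengths and non-integer counts", {
  bad <- tibble::tibble(gene_id = "g", length = 0L, c1 = 5)
  expect_error(compute_tpm(bad), "positive")
  frac <- tibble::tibble(gene_id = "g", length = 100L, c1 = 2.5)
  expect_error(compute_tpm(frac), "Non-integer")
})

test_that("compute_tpm agrees with scater::calculateTPM", {
  cm <- toy_counts(n_genes = 30, samples = sprintf("s%d", 1:4), seed = 8,
                   max_count = 500)
  mine <- as.matrix(compute_tpm(cm)[-1])
  ref <- as.matrix(scater::calculateTPM(as.matrix(cm[-(1:2)]),
                                        lengths = cm$length))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-9)
})

test_that("condition_fractions normalizes, detects undefined rows, and is scale invariant", {
  expect_equal(condition_fractions(c(5, 5, 0, 0)), c(0.5, 0.5, 0, 0))
  expect_true(all(is.na(condition_fractions(c(0, 0, 0)))))
  x <- c(3, 0, 7, 2)
  expect_equal(condition_fractions(x * 17.3), condition_fractions(x))
  expect_error(condition_fractions(5), "at least 2")
  expect_error(condition_fractions(c(-1, 2)), "nonnegative")
})

test_that("entropy_specificity matches analytic values", {
  expect_equal(entropy_specificity(rep(1 / 97, 97)), 0, tolerance = 1e-12)
  single <- c(1, rep(0, 96))
  expect_identical(entropy_specificity(single), log2(97))
  expect_identical(entropy_specificity(c(0.5, 0.5, 0, 0)), 1.0)
  # 0.5*log2(1.5) + 0.5*log2(0.75)
  expect_equal(entropy_specificity(c(0.5, 0.25, 0.25)), 0.08496250072,
               tolerance = 1e-9)
  expect_true(is.na(entropy_specificity(rep(NA_real_, 4))))
})

test_that("normalized_specificity rescales by the analytic maximum", {
  expect_equal(normalized_specificity(rep(1 / 10, 10)), 0, tolerance = 1e-12)
  for (n in c(2, 5, 97)) {
    expect_equal(normalized_specificity(c(1, rep(0, n - 1))), 1)
  }
  expect_equal(normalized_specificity(c(0.5, 0.5, 0, 0)), 0.5)
})

test_that("compute_entropy_table scores, classifies, and excludes all-zero genes", {
  tpm <- tibble::tibble(gene_id = c("gA", "gB", "gC"),
                        c1 = c(100, 0, 0), c2 = c(100, 50, 0),
                        c3 = c(100, 0, 0), c4 = c(100, 0, 0))
  tab <- compute_entropy_table(tpm)
  expect_s3_class(tab, "entropy_tbl")
  expect_equal(tab$entropy[1], 0, tolerance = 1e-12)
  expect_identical(tab$entropy[2], 2)          # single of 4 conditions
  expect_true(is.na(tab$entropy[3]))
  expect_equal(tab$class, c("constitutive-like", "condition-specific", "excluded"))
  expect_equal(excluded_genes(tab), "gC")

  g <- glance(tab)
  expect_equal(g$n_scored, 2L)
  expect_equal(g$n_excluded, 1L)
  expect_equal(g$max_possible, 2)
})

test_that("classification threshold is strict: a score of exactly 1 is constitutive-like", {
  tab <- table_from_scores(c(0.5, 1.0, 1.0 + 1e-9, 1.5))
  expect_equal(tab$class, c("constitutive-like", "constitutive-like",
                            "condition-specific", "condition-specific"))
  # threshold is a parameter
  tpm <- tibble::tibble(gene_id = c("a", "b"), c1 = c(9, 1), c2 = c(1, 9))
  t_lo <- compute_entropy_table(tpm, threshold = 0.1)
  expect_true(all(t_lo$class == "condition-specific"))
})

test_that("interval_fraction counts scored genes inclusively", {
  tab <- table_from_scores(c(0.1, 0.5, 2.0))
  got <- interval_fraction(tab, 0.05, 1)
  expect_equal(got$count, 2L)
  expect_equal(got$fraction, 2 / 3)
  # totality over the full range
  full <- interval_fraction(tab, 0, log2(97))
  expect_equal(full$fraction, 1)
  # brute force on a large synthetic score vector
  withr::local_seed(5)
  scores <- runif(1000, 0, log2(97))
  big <- table_from_scores(scores)
  for (i in 1:20) {
    b <- sort(runif(2, 0, 7))
    expect_equal(interval_fraction(big, b[1], b[2])$count,
                 sum(vapply(scores, function(s) s >= b[1] && s <= b[2], TRUE)))
  }
  expect_error(interval_fraction(tab, 2, 1), "lo")
  expect_error(interval_fraction(table_from_scores(NA_real_), 0, 1),
               "No scored genes")
})

test_that("vectorized scores match the naive per-gene loop on random matrices", {
  withr::local_seed(20)
  for (i in 1:100) {
    ng <- sample(2:20, 1)
    nc <- sample(2:10, 1)
    cm <- dplyr::bind_cols(
      tibble::tibble(gene_id = sprintf("g%02d", seq_len(ng)),
                     length = sample(200:3000, ng, replace = TRUE)),
      tibble::as_tibble(matrix(rpois(ng * nc, lambda = sample(c(0.5, 5, 50), 1)),
                               nrow = ng,
                               dimnames = list(NULL, sprintf("c%d", seq_len(nc)))))
    )
    tpm <- suppressWarnings(compute_tpm(cm))
    tab <- compute_entropy_table(tpm)
    m <- as.matrix(tpm[-1])
    expected <- apply(m, 1, ref_specificity)
    expect_equal(tab$entropy, unname(expected), tolerance = 1e-12)
  }
})

test_that("scores are permutation and row-scale invariant, bounded, and satisfy S + H = log2 N", {
  withr::local_seed(33)
  ng <- 50; nc <- 9
  tpm <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%02d", seq_len(ng))),
    tibble::as_tibble(matrix(rexp(ng * nc, rate = 1 / 100), nrow = ng,
                             dimnames = list(NULL, sprintf("c%d", seq_len(nc)))))
  )
  tpm[3, -1] <- as.list(rep(0, nc))  # one undefined gene
  tab <- compute_entropy_table(tpm)

  # bounds
  s <- tab$entropy[!is.na(tab$entropy)]
  expect_true(all(s >= 0 & s <= log2(nc) + 1e-9))
  expect_true(all(tab$normalized_entropy[!is.na(tab$entropy)] <= 1 + 1e-9))

  # permutation invariance of condition order
  perm <- sample(nc)
  tab_p <- compute_entropy_table(tpm[c(1, 1 + perm)])
  expect_equal(tab_p$entropy, tab$entropy, tolerance = 1e-12)

  # row-scale invariance
  tpm2 <- tpm
  tpm2[7, -1] <- as.list(as.numeric(tpm[7, -1]) * 1234.5)
  expect_equal(compute_entropy_table(tpm2)$entropy[7], tab$entropy[7],
               tolerance = 1e-12)

  # decomposition: S + H(p) = log2 N for every defined profile
  m <- as.matrix(tpm[-1])
  for (g in which(rowSums(m) > 0)) {
    p <- m[g, ] / sum(m[g, ])
    h <- -sum(p[p > 0] * log2(p[p > 0]))
    expect_equal(tab$entropy[g] + h, log2(nc), tolerance = 1e-9)
  }
})

test_that("concentrating mass on one condition strictly increases the score", {
  n <- 12
  grid <- seq(1 / n + 0.01, 1, length.out = 40)
  scores <- vapply(grid, function(q) {
    entropy_specificity(c(q, rep((1 - q) / (n - 1), n - 1)))
  }, 0)
  expect_true(all(diff(scores) > 0))
})

test_that("entropy_histogram bins cover all scored genes", {
  withr::local_seed(6)
  tab <- table_from_scores(c(runif(500, 0, 6.6), rep(NA, 7)))
  bins <- entropy_histogram(tab, binwidth = 0.25)
  expect_equal(sum(bins$count), 500L)
  expect_equal(bins$bin_hi - bins$bin_lo, rep(0.25, nrow(bins)))
})
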
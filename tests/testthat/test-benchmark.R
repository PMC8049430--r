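test_that("geneset_scores accounts for every member with a status", {
  tab <- table_from_scores(c(0.2, 0.7, NA, 3.1),
                           ids = c("g1", "g2", "g3", "g4"))
  gs <- gene_set(c("g1", "g3", "g4", "ghost"), name = "mixed")
  got <- geneset_scores(tab, gs)
  expect_equal(got$status, c("scored", "excluded", "scored", "missing"))
  expect_equal(got$entropy, c(0.2, NA, 3.1, NA))
  expect_equal(attr(got, "set_name"), "mixed")

  only_bad <- gene_set(c("g3", "ghost"), name = "hopeless")
  expect_error(geneset_scores(tab, only_bad), "no scored members")
})

test_that("score_kde integrates to one, locates the mode, and is deterministic", {
  withr::local_seed(14)
  scores <- rnorm(200, mean = 0.25, sd = 0.05)
  kde <- score_kde(scores)
  # normalization: trapezoidal integral over the +-3bw grid
  integral <- sum(diff(kde$grid$score) *
                    (head(kde$grid$density, -1) + tail(kde$grid$density, -1)) / 2)
  expect_gte(integral, 0.99)
  expect_lte(integral, 1.01)
  expect_true(all(kde$grid$density >= 0))
  expect_equal(nrow(kde$grid), 512L)
  # mode consistency with the sampling distribution
  expect_lt(abs(kde_mode(kde) - 0.25), 0.05)
  # grid spans data +- 3 bandwidths
  expect_equal(min(kde$grid$score), min(scores) - 3 * kde$bandwidth)
  expect_equal(max(kde$grid$score), max(scores) + 3 * kde$bandwidth)
  # determinism
  expect_identical(score_kde(scores), kde)
})

test_that("score_kde bandwidth rules and degenerate input behave as documented", {
  withr::local_seed(3)
  x <- runif(50)
  expect_equal(score_kde(x, "scott")$bandwidth, sd(x) * 50^(-1 / 5))
  expect_equal(score_kde(x, "silverman")$bandwidth, stats::bw.nrd0(x))
  expect_equal(score_kde(x, 0.2)$bandwidth, 0.2)
  expect_error(score_kde(rep(1, 10)), "degenerate")
  expect_error(score_kde(1), "at least 2")
  # integral holds across rules
  for (bw in list("silverman", 0.05)) {
    k <- score_kde(x, bw)
    integral <- sum(diff(k$grid$score) *
                      (head(k$grid$density, -1) + tail(k$grid$density, -1)) / 2)
    expect_gte(integral, 0.99)
    expect_lte(integral, 1.01)
  }
})

test_that("ranked_heatmap sorts rows by score with deterministic tie-breaks", {
  tpm <- tibble::tibble(gene_id = c("gB", "gA", "gC", "gD"),
                        c1 = c(0, 10, 5, 0), c2 = c(100, 10, 5, 0),
                        c3 = c(1, 10, 5, 0))
  tab <- compute_entropy_table(tpm)
  gs <- gene_set(c("gA", "gB", "gC", "gD"), name = "all")
  ct <- identity_condition_table(c("c1", "c2", "c3"))
  hm <- ranked_heatmap(tpm, tab, gs, conditions = ct)
  # gA and gC are both uniform (score 0): tie broken lexicographically;
  # gB is concentrated (high score); excluded gD is omitted
  expect_equal(hm$values$gene_id, c("gA", "gC", "gB"))
  expect_true(all(diff(hm$row_scores) >= 0))
  expect_equal(hm$column_categories$category,
               c("Metabolism", "Development", "Light Response"))
  # log2(TPM + 1): a zero TPM cell maps to 0
  expect_equal(hm$values$c1[hm$values$gene_id == "gB"], 0)
  expect_equal(as.numeric(hm$values[hm$values$gene_id == "gA", c("c1", "c2", "c3")]),
               rep(log2(10 + 1), 3), tolerance = 1e-9)
  # identical rerun
  expect_identical(ranked_heatmap(tpm, tab, gs, conditions = ct), hm)
  # pseudocount is a parameter
  hm2 <- ranked_heatmap(tpm, tab, gs, pseudocount = 0.5)
  expect_equal(hm2$values$c1[hm2$values$gene_id == "gB"], -1)
})

test_that("extreme_genes returns disjoint sorted tails matching a full-sort oracle", {
  tab5 <- table_from_scores(c(0.3, 2.0, 0.1, 5.0, 1.0),
                            ids = c("a", "b", "c", "d", "e"))
  ext <- extreme_genes(tab5, k = 2)
  expect_equal(ext$lowest$gene_id, c("c", "a"))
  expect_equal(ext$highest$gene_id, c("d", "b"))
  expect_length(intersect(ext$lowest$gene_id, ext$highest$gene_id), 0L)

  withr::local_seed(40)
  scores <- c(round(runif(295, 0, 6.6), 2), rep(NA, 5))  # rounded to force ties
  big <- table_from_scores(scores)
  ext100 <- extreme_genes(big, k = 100)
  ord <- order(big$entropy[!is.na(big$entropy)],
               big$gene_id[!is.na(big$entropy)])
  scored_ids <- big$gene_id[!is.na(big$entropy)][ord]
  expect_equal(ext100$lowest$gene_id, scored_ids[1:100])
  expect_equal(sort(ext100$highest$gene_id), sort(tail(scored_ids, 100)))
  # excluded genes never selected; tails pairwise ordered
  excluded <- big$gene_id[is.na(big$entropy)]
  expect_length(intersect(c(ext100$lowest$gene_id, ext100$highest$gene_id),
                          excluded), 0L)
  expect_true(max(ext100$lowest$entropy) <= min(ext100$highest$entropy))
  expect_error(extreme_genes(tab5, k = 3), "at least 2k")
})

test_that("KDE modes separate constitutive-like from condition-specific score samples", {
  withr::local_seed(21)
  lo <- pmax(0, rnorm(150, 0.25, 0.1))   # constitutive-like scores
  hi <- rnorm(150, 3.5, 0.5)             # condition-specific scores
  expect_lt(kde_mode(score_kde(lo)), kde_mode(score_kde(hi)))
  expect_lt(kde_mode(score_kde(lo)), 1)
  expect_gt(kde_mode(score_kde(hi)), 2)
})

test_that("heatmap TSV export carries the category line and full-precision values", {
  tpm <- tibble::tibble(gene_id = c("gA", "gB"), c1 = c(10, 0), c2 = c(10, 20))
  tab <- compute_entropy_table(tpm)
  hm <- ranked_heatmap(tpm, tab, gene_set(c("gA", "gB")),
                       conditions = identity_condition_table(c("c1", "c2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_heatmap_tsv(hm, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# category\t\tMetabolism\tDevelopment$")
  expect_equal(lines[2], "gene_id\tentropy\tc1\tc2")
  expect_length(lines, 4L)
})

test_that("autoplot methods return ggplot objects", {
  withr::local_seed(2)
  kde <- score_kde(runif(30))
  expect_s3_class(autoplot(kde), "ggplot")
  tpm <- tibble::tibble(gene_id = c("gA", "gB"), c1 = c(10, 0), c2 = c(10, 20))
  tab <- compute_entropy_table(tpm)
  hm <- ranked_heatmap(tpm, tab, gene_set(c("gA", "gB")),
                       conditions = identity_condition_table(c("c1", "c2")))
  expect_s3_class(autoplot(hm), "ggplot")
  expect_s3_class(plot_entropy_histogram(tab), "ggplot")
})
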
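---
title: "Scoring condition-specific gene expression with entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring condition-specific gene expression with entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entroseq)
```

## The model

`entroseq` quantifies how variable a gene's expression is across a compendium
of RNA-seq experiments — different carbon sources, developmental stages,
light regimes — collapsed to one count column per biological *condition*.
Replicates are merged by summing their count columns
(`merge_replicates()`); gene-level read counts are additive over reads, so
this is exactly equivalent to merging replicate alignments before counting.

Counts are normalized to transcripts per million (`compute_tpm()`): per
column, each gene's count is divided by its length in bp and the resulting
rates are rescaled to sum to 10^6. TPM is the right normalization here
because the score below only uses *within-gene, across-condition* ratios;
any further between-sample normalization (size factors, CPM) would cancel
out of those ratios or is out of scope.

A gene's TPM row is reduced to fractions `p_t = TPM_t / sum(TPM)`
(`condition_fractions()`), a probability vector over the N conditions. The
specificity score (`entropy_specificity()`) is

    S = sum_t p_t * log2(p_t * N)  =  log2(N) - H(p)

in bits, with the `0 * log 0 := 0` convention — the Kullback–Leibler
divergence of the gene's profile from the uniform profile. This is the form
in which "entropy" scores for tissue or condition specificity are used in
expression atlases: a perfectly constitutive gene (uniform profile) scores
0, a gene expressed in exactly one condition scores the analytic maximum
`log2(N)` (6.5999 bits at N = 97). Note the direction: plain Shannon
entropy `H(p)` is *maximal* for constitutive genes; reporting
`log2(N) - H(p)` instead makes "low score = stable expression" hold, keeps
the score's range `[0, log2 N]` independent of how the profile is
discretized, and is what the identity `S + H(p) = log2 N` (asserted in the
test suite) pins down. Base-2 logarithms are used throughout so scores are
in bits.

### Assumptions and edge cases

* **At least 2 conditions.** Specificity is meaningless for one condition;
  `condition_fractions()` refuses N < 2.
* **All-zero genes.** A gene with zero counts in every condition has no
  defined profile. Its score is `NA` and its class is `excluded` — reported
  in a dedicated list rather than scored 0, since "we could not measure
  this gene" is different from "this gene is constitutive".
* **All-zero condition columns** produce all-zero TPM columns with a
  warning instead of an error. Such columns contribute `p_t = 0` to every
  gene and leave scores unchanged; erroring would make degenerate synthetic
  inputs unusable.
* **Classification.** Genes with S ≤ 1 bit are `constitutive-like`, genes
  with S strictly above 1 are `condition-specific`. The boundary is read
  strictly (S = 1.0 exactly is constitutive-like) and the threshold is a
  parameter of `compute_entropy_table()`; 1 bit is the conventional cutoff
  separating the low-entropy bulk of a genome from its condition-specific
  tail.
* **Numerical care.** The vectorized score is clamped at 0 against
  floating-point underflow (a uniform profile can otherwise come out at
  −1e-16). Scores are written to TSV at full double precision so a
  write–read round trip reproduces them to better than 1e-9; rounding for
  display is left to the reader.

## Benchmarking

`geneset_scores()` looks up a gene set's scores and never drops anything
silently: members absent from the table are `missing`, members with
undefined scores `excluded`. Two visual benchmarks mirror standard practice:

* **KDE with rug** (`score_kde()`, `autoplot()`): a Gaussian kernel density
  of the set's scores on a 512-point grid spanning the data ± 3 bandwidths,
  so the curve integrates to one. The kernel and bandwidth rule are not
  dictated by the method; Gaussian with Scott's rule (`sd * n^(-1/5)`) is
  the default and both are overridable (`"silverman"` or a fixed number),
  because the comparison surface is the density's *location*, not its
  parameters. Constant score vectors raise an error suggesting a rug-only
  plot rather than returning a spike.
* **Entropy-ranked heatmap** (`ranked_heatmap()`): `log2(TPM + 1)` values
  with genes sorted by score ascending (low entropy on top), ties broken
  lexicographically by gene ID so output is reproducible, and a
  Metabolism / Development / Light Response category strip over the
  columns. The pseudocount of 1 maps zero TPM to a cell value of exactly 0
  and is a parameter. Palettes and layout are rendering concerns; tests
  compare only the numeric matrices.

`extreme_genes()` returns the k lowest- and k highest-scoring genes (the
tails of the ranked genome), with the same tie-break, refusing tables with
fewer than 2k scored genes so the tails cannot overlap.

## The synthetic generator

Public compendia cannot be downloaded in a test suite, so
`synthetic_spec()` / `generate_counts()` produce count matrices with known
per-gene classes:

| class | mean in condition c |
|---|---|
| constitutive | `base_mean * length_g / mean(length)` everywhere |
| induced | baseline, × `induction_fold` in `n_induced_conditions` random conditions |
| single_condition | 0 everywhere except one random condition at the induced level |
| silent | 0 everywhere |

Counts are negative-binomial (`size = dispersion`), the standard bulk
RNA-seq count model; the generator is documented and parameterized, not
claimed to match any particular organism's data. Means are proportional to
gene length so TPM normalization is exercised non-trivially (a length-blind
normalization would fail the tests). Single-condition genes take the
*induced* mean in their one condition: they model strong exclusive
induction, and a baseline-level mean would occasionally draw a zero and
silently move the gene into the excluded class.

Defaults are the study conditions the package is validated under:
97 conditions (the scale of a large public compendium), `base_mean = 100`,
`dispersion = 10`, `induction_fold = 100` in 2 conditions, gene lengths
uniform on 500–5000 bp, and class proportions 0.70 / 0.20 / 0.05 / 0.05 —
70% constitutive mirrors the fraction of a real genome found in the
low-entropy interval [0.05, 1], and a small silent class mirrors the ~1% of
annotated genes with no detectable expression while staying large enough to
exercise the exclusion path. One top-level seed drives a single RNG stream
(`withr::with_seed`), so a spec is a complete, reproducible description of
a data set.

What the generator does **not** emulate: replicate-level structure, batch
effects, mapping artifacts, or correlation between conditions. Passing the
recovery tests therefore shows the *score* behaves correctly on data
matching its assumptions — not that any particular real compendium is free
of confounders.

`recovery_metrics()` closes the loop: per-class score medians, the AUROC of
the score as a discriminator of conditionally expressed
(induced ∪ single_condition) versus constitutive genes (rank formula,
cross-checked against pROC in the tests), and the fraction of silent genes
correctly excluded, which must be exactly 1.

## Problem sizes and determinism

The validation suite runs at sizes where every property is already sharp:
oracle equivalence on 100 random matrices up to 20 × 10; invariance checks
on ~10 matrices up to 60 × 12; class recovery at 5,000 genes × 97
conditions (AUROC 1.0 under the default effect sizes); end-to-end pipeline
determinism at 300 genes × 15 conditions. The pipeline drivers
(`run_simulate()` → `run_compute()` → `run_benchmark()` →
`run_extremes()`) are pure functions of their input files and options:
reruns produce byte-identical tables and numeric figure exports, which is
what the determinism tests compare (never rendered image bytes).

## Known limitations

* The score ignores expression *level*: a gene uniformly expressed at 1 TPM
  and one at 1000 TPM both score 0. Filter on abundance separately if that
  matters.
* Conditions are weighted equally; over-represented condition types in a
  compendium pull the "uniform" reference toward themselves.
* With N conditions the score resolves at best ~log2(N) bits; comparisons
  of scores computed over different N should use `normalized_entropy`.
* No statistical test is attached to gene-set comparisons — the benchmarks
  are deliberately visual/locational, and no QC filter (e.g. on mapping
  rate) is applied upstream of the count table.
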
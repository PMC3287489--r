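---
title: "Reverse enrichment: inferring gene patterns from their miRNA regulators"
author: "mirsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse enrichment: inferring gene patterns from their miRNA regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Classical miRNA set analysis starts from a list of microRNAs and asks what
their target genes have in common. `mirsets` works in the opposite
direction: starting from one or more protein-coding genes, it collects the
miRNAs predicted to regulate them and asks whether those regulators are
over-represented in predefined miRNA sets — genomic clusters, sequence
families, curated functional groups, disease associations (HMDD-style), and
tissue-specific expression groups. A gene whose regulators concentrate in,
say, tumor-suppressor miRNAs carries a testable hint about its own biology,
because miRNA annotation is often better curated than annotation of the
gene itself.

## The statistical model

Let the background universe contain $N$ miRNAs, of which $K$ belong to the
set under test. The query — the distinct miRNAs predicted to regulate the
input gene(s) — has size $n$, and $k$ of them fall inside the set. Under
the null hypothesis that the query is an unstructured draw from the
universe, $k$ follows a hypergeometric distribution, and the reported
p-value is the one-sided upper tail

$$P(X \ge k) \;=\; \sum_{j=k}^{\min(n,K)}
\frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}} .$$

Each record also reports the *expected* overlap $nK/N$, the *fold*
enrichment $k/(nK/N)$, and the *percent* of the set matched, $100\,k/K$.
Only enrichment is tested; depletion is out of scope. The tail is
evaluated through the survival function of `stats::phyper`, so p-values
down to about $10^{-300}$ are representable; values are floored at the
smallest positive double and never reported as exactly zero.

### The background universe

No single obviously-correct universe exists: candidates include all known
miRNAs, the catalog union, or the miRNAs the prediction source covers.
`mirsets` fixes $N$ as the miRNAs of the chosen target-prediction source
intersected with the catalog universe. This makes the "expected" count
reflect what the source could possibly have matched: a miRNA that the
predictor never reports, or that belongs to no set, cannot contribute to
any overlap and would only dilute the model. Both component sizes are
logged when resources are assembled, and the universe size is echoed into
report metadata. Query miRNAs outside the universe are dropped (with a
logged count) rather than appended to $N$, keeping the sampling model
coherent.

### Multiple-testing correction

Both Bonferroni ($\min(1, mp)$) and Benjamini–Hochberg step-up FDR are
computed for every record, via `stats::p.adjust`. The family size $m$ is
the number of sets actually tested — sets with no member inside the
universe are skipped (and logged), but zero-overlap sets count toward $m$
even though they are hidden from reports, because they were tested.

The default correction scope is `per_category`: results are ranked and
discussed within each of the five categories, so each category forms its
own family. A `global` scope (one family across all categories) is
exposed as an option. The package's own replicate validation studies use
the global scope, for a statistical reason worth spelling out: the type-I
property they check is "no set *anywhere* reaches FDR ≤ 0.05 under the
null", which is a family-wise statement across all tested sets. BH
bounds the probability of any false discovery at the nominal level only
within one family; with five per-category families the per-study rate is
inflated roughly five-fold. Measuring the family-wise property therefore
requires the family-wise scope.

## Analysis modes and parameters

* **Single gene** — regulators of one gene form the query. Identifiers in
  any of seven namespaces (symbol, Entrez, Ensembl gene/transcript, UCSC,
  RefSeq mRNA, GenBank) are resolved to the official symbol; symbol
  matching is case-insensitive, accession matching case-sensitive.
* **Gene list** — the query keeps only miRNAs regulating at least
  `threshold` of the resolved input genes (inclusive, default 1; 1 yields
  the union of the per-gene regulator sets). Raising the threshold can
  only shrink the query. Unresolvable rows are skipped with a message,
  never fatal; duplicates collapse before the threshold is applied.
* **Pathway, individual** — every member gene is analyzed as its own
  query and corrected within its own family, mirroring per-gene result
  pages; the `highlight_map` then records, for each set, the genes whose
  per-gene FDR is at or below `fdr_cutoff` (default 0.05). A pathway-wide
  correction across genes is deliberately not the default: each gene is
  an independent question, and the highlight cutoff is descriptive.
* **Pathway, whole** — the member genes are pooled through the gene-list
  pipeline with threshold 1. The two routes are byte-identical by
  construction and by test.

Reports show only sets with at least one matched miRNA and can be ranked
by count, percent, fold (descending) or by raw, Bonferroni- or
FDR-corrected p (ascending); ties break by p-value and then set name, so
output files are deterministic. Function-category records carry a fixed
advisory string: because miRNAs repress their targets, a functional
pattern found among the *regulators* can be inverted in the gene itself.

## The synthetic resource generator

Real set collections and prediction tables are curated snapshots that
cannot be bundled, so `fixture_spec()` / `simulate_resources()` emulate
all four resource files at desk scale. Defaults: a universe of 200
miRNAs, 100 genes, six sets per category with 10–20 members, and 4–12
predicted target genes per miRNA — sizes at which a single gene collects
a regulator set of a realistic few dozen miRNAs and each set retains
enough members for the hypergeometric tail to be informative. A fifth of
the miRNA names carry mature-arm suffixes (`-5p`/`-3p`), exercising the
normalizer's arm-preservation contract; set members use mature-style
names throughout, one convention chosen once and documented here.

Planted enrichments are the ground truth for validation: a planted gene's
regulators are drawn without replacement with sampling odds `odds` (default
8) toward one designated set, exactly `n_regulators` (default 25) draws,
and planted genes are excluded from the uniform background pairing so the
plant is not diluted. The recovery study (200 replicates, universe 200,
planted set of 20, odds 8) requires the planted set to attain the minimum
FDR in at least 95% of replicates; the matching null study (no planting)
requires any-set discovery at FDR ≤ 0.05 in at most ~8% of replicates.
Both studies pass comfortably (measured ~99% and ~2–3%).

What the generator does **not** emulate: correlated set membership
(real families and clusters overlap heavily), prediction-score structure
(targets are a binary relation here), transcript-level redundancy, and
species other than a single human-style namespace. Passing tests
therefore demonstrate correctness of the statistical machinery and the
pipeline plumbing — not the biological fidelity of any particular curated
snapshot, whose exact numbers depend on resource versions.

## Numerical and degenerate-input choices

* p-values floored at `.Machine$double.xmin`; corrections capped at 1.
* `expected = 0` (an empty query after universe intersection cannot reach
  this point; it arises only for $n = 0$) makes fold undefined; it is
  reported as `NA`, never `Inf`.
* Sets with no universe member are skipped with a logged reason; an empty
  query after intersection produces an empty result with a warning, not
  an error.
* TSV reports print floats with 6 significant digits; the JSON report
  keeps full precision plus run metadata (source, $N$, $n$, $m$, scope,
  threshold, tool version, input digests). No timestamps: identical
  inputs give byte-identical files.
* Validation problem sizes (universe ≤ 25 for exhaustive-oracle grids,
  200-replicate studies, 10⁴-case property grids) were chosen so the full
  suite summarizes the method's behaviour at desk scale in about two
  minutes.

## Limitations

The quality of any real analysis is bounded by the prediction table
(target prediction has high false-positive and false-negative rates) and
by the coverage of the set collections; both biases are inherited, not
corrected. The tool reports association patterns, not mechanisms, and the
Function-category advisory above applies whenever directionality matters.
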
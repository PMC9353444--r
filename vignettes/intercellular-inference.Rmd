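---
title: "Annotation-aware inference of intercellular communication networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-aware inference of intercellular communication networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellxtalk)
```

## The problem and the model

Tissues function through signalling between cell populations: a *sender*
population releases a ligand, a *receiver* population expresses the
matching receptor. Single-cell RNA-seq resolves populations into clusters
and yields, per cluster, normalized expression and differential-expression
statistics. `cellxtalk` turns those summaries into a ranked, statistically
screened list of sender→receiver gene pairs between every ordered pair of
clusters.

The strength score of a candidate pair (A from the sender cluster, B from
the receiver cluster) is the product of cluster-mean normalized expression,

$$\mathrm{Power}_{A,B} = \overline{\mathrm{Exprs}}(A)\cdot\overline{\mathrm{Exprs}}(B),$$

and its significance comes from a cell-label permutation test: the full
label vector over *all* cells is shuffled \(N\) times (cluster sizes are
preserved), the power is recomputed under each shuffle, and

$$p = \frac{\#\{n:\ \mathrm{Power}^{(n)}_{A,B} \ge \mathrm{Power}_{A,B}\}}{N},
\qquad N = 100 \text{ by default}.$$

Pairs with \(p < 0.05\) are retained. Per ordered cluster pair \((i,j)\)
the retained pairs are aggregated into a network edge carrying the count
\(M\) and the aggregated power

$$W_{i,j} = \sum_{k=1}^{M} \mathrm{Power}_{A_k,B_k}.$$

Two deliberate reading choices in the test statistic deserve a note:

* **Tail direction.** The test is upper-tailed: a pair is significant
  when random relabelings rarely *reach* the observed power. A
  lower-tail reading would flag the weakest pairs as significant, which
  contradicts the use of the score as an interaction strength. A
  `tail = "lower"` switch exists for completeness.
* **No pseudo-count.** \(p\) uses the plain count over \(N\), so \(p = 0\)
  is possible at finite \(N\). The `conservative_p` flag switches to
  \((1+\#)/(1+N)\) for users who prefer a strictly positive estimator.

Labels are shuffled globally across all cells, not merely within the two
clusters under consideration: the null hypothesis is that cluster identity
as a whole is uninformative about the two genes, and global shuffling
keeps every cluster's size fixed while realizing that null. Sender and
receiver are distinct roles, so cluster pairs are ordered and self-pairs
\((i,i)\) are included unless `exclude_self` is set.

## The annotation model

Not every co-expressed pair can physically interact. Two databases encode
the biology used to filter candidates:

* **Gene database** (`load_gene_db`): per gene, subcellular localization
  over a closed vocabulary of 13 categories, each with an integer
  confidence 1–5; functional classes from a bundled taxonomy of 132
  classes partitioned into 16 groups (cytokine, receptor, enzyme, …); and
  GO-term memberships. A gene may carry several localizations — secreted
  proteins also appear in the cytoplasm — so selection asks whether *any*
  annotation matches. The default confidence cutoff is 4: only
  confidently placed proteins (confidence 4 and 5) satisfy a localization
  constraint, which is the recommended operating point; lowering it is a
  deliberate, monotone relaxation.
* **Interaction database** (`load_interaction_db`): per unordered gene
  pair, evidence-channel scores from which three (non-exclusive)
  provenance classes are derived — experiment-validated (`experiments`
  channel > 0), pathway-curated (`database` > 0), predicted (any other
  channel > 0) — plus a combined credibility score on 1–1000, binned at
  the fixed cutoffs 400/700/900 into low/medium/high/highest, and action
  records: one of 8 modes (activation, binding, catalysis, expression,
  inhibition, ptmod, reaction, other) and one of 4 effects (positive,
  negative, unspecified, undirected).

The bundled 132-class taxonomy is a synthetic stand-in honoring the
schema (132 unique classes, each mapped to exactly one of the 16 named
groups); installations with a curated class list can pass their own
mapping file to `function_taxonomy()` and the loaders.

Selection semantics are conjunctive across annotation axes (localization
AND function AND GO) and disjunctive within an axis (any listed category
counts). This mirrors how analysts phrase questions — "up-regulated,
secreted cytokines" on the sender side and "up-regulated membrane
receptors" on the receiver side, the canonical specs returned by
`canonical_specs()`.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `min_confidence` | 4 | integer 1–5 | keep confidently localized proteins only |
| `min_abs_log2fc` | 0.25 | log2 fold change | conventional cutoff for calling a gene regulated |
| `max_adj_p` | 0.05 | probability | standard significance convention |
| `n_perm` | 100 | count | default permutation budget; p-resolution 1/N |
| `alpha` | 0.05 | probability | permutation significance cutoff; `alpha >= 1` disables filtering |
| `min_level` / `min_credibility` | none | level / 1–1000 | interaction credibility floor (bins at 400/700/900) |
| `noise_sd` (generator) | 0.5 | log-scale SD | realistic spread for log-normalized cluster data |
| `effect_size` (generator) | 2.0 | expression units | clear but not degenerate planted separation |

No multiple-testing correction is applied by default — the permutation
test is screened per pair at `alpha`, matching common practice for this
family of tools; `stats::p.adjust` can be applied to the returned
`p_value` column when a corrected ranking is wanted.

## What the synthetic generator emulates — and what it does not

`make_fixture()` builds a complete, internally consistent dataset:
baseline expression `exp(N(0, noise_sd))` (non-negative, right-skewed,
mimicking log-normalized single-cell values), an additive `effect_size`
for each planted ligand in its sender cluster and receptor in its
receiver cluster, DEG tables computed from the generated matrix
(cluster-vs-rest log2 mean ratio, Wilcoxon rank-sum p, BH-adjusted within
cluster), and annotation/interaction databases in which the planted pairs
are confidently secreted cytokines binding confidently membrane-bound
receptors at credibility ≥ 900. Decoys exercise every filter: annotated
ligand/receptor lookalikes absent from the interaction database,
high-credibility interactions between unannotated background genes, and
low-credibility non-binding records.

The generator deliberately does **not** emulate dropout/zero inflation,
library-size variation, gene–gene correlation structure, batch effects,
or doublets. Passing tests therefore demonstrate the correctness of the
statistical machinery on clean, well-separated input — not robustness to
the full noise anatomy of real single-cell data, whose handling belongs
to upstream preprocessing.

Default fixture dimensions are 3 clusters × 20 cells and 30 genes with
two planted pairs of effect 2.0 — small enough to validate quickly and
large enough that the Wilcoxon DEG step and the permutation null behave
non-degenerately.

## Numerical and design choices

* `Exprs(·)` is the arithmetic cluster mean of normalized expression over
  *all* the cluster's cells (not the fraction expressing, not the
  median, and not restricted to DEG-passing cells); the DEG filter acts
  only on gene selection. Cluster means make the permutation null exact
  under label exchange.
* Localization confidence arrives on the integer 1–5 scale in the input
  table; the importer does not re-derive it from raw source-database
  scores (ETL is out of scope).
* Duplicate (gene, category) localization rows collapse to the maximum
  confidence; duplicate interaction rows for one unordered pair are a
  validation error.
* Ties in the permutation comparison use `>=`, so a constant gene yields
  p = 1 exactly.
* Output ordering is total and documented — power descending, then
  p-value ascending, then lexicographic gene and cluster names — so
  identical inputs and seed reproduce byte-identical tables.
* All randomness flows through an explicit `seed`; the caller's RNG
  state is saved and restored. The permutation index matrix depends only
  on the cell count, the permutation count and the seed, so every entry
  point (single-pair test, full inference, scans) sees the same
  permutations and the results are invariant to gene-row ordering.
* A pair matched by an undirected database record is emitted once per
  orientation that passes the sender/receiver gene selections: direction
  is imposed by the selections, not by the database.
* Multiple action records with conflicting effects for one pair are all
  preserved (filtering strips only non-matching ones); ranking among
  them is left to the caller.
* In the spatial-pattern layout the 13 localization categories collapse
  onto 4 diagram zones by a fixed mapping: extracellular region →
  extracellular space, plasma membrane → cytomembrane, nucleus → cell
  nucleus, everything else → cytoplasm. Genes without any localization
  fall back to cytoplasm with a warning.
* Benchmark pair sets are canonicalized as unordered pairs, since
  published ligand–receptor resources disagree on orientation;
  complex-based (multi-subunit) entries must be pre-expanded to binary
  pairs by the caller.

## Validation problem sizes

The shipped test-suite and acceptance script validate at desk scale,
chosen to exercise the mathematics rather than throughput: exact
enumeration of all 20 label splits of a 6-cell two-cluster configuration
against a 10,000-permutation Monte-Carlo estimate; a 200-replicate
vanishing-effect study confirming the empirical type-I rate at the
nominal 5% level; and full-pipeline recovery of the two planted pairs on
the standard fixture with zero decoys reported.

## Known limitations

* The score is expression-product based; it does not model downstream
  signal transduction in the receiver, receptor complex stoichiometry,
  or spatial proximity.
* Permutation p-values have resolution 1/`n_perm`; with the default 100
  permutations the smallest nonzero p is 0.01, and p = 0 means "never
  reached in N shuffles", not impossibility.
* The importer trusts the upstream normalization; only a negative-value
  check guards against z-scored or otherwise incompatible matrices.
* Cross-species analysis is limited to symbol-casing normalization;
  orthology mapping is out of scope.
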
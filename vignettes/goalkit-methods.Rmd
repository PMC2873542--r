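---
title: "Methods: over-representation analysis with configurable GO search strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: over-representation analysis with configurable GO search strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goalkit)
```

## The model

`goalkit` tests whether a group of genes is over-represented in functional
categories relative to a reference list.  For one category, membership of
the input list is summarized by the quadruple (n, K, I, N): `n` input genes
in the category, `K` reference genes in the category, `I` input genes found
in the reference, `N` unique reference genes.  Under the null hypothesis
that the input list is an exchangeable draw from the reference, the number
of category genes in the input is hypergeometric, and the evidence for
over-representation is the upper-tail probability

$$P(X \ge n) \;=\; \sum_{j=n}^{\min(K, I)}
  \frac{\binom{K}{j}\binom{N-K}{I-j}}{\binom{N}{I}},$$

identical to the one-sided Fisher's exact test on the 2×2 table.  The
implementation accumulates the tail in log space (`lchoose`) and clamps the
sum to [0, 1]; tests verify it against an exact-rational enumeration oracle
(`fisher_oracle()`, which shares no code with it), `stats::phyper` and
`stats::fisher.test` to 1e-12 over every table with N ≤ 12.

**Assumptions worth stating.** Genes are exchangeable under the null (no
gene-length or expression-level bias correction); categories are tested
marginally, ignoring the strong overlap correlation between a GO term and
its ancestors; and the reference list defines the sampling universe, so an
inappropriate reference (e.g. whole genome when only half the genome was
assayable) biases every p-value.  When no reference is supplied,
`run_analysis()` falls back to the whole annotated universe with a warning;
a study-matched reference is preferable whenever one exists.

Only over-representation is tested.  Under-representation and two-sided
alternatives are out of scope.

## Multiple-testing corrections

Raw p-values are corrected across the `m` categories tested in one analysis
run with Bonferroni (`min(1, p·m)`), Holm step-down, or Benjamini–Hochberg
step-up FDR — in decreasing order of stringency, so for every input vector
raw ≤ BH ≤ Holm ≤ Bonferroni elementwise.  Holm and BH are delegated to
`stats::p.adjust` behind the package's `correct_*()` surface; tests pin the
results to hand-computed values.  Two design choices the corrections depend
on:

* **Correction scope.** Each analysis kind — GO terms of one namespace, TF
  target sets, pathways — is corrected independently, mirroring the three
  separate result panels a user inspects.  Correcting jointly across kinds
  would be defensible but changes `m`; the per-kind choice is recorded in
  `run_report.json` so the multiplicity is always auditable.
* **Eligibility before correction.** Categories with fewer than `min_genes`
  input genes (default 2) and categories with no reference genes are removed
  *before* correction, so `m` counts only categories that could have been
  reported.  This treats `min_genes` as an eligibility filter, the
  conservative-transparent reading; applying it after correction would
  silently inflate `m`.

## The three search strategies

A gene's direct GAF annotations are its most specific terms ("leaves" in
the loose sense — they need not be topological leaves).  A gene with several
direct annotations keeps all of them, even when one is an ancestor of
another; no minimization is attempted.  The strategies differ in how far
annotations travel up the DAG before testing:

* **Strategy I (max path length from leaf, parameter k).** A gene counts
  toward every term within k parental steps of a direct annotation, along
  *any* parental path (a term reachable in ≤ k steps on one path qualifies
  even if another path is longer).  k = 0 tests direct annotations only.
* **Strategy II (min path length from root, parameter L).** Full upward
  propagation, then terms with `min_depth < L` are discarded.  The cut is
  *at-or-below* the level L, not exact-level-only: the alternative reading
  (test exactly level L) would silently drop every deep term, contradicting
  the combined strategy's stated purpose of discarding only terms *more
  general* than the threshold.
* **Strategy III (combined, k and L).** Strategy I's collection restricted
  by Strategy II's depth filter; parents within k steps that survive the
  depth cut are retained.  `III(k, L = 0) ≡ I(k)` exactly, which the tests
  assert on every fixture.

Depth is the *shortest* parent-edge path to the namespace root, computed
once at parse time by breadth-first search.  Depth and ancestry never cross
namespaces, and the analysis runs within one user-selected namespace.

**Edge semantics.** Which OBO relations count as "parental" is a genuine
design choice: `is_a` always; `part_of` by a config switch, default on,
matching common GO practice.  Users comparing against tools that walk
`is_a` only should set `include_part_of = FALSE`; path lengths (hence k and
L) change with the switch.  Obsolete terms contribute no traversal edges,
annotations to them are dropped with a warning, and `alt_id` aliases resolve
transparently to their primary id.

## Parameters and defaults

| parameter | meaning | default | rationale |
|---|---|---|---|
| `strategy` | GO-tree search strategy | `III` | specific terms plus a generality cut |
| `k` | max parental steps from a direct annotation | 0 | most specific terms only |
| `L` | minimum depth below the root | 3 | the cut level several classic GO tools default to |
| `correction` | multiple-testing correction | `bh` | FDR control; `none` available for diagnostics |
| `max_p` | corrected p-value ceiling | 0.05 | conventional |
| `min_genes` | minimum input genes per tested category | 2 | singletons are rarely interpretable |
| `include_part_of` | `part_of` edges are parental | `TRUE` | common GO practice |

All are overridable; none is a mandate.

## The synthetic-fixture generator

`fixture_spec()` / `make_dag()` / `make_annotations()` / `make_input_list()`
generate everything the test suite and the acceptance script consume, so no
ontology or annotation download is ever needed.  The generator emulates the
*structural* features the engine depends on — a rooted acyclic hierarchy
with multiple parents (layered construction: each term draws 1–2 parents
from the layer above, guaranteeing acyclicity and root reachability), genes
with 1–3 direct annotations, and an input list with enrichment planted at
one term.  It does **not** emulate realistic GO topology statistics
(branching factors, term-size power laws), annotation evidence-code
composition, or inter-category correlation structure of real genomes, so
passing tests demonstrate correctness of the machinery, not field
performance on any particular species' annotation.

Default study conditions, used throughout the validation: a 4-layer,
19-term ontology; a 200-gene universe; a 20-gene input list with
planted fraction 0.8 (16 of 20 genes drawn from the planted term's pool).
The planted term defaults to the deepest term with the largest annotated
pool, so recovery is tested where a specific term carries the signal.  With
`planted_fraction = 0` the generator degenerates to a uniform null draw
from the universe: the non-planted remainder is sampled from the untaken
universe rather than from the complement of the planted pool, precisely so
the null case is exactly uniform.

Generators are pure functions of `(spec, seed)`: RNG state is scoped and
restored, and the three sub-generators use fixed offsets of the spec seed.
All fixtures serialize to the same OBO/GAF/TSV dialects the parsers read,
so parser tests and engine tests share one source of truth.

## Numerical and degenerate-input policy

* Tail sums in log space; result clamped to [0, 1]; `n = 0` gives exactly 1.
* Output ties broken deterministically: corrected p, then raw p, then
  lexicographic category id — reruns are byte-identical.
* Gene ids are matched case-insensitively after whitespace trimming
  (normalized to upper case); no fuzzy identifier mapping is attempted.
* Hard errors, not guesses: cycles in the ontology (detected by topological
  sort, reported with a member term), `is_a` references to unknown ids,
  duplicate term ids, alt-id collisions, non-binary or ragged TF-matrix
  cells, an input list with no gene in the reference.  Recoverable problems
  (malformed GAF rows, annotations to unknown/obsolete terms, short pathway
  rows, input genes missing from the reference) are dropped with warnings
  and counted.

## Validation design

The type-I calibration check draws 2,000 null input lists (20 genes uniform
from a 200-gene reference) and measures how often a fixed category attains
raw p ≤ 0.05.  Because the test statistic is discrete, the rejection
probability equals the largest achievable tail level below α, not α itself;
the fixed category was therefore sized analytically at 15 genes, where
P(X ≥ 4) = 0.0484 sits next to the nominal 0.05, making the check
informative rather than vacuously conservative.  The planted-recovery check
asks that the planted term rank first by corrected p in ≥ 95% of 1,000
simulated input lists under the default study conditions.  Problem sizes
(N ≤ 12 for the exhaustive oracle sweep, 50-term DAGs for the
path-enumeration oracles, 10 oracle seeds / 100 monotonicity seeds) were
chosen so each property is exercised across thousands of cases while the
whole suite stays interactive.

## Known limitations

* No correction for the dependence between a term and its ancestors
  (no elim/weight-style decorrelation); Strategy I at small k limits, but
  does not remove, redundant reporting along paths.
* No gene-identifier translation: input, reference, GAF, TF matrix and
  pathway map must already share an id space.
* TF matrices must arrive pre-binarized; probabilistic binding scores are
  not thresholded internally.
* OWL ontologies, annotation downloads and under-representation testing are
  out of scope.
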
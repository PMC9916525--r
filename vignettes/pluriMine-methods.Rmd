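---
title: "Mining candidate pluripotency genes from unreplicated reprogramming transcriptomes"
author: "pluriMine authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining candidate pluripotency genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pluriMine)
```

## The problem

Deriving induced pluripotent stem cells (iPSCs) from a non-model species —
the motivating case is the Bactrian camel, where clonal iPSC lines were
reprogrammed from fetal fibroblasts (BCFFs) with the four Yamanaka factors —
leaves an obvious question: which genes of *this* species behave like
pluripotency genes? The experimental design that produces the data is
awkward for standard differential-expression machinery: one unreplicated
fibroblast baseline against a handful (typically seven) of unreplicated
clonal iPSC lines. pluriMine implements a complete, testable mining
procedure for exactly this design:

1. **Per-line differential expression** of every line against the baseline.
2. **Gene-set enrichment** of the up-regulated genes over six annotation
   levels (KEGG A-class, B-class and pathway; GO component, function and
   process), and selection of the terms worth screening.
3. **Three screening groups** sharing one count filter: an
   enrichment-membership screen (group 1), a screen driven by annotation
   subdatasets containing the known literature reprogramming factors
   (group 2), and an unscreened per-line top-*k* abundance ranking
   (group 3, the "supplementary" genes).
4. **Network core extraction**: the merged group-1/2 genes induce a
   subnetwork of a confidence-scored protein–protein interaction (PPI)
   graph; components with at least 6 proteins are retained and genes with
   more than three connections inside them become **core genes**.
5. **Combination** of core and supplementary genes into the final candidate
   table with full provenance.

A seeded synthetic-data generator emulates the whole study, so every stage
is exercised end-to-end with known ground truth and no external downloads.

## The differential-expression statistic

With no replicates anywhere, a dispersion cannot be estimated from the
data. pluriMine therefore uses the exact conditional binomial test: writing
$a$ and $b$ for the line and baseline counts of one gene and $L_a$, $L_b$
for the two library sizes (column sums), then conditional on the total
$t = a + b$, under the null of equal relative abundance

$$a \mid t \;\sim\; \mathrm{Binomial}\!\left(t,\ \pi\right),
  \qquad \pi = \frac{L_a}{L_a + L_b},$$

and the two-sided p-value is the total probability of all outcomes at most
as probable as the one observed (outcomes within $10^{-12}$ relative
probability of the observed one are treated as ties and included). The
implementation enumerates all $t+1$ outcomes for totals up to $10^5$ and
switches to binary-searched tail boundaries above that; both paths are
checked against a brute-force `choose()`-based oracle in the test suite.

Three properties matter in practice:

* Under Poisson-distributed counts the test is *exact* and slightly
  conservative at small totals (discreteness).
* Under overdispersed counts it is anti-conservative — as is any
  unreplicated exact test. The pipeline therefore treats p-values as a
  ranking device and pairs them with a fold-change threshold, and the
  default significance measure is the Benjamini–Hochberg FDR (`q`), the
  stricter of the two conventions in circulation for this procedure; raw
  `p` is available via `significanceOn = "p"`.
* It is a deliberate stand-in: it is **not** an emulation of replicate-aware
  negative-binomial machinery (edgeR/DESeq2), which this design cannot
  support.

Fold changes are CPM ratios with a pseudocount of 1 added to the raw counts
before library scaling — the conventional choice that stabilizes zeros and
makes the statistic antisymmetric under sample swap. A gene is called `up`
in a line if $\log_2\mathrm{FC} \ge 1$ and the significance measure is
below $\alpha = 0.05$ (`down` symmetrically). BH adjustment is applied per
line (each line is its own hypothesis family), and per annotation level for
enrichment, since the six catalog levels are separate families.

## Enrichment and term selection

Enrichment is the upper-tail hypergeometric test
$P(X \ge k)$ for an overlap of $k$ query genes with a $K$-gene term inside
an $N$-gene universe and an $n$-gene query. Term selection mirrors the
field's practice for this procedure: each GO level contributes its top 20
terms by p-value (ties broken by larger overlap, then term id — every tie
break in the package is deterministic), while KEGG levels contribute all
terms with $q < 0.05$ plus an `alwaysInclude` list for pathways selected on
biological grounds (the stemness pathways — apoptosis, oxidative
phosphorylation, the pluripotency-regulating, PI3K, MAPK, Wnt, JAK-STAT and
TGF-β pathways — regardless of their q-value; such forced terms are flagged
`"forced"` in the output). Applying "top 20" per GO level rather than
globally is a design choice: the three GO namespaces are not comparable
families, and a global cut would let one namespace crowd out the others.

## The count filter and the three groups

All screens share one count filter: baseline count $\le 50$ **and** line
counts $\ge 20$, both inclusive. The intuition is biological: a candidate
pluripotency gene should be near-silent in fibroblasts and clearly
expressed in the reprogrammed lines. How the seven line counts meet the 20
threshold is configurable (`mean` across lines by default, with
`all_lines`, `any_line` and `at_least_k` selectable); the mean is robust to
a single dropout line and closest to a per-group reading of the rule.
Similarly, "up-regulated" membership for the groups defaults to "called up
in at least one line" (`minUpLines = 1`), since the procedure pools seven
per-line DE tables.

Group 3 ranks, per line, the qualifying up-regulated genes by that line's
*raw* count descending (interpreting "copy number" as raw counts; CPM
ranking is available by filtering beforehand) and unions the per-line top
30. Note one mathematical property verified in the tests: the count filter
is idempotent and monotone in both thresholds, and so are groups 1 and 2 as
sets, but a *capped* top-$k$ ranking is not inclusion-monotone — widening
the baseline threshold can admit a high-count gene that displaces a
previous member of some line's top 30. The monotonicity invariant therefore
applies to the uncapped qualifying pools.

The group-2 "main subdatasets" are the catalog terms containing at least 3
(GO levels) or 2 (KEGG levels) detected inducible genes; the thresholds are
configurable because the original procedure lists its chosen terms without
stating the rule, and KEGG strata are coarser and fewer than GO terms. The
packaged default inducible list (`inducibleGenesDefault()`) holds the 25
literature factors: OSKM plus the published substitutes for each factor.

## Network core extraction

The merged group-1/2 genes are looked up in a user-supplied STRING-style
edge table (`protein1 protein2 combined_score`, scores 0–1000, kept at
`combined_score >= 400` by default — the medium-confidence convention). The
induced subnetwork keeps only edges internal to the query. Connected
components with $\ge 6$ proteins are retained (inclusive, with stable ids
ordered by size then smallest member), and genes with degree $\ge 4$
("more than three connections") within their retained component become core
genes. Degree is counted in the induced subnetwork, not in the full
background graph — the procedure reads its network diagrams as induced
query networks; both thresholds are arguments. The final table is the union
of core and supplementary genes labeled `core` / `supplementary` / `both`,
ordered with shared genes first, then by degree.

## What the generator emulates — and what it does not

`simulateCounts()` draws negative-binomial counts with log-normal base
means across genes (meanlog $\log 150$, sdlog 1.5), one baseline column and
seven line columns at nominal library size $10^6$ each, NB shape
(`size`) 100 — a biological coefficient of variation of about 0.1, chosen
for clonal lines sequenced without biological replication. A planted block
of 100 "pluripotency" genes is up-regulated in every line by $+3\ \log_2$
units; its baseline means are drawn low (meanlog $\log 12$, sdlog 0.6)
because pluripotency genes are silenced in fibroblasts — which is also
exactly what lets them pass the 50/20 count screen. A 100-gene fibroblast
block is down-regulated by $-3$; everything else is null. The first six
planted-up genes form the planted PPI core, wired as a complete subgraph
over an Erdős–Rényi background (edge probability 0.002, scores uniform on
[400, 1000] so default thresholds keep every planted edge).
`simulateAnnotations()` builds 30 terms per level (sizes 15–60); the first
3 per level are enriched, drawing 80% of members from the planted-up block,
with two guarantees: every planted-up gene occurs in at least one enriched
term, and the first enriched pathway-level term — the simulated stemness
pathway — contains the whole planted core. Every simulated inducible gene
is annotated at every level. A single master seed determines everything;
sub-generators derive child seeds by fixed offsets recorded in the run
manifest.

What passing tests on this generator show: the pipeline's set algebra,
statistics and graph filters are correct, and the procedure recovers a
planted pluripotency module under realistic noise. What they do not show:
performance on real data with unmodeled features — composition bias between
dissimilar libraries (no TMM-style normalization is applied), correlated
genes, annotation incompleteness, ortholog mismatch across species, and
overdispersion beyond the configured shape. Sequencing depth and dispersion
of the motivating study's libraries are unpublished, so the defaults are
chosen for testability, not fidelity.

## Numerical and degenerate-input choices

* Gene identity is the uppercased, trimmed symbol everywhere; all joins are
  case-insensitive (sources mix `Epha3` with `ASF1B`-style casing).
* `exactCountTest` returns 1 when the total is 0; enumeration switches to
  tail search above totals of $10^5$; ties use a $1+10^{-12}$ relative
  cushion on both sides of the comparison.
* Empty selected-term sets, empty queries, undetected inducible lists and
  empty networks all return empty results with warnings rather than errors;
  truly malformed inputs (negative counts, duplicate gene ids, short GMT
  lines, non-numeric scores) are errors naming the offender.
* Every ordering that could be ambiguous (equal p, equal counts, equal
  component sizes) is broken deterministically, ending in lexicographic
  ids, so identical inputs give byte-identical outputs.
* Multiple baseline replicates (supported, default 1) are pooled by
  summation for testing and averaged for the baseline count filter.

## Problem sizes used by the checks

The packaged tests and the acceptance checks run the full pipeline at the
generator's default scale (2000 genes × 8 samples, 14 000 gene-line tests,
about 4000 background PPI edges), plus a 1500-gene zero-effect null run;
oracle equivalences cover all two-sample totals up to 25 at three library
ratios, hypergeometric grids to $N = 30$, and 100 random graphs of up to
100 nodes. These sizes were chosen so a complete check runs comfortably on
a laptop while leaving every code path, including the large-total tail
search, exercised.

## Known limitations

* The exact conditional test's size holds under Poisson-like noise; under
  strong overdispersion its raw p-values are optimistic. This is inherent
  to unreplicated designs, and is why the fold-change threshold and FDR
  default matter.
* The procedure's published gene counts (511 group-1 genes, 401 group-2,
  46 core, 42 supplementary, 85 candidates from the motivating study)
  depend on undeposited raw data; the package reproduces the *procedure*
  and its arithmetic (e.g. $46 + 42 - 3 = 85$), not those exact lists.
* Cross-species comparison trusts the supplied ortholog table; the
  uppercase-symbol fallback is approximate and logged as such.
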
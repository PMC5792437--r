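---
title: "cogex: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cogex: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogex)
```

## Scope and data model

`cogex` analyzes an ordered progression series of cell lines: an FPKM matrix
(genes × samples) plus a sample sheet assigning every sample to exactly one
line, with an explicit total order on the lines. The analysis is
*transition-wise*: every statistic is computed between a parental line and the
next (derived) line in the series. Upstream steps — alignment,
quantification, identifier mapping — are out of scope; FPKM values are taken
as given, and gene identifiers are matched as exact case-sensitive strings.

## Differential testing

Each gene is tested with a two-sided two-sample t-test on the replicate FPKM
values of the two lines. The default is the pooled-variance Student form,
because the replicates of a line are treated as exchangeable draws from one
population (see *Synthetic data* below for why); the Welch form is available
via `welch = TRUE` for users who distrust variance homogeneity between lines.

Two degenerate conventions are fixed explicitly because FPKM ties — above all
ties at zero — are routine:

* zero pooled variance and equal group means (e.g. an all-zero gene):
  `p = 1`, never `NaN`;
* zero pooled variance and different means (two distinct constants):
  `p = 0`.

FDR correction is Benjamini–Hochberg, implemented as the literal step-up
(`q_(i) = min_{j>=i} p_(j)·m/j`, capped at 1) and verified in the test suite
against an independent brute-force suffix-minimum oracle and
`stats::p.adjust`. One numerical subtlety: the scaling is computed as
`(m/j) * p`, not `(p*m)/j`; the latter can land one floating-point ulp below
`p` at `j = m` and break the exact elementwise invariant `q >= p`. Correction
is performed *within* each pairwise comparison (`m` = genes tested in that
pair), matching the per-pair DEG counts the workflow reports; an optional
`min_expression` filter (default off — every gene is tested) excludes
genes weak in both lines from testing and hence from `m`.

## Direction labels and thresholds

DEG calling uses `alpha = 0.05` on either `p` (mode `"p"`) or `q` (mode
`"q"`). For a DEG with parental mean `mP` and derived mean `mD`, exclusive
expression is checked first (`mD == 0` → `EXCLUSIVE_PARENTAL`, `mP == 0` →
`EXCLUSIVE_DERIVED`; exact-zero comparisons are intended — FPKM zeros are
exact in practice). Otherwise the ratio `r = mD/mP` is classified with the
0.8 / 1.2 thresholds; the continuum interval is **closed** on both sides
(`r = 0.8` and `r = 1.2` are `CONTINUUM`). The ±0.2 band reflects the rule of
thumb that ratio fluctuations of ~0.1 occur between technical replicates
while ~0.3 marks real variation. Both thresholds are tunable (`ratio_low`,
`ratio_high`), with the invariant `ratio_low < 1 < ratio_high`. A gene
flagged significant with zero FPKM in both lines is an invalid state and
raises an error rather than a silent label.

## The 11 clusters of gene expression

The CoGE taxonomy mixes two kinds of definitions: three patterns (exclusive
parental, exclusive derived, continuum) are stated in terms of a *single*
parental/derived pair, while the other eight distinguish "parental",
"derived" and "common" regulation with both DOWN and UP variants per side —
impossible to satisfy within one ratio. `cogex` therefore evaluates the
first three on the focal comparison alone, and the other eight on the cross
of the predecessor's and the focal comparison's DOWN/UP status. This is the
only reading under which all eleven names are satisfiable, and it makes the
first comparison of a series (which has no predecessor) a pure reference for
the second.

Precedence in `assign_coge()`: focal `EXCLUSIVE_PARENTAL`, then focal
`EXCLUSIVE_DERIVED`, then focal `CONTINUUM`, then the cross rules on
`{DOWN, UP}` where "not regulated" means any other label. Consequences worth
stating:

* every gene that is a DEG in the focal comparison receives exactly one
  cluster;
* a gene regulated only in the predecessor receives a cluster only if its
  predecessor label is `DOWN` or `UP` (the `EXCL_PARENTAL_*` clusters); a
  predecessor-only exclusive or continuum gene matches no rule and stays
  unassigned. The cluster counts therefore partition the focal DEGs plus the
  predecessor's DOWN/UP genes, not the full union of both DEG lists.

Whether the `CONTINUUM` cluster should additionally require DEG status in the
predecessor comparison is genuinely undecidable from the published counts;
the package defaults to requiring focal DEG status only and exposes the
alternative as `continuum_requires_prev = TRUE` (CLI flag
`--continuum-requires-prev`).

## Progression-consistent genes

`find_consistent_genes()` keeps genes that are DEGs in *every* comparison of
a chained list and carry the identical direction label in all of them. The
filter operates on direction labels, not on the 11 CoGE names: the published
26-gene biomarker set groups exactly by the three labels (15 down / 10
continuum / 1 up), and all 26 printed FPKM quadruples verify numerically
under this rule — the package's acceptance suite recomputes that grouping
from the shipped fixture. In the full pipeline the filter runs over the
focal transitions (those with a predecessor), mirroring the practice of
discussing only the transformed-line comparisons.

## Hallmark contributions

Pathways come in as GMT gene sets plus a pathway→hallmark table over the
8 + 2 vocabulary (the eight consensus hallmarks plus "other cancer types" and
"chronic diseases"); the curated mapping is consumed as data, never computed.
Gene-level hallmark membership is via pathway union, so one gene may count in
several hallmarks — intentionally, since genes take part in more than one
pathway.

For the relative contribution of hallmark `h` to the reference in cluster
`c`, the denominator is the *hallmark's* genes inside the cluster,
`n(h,c) = |G(h) ∩ C(c)|`, not the cluster size and not the reference's size.
This choice reproduces two conventions of the published table: the reference
hallmark scores exactly 100 in every cluster where it has genes, and empty
cells print as 0.0. `0/0` is defined as `0.0` (not `NaN`) so that the
11-cluster mean is always defined. Aggregation is deliberately unweighted: a
plain mean over the 11 cluster percentages per comparison, then a plain mean
over comparisons, then a descending rank with the reference excluded. Both
the per-comparison and the overall means are reported, since pooling genes
across comparisons would be a defensible alternative reading.

## Synthetic data: the stated world

`simulation_config()` defaults encode the experimental design the package
emulates: **5 lines × 7 replicates** (three biological experiments pooled
into seven flat technical datasets per line — hence replicates are modeled as
exchangeable within a line, with no biological/technical hierarchy, matching
the flat t-test design), lognormal multiplicative replicate noise with
**cv = 0.10**, base first-line means uniform on **[5, 200] FPKM**, and planted
ratio patterns per transition: DOWN steps in **[0.2, 0.6]**, UP in
**[1.5, 3.0]**, CONTINUUM in **[0.95, 1.05]**, plus exclusive-expression genes
(exact zeros before/after a random switch line) and null genes (one mean for
all lines). No distributional information about the real replicates is
published, so cv = 0.10 and the lognormal form are stand-ins chosen because
expression noise is strictly positive with variance growing with the mean;
they are not estimates.

One planted pattern needs a dedicated knob: a CONTINUUM gene must be
*statistically significant with negligible fold change*. At cv = 0.10 a
ratio in [0.95, 1.05] is a near-null contrast with ~15% power, so continuum
genes as a class would be undetectable. The generator therefore draws
continuum replicates with a much tighter `continuum_cv` (default 0.001),
making them significant by construction — which is precisely what the
continuum concept asserts: a reproducible, tightly measured shift that is too
small to matter as fold change. All other patterns use `cv`.

What a green synthetic test does **not** establish: recovery of published
genome-scale constants (DEG counts per pair, pathway inventories, hallmark
pathway totals), robustness to batch effects, dropout processes beyond exact
planted zeros, or count-level noise (the generator works on FPKM directly,
not reads). Those quantities depend on the unavailable raw data and on
version-pinned external resources, and are deliberately replaced by
property-based checks (oracle equivalence, invariants, parameter recovery,
type-I control at 2000+ null genes within three Monte-Carlo standard errors).

## Determinism and I/O

Identical seeds give byte-identical simulated files; `write_results()` output
is deterministic (fixed column order, rows sorted by pair and gene id, no
timestamps). Expression readers accept decimal commas (`0,4972`) — published
tables print them — normalize to dot decimals, and reject any other
malformed numeric rather than coercing to `NA`. GMT parse errors carry line
numbers; hallmark names outside the 10-name vocabulary are errors unless
explicitly overridden. Packaged fixtures are verified against recorded MD5
checksums at load time, so the acceptance surface cannot drift through an
accidental edit.

## Known limitations

* The pooled t-test on 7 pooled technical/biological replicates understates
  biological variance; the per-pair DEG lists should be read as descriptive
  of this model system, not as population-level inference.
* FPKM ratios are unstable near zero; the exclusive-expression rules catch
  exact zeros, but very small parental means can still produce extreme
  ratios. The `min_expression` filter exists for that case and is off by
  default to keep the default behavior faithful to the emulated workflow.
* Hallmark scoring is set-based; it ignores pathway topology, gene weights
  and expression magnitude.
* The unassigned residue of the CoGE rules (predecessor-only exclusive or
  continuum genes) is reported as `NA` rather than forced into a cluster.
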
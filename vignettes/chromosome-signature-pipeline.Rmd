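---
title: "Chromosome-restricted cell-type signatures: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-restricted cell-type signatures: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telosig)
```

## The problem

Lung telocytes — interstitial cells with long prolongations — were
characterized against seven neighbouring cell types (mesenchymal stem
cells, fibroblasts, alveolar type II cells, airway basal and proximal
airway cells, and CD8+ T cells from bronchial lymph nodes and lungs) by
comparing microarray expression profiles restricted to chromosome 1.
The focal type is observed at two culture timepoints (day 5 and day 10);
the other types come partly from the same platform and partly from
public repository series, so the analysis mixes arrays that were never
hybridized together. `telosig` re-implements that workflow as a tested,
reusable pipeline: harmonize across datasets, compute a signed fold for
every focal-vs-other comparison, count differential genes over a
threshold grid, intersect to a focal-type-specific signature, cluster
the samples, and test gene-set over-representation.

Because the original raw arrays are not available at desk scale, the
package ships a first-class synthetic generator that emulates the
statistical structure of such a merged collection, with planted ground
truth against which every stage is validated.

## The fold statistic

All differential calls rest on one statistic. For a gene with focal
group mean $a$ and other-group mean $b$ (linear "density of expression",
averaged over replicates), with pseudocount $\varepsilon > 0$ and
$a' = a + \varepsilon$, $b' = b + \varepsilon$:

$$
f =
\begin{cases}
\; (a' - b')/b', & a' \ge b' \\
\; -(b' - a')/a', & a' < b'
\end{cases}
$$

i.e. the relative difference over the *smaller* side's mean. Under this
definition "up-regulated more than onefold" ($f > 1$) is exactly a more
than twofold ratio, and $f(a,b) = -f(b,a)$. The historical formula
"(focal − other) / focal" is bounded above by 1 whenever the other cell
expresses the gene at all, so an up-threshold of 1 is unsatisfiable
under it; it remains available as `fold_change(..., variant =
"literal")` for comparison, but the symmetric form is the default and
the one all signature logic uses. The pseudocount default is
$\varepsilon = 1$ linear intensity unit: large enough to guard division
by near-zero background on a microarray intensity scale (where
expressed genes sit at hundreds to tens of thousands of units), small
enough not to distort expressed genes. Thresholds are strict
(`fold > t`), matching the "more than onefold" wording.

A gene belongs to the focal-type-specific **signature** at threshold
$t$ only if it passes against *every* other cell group. With two focal
timepoints the `timepoint_rule` decides whether the all-comparison
condition must hold in both (`"both"`, the default) or in at least one
timepoint's complete comparison set (`"either"`). The source material
is ambiguous between the two ("days 5 and/or 10" in one place, a
both-timepoints table elsewhere), which is why the rule is a named
parameter rather than a constant.

## Harmonization

Two steps precede the folds.

**Quantile normalization** (within each dataset block) forces every
sample column to the common distribution given by the row-wise mean of
the column-sorted input. Ties within a column receive the mean of the
quantile targets their ranks span — deterministic, and it preserves the
column total of the targets. The implementation is in the package
because this tie rule is part of the contract; it is cross-checked
against `limma::normalizeQuantiles` in the test suite.

**Housekeeping scaling** (across datasets) assumes a designated set of
housekeeping genes is equally expressed in every cell type. With $B$
the full linear matrix and $H$ its housekeeping rows, $Y_j$ is the mean
of $H$ in sample $j$; $C$ is the mean of $Y_j$ over the *reference*
samples (the groups from the platform whose scale is taken as the
baseline — in the default design the focal type's own platform,
contributing the first four sample groups); the scale factor is $Z_j =
1$ for reference samples and $Y_j / C$ otherwise; and the harmonized
matrix is $E_{ij} = B_{ij} / Z_j$. This removes any per-dataset
multiplicative factor exactly in the noise-free limit, never changes
within-column gene ratios, and leaves reference columns untouched. The
defining equations survive only as fragments in the source material;
this reconstruction is the minimal one consistent with all of them, and
the operation's contract (a `housekeeping_spec` in, matrix plus audit
report out) is deliberately narrow so an alternative reading could be
slotted in behind the same interface. The housekeeping set itself is
user-supplied — the original study never names its genes — and the
synthetic generator designates its own.

The pipeline default is quantile-normalize within dataset first, then
housekeeping-scale across datasets (the order is recorded in the run
manifest). The reverse order is defensible; within-dataset
normalization first means the cross-dataset step sees columns that are
already distributionally comparable inside each block, and the
housekeeping step is the only one that can bridge blocks.

**Median polish** is provided as the RMA-style probe summarizer
(`collapse_probes_to_genes(method = "median_polish")`): iterated median
sweeps of the additive model `log2 value ~ overall + probe + sample`,
stopping when the largest absolute residual change falls below `tol`
(default `1e-8`, `max_iter = 100`). The default collapse is the
per-symbol mean: the source never states its collapse rule, and the
mean is scale-stable and order-independent. Background correction of
raw scanner files is out of scope — the pipeline never sees them.

## The synthetic generator

`synthetic_config()` describes the study conditions; its defaults *are*
the emulated design and are not tuned per test:

* 645 genes on the focal chromosome ("1") among 10,000 background genes
  spread over the other chromosomes;
* eight cell types — the focal type (two timepoints, so nine sample
  groups) plus seven others — split over four dataset blocks mirroring
  one in-house platform plus three public series;
* 3 replicates per sample group (the public groups in the emulated
  design had 1–3; a uniform 3 keeps group means equally precise);
* 20 housekeeping genes drawn from the background, one shared true mean
  across all groups;
* 14 planted up- and 39 planted down-regulated focal-specific genes at
  linear effect ratio 3, applied in both focal timepoints (a switch
  restricts the effect to one timepoint to exercise the both/either
  rules);
* per-gene baseline drawn once on log2 scale from N(8, 2²) and
  exponentiated — matching the positive, right-skewed behaviour of
  array intensities;
* measured value = true group mean × dataset batch scale ×
  `2^N(0, noise_sigma²)`, with `noise_sigma = 0.2` as the default noisy
  condition and batch scales defaulting to 1;
* optionally, k probes per gene with fixed log2 affinity offsets, and
  unannotated junk probes for the annotation filter.

One field goes beyond the minimal design: each non-focal cell type
receives `n_type_markers` (default 10) of its own up-regulated marker
genes *on the focal chromosome*. Without them, every non-focal type
would have an identical true profile after chromosome restriction, and
the clustering claim worth testing — that each cell type's replicates
form a clade and the focal timepoints pair up before joining anything
else — would be vacuous. Markers are up in exactly one non-focal type,
so they can never pass the all-comparisons signature rule and leave the
planted-recovery properties untouched.

What the generator does **not** emulate: probe-level spatial or dye
artefacts, heteroskedastic intensity-dependent noise, correlated gene
modules beyond the planted effects, annotation errors, or
platform-specific probe sets measuring different gene universes.
Passing recovery tests on this generator therefore demonstrates the
*logic* of the pipeline — filtering, harmonization, fold algebra,
intersection — not robustness to every pathology of real arrays.

## Numerical and design choices

* **Determinism.** Every stochastic step flows from one integer seed;
  `run_pipeline` with identical config and seed produces byte-identical
  outputs. Clustering ties are broken by the lexicographically smallest
  pair of cluster member sets; top-k ties by C-locale symbol order.
* **Clustering.** Samples are clustered over the union of differential
  genes (|fold| beyond the signature threshold in any comparison),
  using 1 − Pearson on log2 values and average linkage — common
  microarray defaults; both are configurable since the original names
  neither. The agglomerator is written in the package (the deterministic
  tie-break is part of the contract) and matches `stats::hclust` merge
  heights on tie-free inputs.
* **Enrichment.** Upper-tail hypergeometric via `stats::phyper` with
  Benjamini–Hochberg adjustment across the supplied collection;
  over-representation only. Gene-set collections are user-supplied GMT
  files; no ontology retrieval, keeping everything offline.
* **Degenerate inputs.** Missing values are rejected at parse time
  rather than imputed; zero-variance samples make the Pearson distance
  fail loudly (naming the sample); a housekeeping mean of zero aborts
  scaling; an empty chromosome restriction warns and returns an empty
  matrix.
* **Gene universe.** Probes without an official symbol are dropped
  first; the cross-platform gene universe is whatever survives the
  explicit annotation and intersection steps, which the manifest logs
  stage by stage (genes × samples), so attrition is auditable.

## Problem sizes used in validation

The test suite and the acceptance script exercise the full study-scale
design (10,645 genes × 27 samples) for the end-to-end recovery checks —
a single run takes a few seconds — and 20 seeded replicates for the
noisy-recovery summary. Oracle equivalence checks (median polish,
correlation, clustering, hypergeometric enumeration) run on small
random instances (n ≤ 8 leaves, N ≤ 16 universes) where brute force is
exact.

## A worked run

```{r run, eval = FALSE}
cfg <- pipeline_config(
  synthetic = synthetic_config(noise_sigma = 0, seed = 5),
  outdir = "telosig_demo", seed = 5)
res <- run_pipeline(cfg)
res$signature
#> signature_set: 14 up, 39 down (fold > 1, timepoints: both)
head(res$counts[, 1:4], 3)
#>    comparison up_gt_1 up_gt_2 up_gt_5
#> 1  TC5 vs MSC      14       4       0
#> 2 TC10 vs MSC      14       4       0
#> 3  TCs vs MSC      14       4       0
```

The noiseless run recovers exactly the 14 planted up and 39 planted
down genes; the per-comparison down counts additionally include the
other type's own markers, as they should — those genes really are lower
in the focal type than in that one comparator, but they are not
focal-specific and never enter the signature.

## Known limitations

* The housekeeping reconstruction, while the minimal consistent
  reading, is still a reconstruction; results depend on the chosen
  housekeeping set and reference samples.
* The literal fold variant is provided for comparison but produces no
  up-calls at threshold 1 by construction.
* The co-expression network is a local stand-in for curated
  protein-association networks: absolute Pearson correlation across the
  analysed samples, which conflates direct and indirect association and
  depends on the sample panel.
* No variance-based test statistic is computed; the screening is pure
  fold thresholding, as in the workflow it re-implements.
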
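---
title: "Enrichment-score deconvolution of homogenate RNA differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enrichment-score deconvolution of homogenate RNA differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eshrd)
```

## The problem

Bulk ("homogenate") RNA-seq of brain tissue mixes transcripts from neurons,
glia and vascular cells, so a differential-expression (DE) result from
case-vs-control homogenates cannot say *which* cell type drives a change.
Cell-resolved alternatives (cell sorting, laser capture microdissection,
snRNA-seq) are expensive and often unavailable for archival cohorts. This
package implements a label-transfer approach: a cell-sorted reference panel
is used once to classify every gene by cell-type specificity, and those
labels are then joined onto any homogenate DE table to read bulk results in
cell-type-resolved terms.

## The classifier

The reference is a genes × cell-types matrix of fpkm values; the intended
panel profiles seven cerebral-cortex cell types: neurons (N), astrocytes
(A), microglia (M), myelinating oligodendrocytes (MO), newly formed
oligodendrocytes (NFO), oligodendrocyte precursors (OPC) and endothelial
cells (EC). For gene $g$ and cell type $c$ the enrichment score is

$$ES_c(g) = \frac{x_c(g)}{\operatorname{mean}_{c' \neq c} x_{c'}(g)},$$

the fpkm in the focal cell type over the mean fpkm of all other cell types.
Writing $ES_{high}(g) = \max_c ES_c(g)$, cell types split into a high set
$H = \{c : ES_c \ge \alpha_{high} ES_{high}\}$ and a low set
$L = \{c : ES_c \le \alpha_{low} ES_{high}\}$ with defaults
$\alpha_{low} = 0.25$, $\alpha_{high} = 0.75$:

* **cell-specific** — $H \cup L$ covers all cell types and $|H| = 1$;
* **multiple-cell-specific** — coverage with $|H| > 1$; the label is the
  slash-joined high set in panel column order (e.g. `MO/NFO`);
* **mixed** — at least one score falls strictly inside the open band
  $(\alpha_{low} ES_{high},\, \alpha_{high} ES_{high})$: the gene cannot be
  attributed to a small set of cell types.

Two boundary conventions make the three classes a true partition, which the
verbal definitions alone do not guarantee. First, scores exactly at
$\alpha_{low} ES_{high}$ or $\alpha_{high} ES_{high}$ belong to the low/high
sets, so the mixed band is open. Second, a gene whose high set is the *full*
cell-type set (a perfectly uniform gene has $ES_c = 1$ everywhere) is
relabelled mixed: "expressed in all cells" is the operational meaning of
mixed, not a seven-cell-specific class. Since the maximum always sits in
$H$, every valid profile receives exactly one label, and because $ES$ is a
ratio the label is invariant to rescaling a gene's row and to reordering
the panel's columns.

A collapsed view merges the three oligodendrocyte sub-types and their
combinations into one pan-oligodendrocyte class `O` (`MO/NFO` → `O`,
`OPC/M` → `M/O`, `mixed` untouched), which is the granularity used for
downstream enrichment and validation.

### Pre-processing

* **Floor filter.** Genes whose value is at or below the detection floor
  (default 0.1 fpkm) in *every* cell type are removed. The filter is
  implemented as "all values ≤ floor" rather than "= floor" so panels with
  values below the nominal floor behave sensibly.
* **Positivity clamp.** Surviving sub-floor values are raised to the floor
  before scoring, guaranteeing strictly positive denominators. The clamp
  intentionally breaks exact scale invariance for values *below* the floor;
  at measurable expression levels the invariance is exact.
* **Ortholog mapping.** When the reference and the DE tables live in
  different identifier namespaces (mouse symbols vs human Ensembl ids), a
  two-column ortholog table translates the panel after filtering. Unmapped
  genes are dropped and counted; one-to-many sources are duplicated under
  each target; many-to-one collisions are averaged per column; many-to-many
  entries are dropped entirely, because the ambiguity cannot be resolved
  without external evidence. Ambiguity is judged on the map restricted to
  genes actually present in the panel — a many-to-many tangle among genes
  the panel never measured is irrelevant.

`eshrd()` composes filter → map → score → classify → collapse and returns a
fitted classification object; `predict()` applies it to DE tables.

## Deconvoluting DE tables

A DE record carries `gene_id`, `log2fc`, `pvalue`, `fdr` and a dataset tag.
DEGs are selected by strict `fdr < 0.05` (the threshold is a parameter).
Each DEG inherits its gene's collapsed label; genes absent from the
classification are tagged `unclassified`, reported separately, and excluded
from prevalence denominators. Per (dataset, class) summaries report the DEG
count, the percentage with `log2fc > 0` (exactly zero counts as
not-upregulated), and the class prevalence among classified DEGs. Duplicate
gene ids within one DE table are an error rather than silently collapsed:
two rows for one gene in one contrast are ambiguous.

## Permutation enrichment

Whether a class is over-represented among a dataset's DEGs is tested by
permutation: each of `n_perm` (default 50,000) iterations draws
$|DEG|$ genes *without replacement* from the universe of classified,
measurable genes of that dataset and counts members of the focal class. The
empirical p-value uses the add-one correction
$p = (1 + \#\{\text{resampled} \ge \text{observed}\})/(n_{perm} + 1)$, and
a companion flag records the procedure's own criterion — the observed count
strictly exceeds the resampled count in at least 95% of permutations. Both
are reported because they answer slightly different questions; under a
uniform null the flag fires in well under 10% of tests (checked by
simulation in the test suite). The resampled count is exactly
hypergeometric, and the test suite checks the permutation estimate against
`phyper` within Monte-Carlo error; the user-facing path keeps the actual
permutation so that the reported numbers are the procedure's own. Per-test
seeds are derived from a mandatory master seed and the (dataset, class) name
with a rolling hash, so adding one test never perturbs another's stream.

One sampling ambiguity had to be resolved: the sampled set size is the
dataset's *total* DEG count, not the focal class's DEG count. Sampling a
set sized to the observation and then comparing it to the observation is
degenerate; the chosen reading is the only one that yields a well-defined
comparison.

## Concordance validation

Homogenate-derived cell-specific calls are validated against an independent
cell-resolved DE table two ways:

* **FDR sweep** — for every cutoff on the inclusive grid 0.05 to 1.00 in
  steps of 0.001 (951 points), both tables are restricted to focal-class
  genes with `fdr < cutoff` (strict, matching the DEG rule), intersected,
  and the sign concordance (percentage of pairs with agreeing `log2fc`
  sign; zero fold changes have no sign and leave the denominator) and
  Spearman's $\rho$ (average ranks, two-sided p) computed. The sweep
  filters *both* tables by default; `filter_side` restricts the cutoff to
  one side for asymmetric designs.
* **log2FC cutoffs** — the cell-resolved table is filtered only by
  $|log2FC| \ge L$ for $L \in \{0, 0.25, 0.5, 1\}$ (no p-value filter, to
  admit more genes) and intersected with the class-restricted DEGs of the
  bulk side. Points with fewer than 10 overlapping genes are *flagged*
  low-support rather than dropped, so the full curve stays visible.

Self-comparison is a fixed point (100% concordance, $\rho = 1$ wherever at
least two non-tied pairs exist), and the strict-< filter makes the passing
gene sets nested in the cutoff, so `n_overlap` is non-decreasing along the
sweep — both are enforced as tests.

## The synthetic world

`generate_panel()` plants genes with known labels: a cell-specific gene
carries `specificity_fold` (default 50) times the background fpkm in its
focal cell(s); a mixed gene additionally carries one cell placed, in the
noise-free construction, *exactly* at the middle of the indeterminate band
(the intermediate multiplier solves
$m^2 + (k-2)m - t F (F + k - 2) = 0$ for band position $t = 0.5$). Default
class proportions mirror the reference database this method was built from
(73.4% mixed; microglia 6.6%, neuron 5.9%, endothelial 5.7%, astrocyte
3.6%, pan-oligodendrocyte 3.1% split over sub-types; the remainder a small
neuron/astrocyte multi-cell class). Rows are scaled by a log-normal overall
expression level (median 5 fpkm), multiplicative log-normal noise with
coefficient of variation `noise_cv` is applied per value, and everything is
clamped at the floor.

`noise_cv = 0.25` is the default — a realistic between-replicate CV for
sorted-cell RNA-seq fpkm. Two things follow. Noise-free panels are
recovered *perfectly* (this is an acceptance test), so any green result at
`noise_cv = 0` establishes the algebra, not robustness. At the default
noise, genes planted mid-band drift across the 0.25/0.75 boundaries first —
a 2,000-gene default panel classifies roughly half the planted mixed genes
as mixed, with the spillover landing mostly in adjacent multi-cell classes.
That is the intended behaviour of a hard-thresholded partition under
multiplicative noise, and it is why accuracy-vs-noise is tested as a
monotone trend, not a fixed number. The generator emulates specificity
structure and measurement noise only: no read counts, library-size effects,
covariates, or correlated genes.

`generate_de_table()` plants DEGs over a classified universe with per-class
direction probabilities and effect sizes, optional per-class sampling
weights (to plant enrichment), uniform null p-values for the rest, and a
Benjamini–Hochberg FDR column; planted DEG p-values are uniform on
$(0, 10^{-6}]$ so they pass any reasonable FDR cut without tuning.

## Numerical and design choices

* Thresholds, floor and the permutation count are parameters with the
  reference defaults (0.25, 0.75, 0.1 fpkm, 50,000), so the method
  generalizes beyond the 7-cell panel.
* Ties at $ES_{high}$ need no tie-break: all maxima are in $H$ by
  construction.
* Duplicate panel rows and ortholog many-to-one collisions average per
  column (order-independent, unbiased) and warn.
* TSV outputs serialize floats at 6 significant digits for reproducible
  diffs; every output round-trips through its own reader.
* Empirical p-values can never be exactly zero (add-one correction).
* Spearman's $\rho$ on fewer than ~20 genes is noisy; the sweep reports it
  at every point and leaves significance statements to the caller.

## Limitations

* Labels are only as good as the reference panel; the intended panel's OPC
  fraction carries a documented ~5% microglial contamination that is not
  corrected here.
* A fixed ortholog map cannot reproduce historical mapped-gene counts
  exactly across resource versions; counts of dropped/merged genes are
  logged so drift is visible.
* The classifier is a hard partition: genes near a threshold flip class
  under small perturbations, which is why validation leans on sweeps and
  sign concordance rather than single cutoffs.
* Upstream DE estimation (and its covariate handling) is an input, not
  part of this package.
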
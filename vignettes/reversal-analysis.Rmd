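---
title: "Quantifying treatment-induced reversal of aging transcriptomic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying treatment-induced reversal of aging transcriptomic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screversal)
```

## The question and the statistic

Brain aging shifts the transcriptome of every major glial and neurovascular
cell type. A systemic treatment "reverses" those shifts when, gene by gene,
its expression effect points in the direction opposite to the aging effect.
`screversal` quantifies this with two summaries computed over the union of
genes significant in either contrast (aging: aged vs young; treatment:
treated vs aged), both at FDR-adjusted q < 0.05:

* the **proportion reversed** — the fraction of union genes whose two
  natural-log fold changes (lnFC) have opposite signs, and
* the **reversal slope** — the ordinary-least-squares slope of the
  treatment lnFC (y) on the aging lnFC (x), with intercept. A slope near
  −1 means near-complete reversal; 0 means no systematic relation; +1
  means the treatment reproduces the aging signature.

Conventions that matter and are easy to get silently wrong:

* lnFC follows the back-transformed-mean form used by the common
  single-cell toolkits: `ln(mean(expm1(y_A)) + 1) − ln(mean(expm1(y_B)) + 1)`
  on log-CP10K values, so it is well defined for genes undetected in one
  group.
* A gene with an lnFC of exactly zero carries no direction and is counted
  as *not* reversed. Zero is rare for estimated fold changes but exact for
  planted truth values; the convention is applied identically in both
  places.
* The regression is of treatment changes on aging changes, unweighted,
  with an intercept. The direction was fixed once (it matches the axis
  convention of the motivating analyses); both directed slopes are reported
  where subtype pairs are compared with each other.
* Genes significant in one contrast but never tested in the other are
  excluded from the union rather than imputed at lnFC 0, which would
  fabricate a direction. The count of exclusions is warned about.

"Top reversed" genes — the input to over-representation analysis — are the
genes ranked within the top `rank_limit` (default 500) by |lnFC| among the
significant genes of *each* contrast separately, with opposite signs. Ties
at the boundary are broken by gene ID so output is deterministic.

## Differential expression: the two-part hurdle model

Sparse UMI expression is modeled per gene in two parts: a logistic
regression for detection (is the value nonzero?) and a Gaussian model for
the positive log-normalized values. The group effect is tested by a
likelihood-ratio chi-square summing both parts; degrees of freedom equal
the number of parts in which the group coefficient is estimable (2
normally; 1 when a gene has no zeros, is detected too rarely — fewer than
3 cells — or is detected in only one group). Genes untestable in both
parts get `NA` p-values and do not count toward the number of
Benjamini–Hochberg tests; setting them to p = 1 instead would deflate the
q-values of real tests.

Two implementation routes coexist and are tested for equality: a
closed-form vectorized route for the plain two-group design (the MLEs are
group-wise detection rates and group means with pooled ML variance), and a
per-gene iterative route used when the cellular detection rate (fraction
of genes detected per cell, centered) is included as a nuisance covariate.
Complete separation in the logistic part is handled by a small ridge
penalty (1e-8) and flagged. The empirical-Bayes variance shrinkage of the
reference hurdle implementation is deliberately omitted — plain maximum
likelihood is used and the cost is paid in verification instead: the test
suite checks the type-I error of the LRT on null negative-binomial data
(2000 genes, ~200 vs ~200 cells) against the 0.035–0.065 band and the
empirical FDR at q < 0.05 with 10% planted effects against 0.07. The
false discovery *proportion* of any single run is highly variable (its
standard deviation at ~190 discoveries is about 0.03), so the FDR is
estimated by pooling ten replicate simulations.

## What the simulator plants, and why the oracle is what it is

`simulate_dataset()` draws counts `NB(mean = L_c * q_gc, size = theta_g)`:
per-gene log-normal dispersions, log-normal library sizes, relative
expression renormalized within each cell so library size is independent of
group (composition effects are isolated on purpose). Each affected cell
type gets a fraction `f_de` of genes an aging effect `delta` (Rademacher
sign times a normal magnitude truncated at zero, natural-log scale); a
fraction `p_rev` of those genes gets a treatment effect `tau = −rho *
delta` exactly, the rest `tau = 0`; optionally a fraction of genes gets
treatment-only effects. Marker genes are elevated by `ln 5` in their own
type; a planted disease-associated signature (default 50 genes) is
up-shifted by 0.5 natural-log units in aged cells of one designated type
and moved back by `rho` times that shift under treatment; a small fraction
of cells has mitochondrial relative expression inflated to an expected
fraction of 0.35, well above the 0.20 QC cutoff. Sample-level log-normal
jitter shared by all cells of one animal emulates mouse-to-mouse variation
with three animals per group.

Defaults were set once as the study conditions: effect magnitudes
(mean 0.8, sd 0.25 on the natural-log scale) are chosen for statistical
power rather than realism — the motivating data's age-related changes are
mostly smaller, but no effect-size distribution is published for them —
and `rho = 0.8`, `p_rev = 0.9` define the recovery condition used
throughout validation, with a second cell type at `rho = 0` as the
non-reversed control.

`expected_reversal()` computes the truth-level oracle: the OLS slope of
`tau` on `delta` and the sign-discordance proportion over genes with any
planted effect, Monte-Carlo averaged over fresh truth draws because the
planted effects are themselves random. Under the defaults the oracle slope
is about `−rho * p_rev ≈ −0.72`, not `−rho`: the non-reversed tenth of DE
genes (with `tau = 0`) dilutes the regression.

One asymmetry between the oracle and the estimate deserves a paragraph,
because it is a property of the statistic and not a bug. At the truth
level a gene with `tau = 0` is not reversed. Its *estimated* treatment
lnFC, however, is symmetric noise around zero, so such a gene — which
enters the union through the aging contrast — is counted reversed about
half the time. The estimated proportion therefore converges not to the
oracle proportion `p0` but to roughly `p0 + (1 − p0)/2`, and at `rho = 0`
(all `tau = 0`) to about one half, not zero. The package's validation
compares the estimated slope against the oracle slope directly (estimation
noise in lnFC only attenuates it slightly at the default power), and the
estimated proportion against the noise-aware expectation within a binomial
confidence interval. When interpreting real data, the same logic applies:
a proportion reversed near 0.5 is what pure noise produces over a union of
genuinely age-affected genes, and the regression slope is the more
trustworthy summary.

## Preprocessing, clustering and cell-type assignment

Quality control follows a fixed order and is applied once: genes detected
in fewer than 5 cells are removed from the raw matrix; cells are then
removed if their total UMI or detected-gene count falls strictly below the
5th or strictly above the 95th percentile (type-7 linear interpolation,
computed over all cells jointly) or if their mitochondrial fraction
(case-insensitive gene-ID prefix `mt-`) exceeds 0.20. Strict percentile
filtering is not idempotent if recomputed on the filtered set — removing
the tails moves the percentiles inward — which is why the pipeline never
re-applies it.

Normalization for differential expression and scoring is log-CP10K; a
simplified Pearson-residual normalization (per-gene Poisson regression on
log10 library size, method-of-moments dispersion pooled by bin-median
smoothing over gene-mean bins, residuals clipped at ±sqrt(n_cells)) is
available as an alternative for embedding. High-variance genes are
selected by a variance-stabilizing criterion: a loess trend (span 0.3) of
log10 variance on log10 mean, counts standardized by the trend-predicted
sd, clipped at sqrt(n_cells), ranked by the variance of the clipped
values with ties broken by gene ID. PCA (default 30 components) uses an
exact SVD of the centered, unit-scaled (clipped at ±10) HVG submatrix
with the sign convention that each component's largest-magnitude loading
is positive. The SNN graph uses k = 20 Euclidean neighbors in PC space
(self included), Jaccard edge weights, pruning below 1/15; clustering is
seeded multi-level (Louvain) modularity optimization at resolution 1.4.

Cluster labels are mapped to cell types by marker z-scores: each marker
gene is z-scored across all cells, averaged within marker sets per cell
and then per cluster; a cluster is assigned the argmax set if its score
exceeds 0.5 and is excluded when two or more sets exceed the threshold
(the pericyte-contaminated-by-endothelial-fragments situation) or when
none does. The 0.5 threshold is a package choice — no number is published
for "high expression" — and it separates the planted markers cleanly.
Because z-scores need between-type contrast, a dataset containing a
single cell type cannot be assigned this way; the pipeline expects
multi-type input, which is the setting the method was built for.

## Signature scores and group comparison

`module_score()` implements binned-control scoring: genes are binned into
24 equal-size bins by mean expression over all cells (ties by gene ID);
each signature gene draws 100 control genes uniformly from its bin,
seeded, without replacement where the bin allows. Signature genes are
excluded from the control pool — this makes the score exactly linear in
shifts of the signature genes, at the cost of a negligible change in the
control distribution. The cell's score is the mean expression of the
signature genes minus the mean of the pooled, deduplicated controls.
Scores are compared across groups with the tie-corrected Kruskal–Wallis
test (all values tied is defined as H = 0, p = 1) and post hoc Dunn
z-tests, unadjusted by default with optional Holm adjustment, since the
motivating analyses report unadjusted pairwise p-values.

Over-representation of the top reversed genes is the one-sided
hypergeometric tail, computed in log space, BH-adjusted across sets. The
background universe is the set of genes tested in the relevant contrast,
not the whole genome: enrichment against an inflated universe is the most
common way to manufacture significance in ORA.

## Numerical choices and degenerate inputs

* Percentiles: type 7 (linear interpolation); removal inequalities are
  strict, so a dataset of identical cells loses nothing.
* All-zero cells are flagged by QC and removed unconditionally;
  `lognormalize()` refuses zero-total cells rather than dividing by zero.
* `hurdle_lrt` chi-squares are floored at 0 (they are nonnegative in exact
  arithmetic); a continuous part with zero residual variance is treated as
  untestable rather than producing an infinite statistic.
* Ties are always broken by gene ID (HVG ranking, fold-change ranking,
  expression binning) so every output is reproducible byte for byte; the
  pipeline derives per-stage seeds deterministically from one master seed.
* Degenerate requests fail loudly: empty unions, empty groups, unknown
  configuration keys, marker sets absent from the matrix.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on simulated data:
recovery experiments use 1500 genes, two cell types and 40 cells per
animal per type (≈360 cells per group per type) across 20 seeds;
calibration uses 2000 genes with ~200 vs ~200 cells; signature ordering
uses 800 genes and 50 signature genes across 20 seeds; the demo pipeline
uses 1500 genes and 720 cells. These sizes were chosen so the planted
effects are recoverable with comfortable power while the full validation
completes quickly on a laptop.

## Known limitations

* No random-effect (per-animal) hurdle model and no pseudobulk path: with
  three animals per group, animal-level variance is absorbed by the
  sample-jitter term in simulation but not modeled in inference, exactly
  as in the reference workflow.
* The simulator does not emulate ambient RNA, chemistry batch effects,
  doublet kinetics or spatial structure; passing tests demonstrate
  recovery of planted structure under the stated generative model, not
  robustness to artifacts the model lacks.
* The Pearson-residual normalization is a simplified stand-in for full
  kernel-regularized NB regression and is not used for fold changes.
* Marker-based assignment replaces probabilistic reference-based
  assignment; subtype analyses reuse the same machinery on cell-type
  subsets with subtype marker sets.
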
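---
title: "Survival-based gene set enrichment: models, parameters and design choices"
author: "survGSEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival-based gene set enrichment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survGSEA)
```

# The problem

Functional enrichment analysis usually asks which biological pathways
differ between two experimental groups. A different, clinically central
question is which pathways are associated with a *censored outcome* —
typically overall survival in a tumor cohort where every sample is a case
and many patients are still alive at last follow-up. survGSEA answers that
question by replacing the usual log fold change with a per-gene **Cox log
hazard ratio** as the gene-ranking statistic and then running a standard
weighted gene set enrichment test on that ranking.

# The model

## Per-gene Cox ranking

For gene $i$ with normalized expression $x_i$, the hazard of death at time
$t$ is modeled as

$$h(t \mid x_i) = h_0(t)\, e^{\beta_i x_i},$$

so $\beta_i$ is the log hazard ratio for a one-unit increase in $x_i$. The
baseline hazard $h_0$ is left unspecified and profiled out by the partial
likelihood; censored samples contribute through their risk-set membership
only. Each gene is fit marginally (optionally with a shared covariate
block), and genes are ranked by $\hat\beta_i$ in decreasing order: the top
of the list is most associated with mortality, the bottom with survival.

The fitter is a Newton–Raphson maximizer of the Efron-corrected (default)
or Breslow-corrected partial log-likelihood, with step-halving,
convergence when the relative log-likelihood change drops below `tol =
1e-9`, and a cap of 25 iterations. Fits that do not converge, or that
wander past $|\beta| = 15$ (quasi-separation, e.g. when the single
uncensored extreme sample carries the whole likelihood), are **excluded**
from the ranking rather than clipped: a clipped $\pm 15$ would dominate
the list extremes and distort every downstream enrichment score. The
exclusion fraction is reported. Constant expression vectors carry no
likelihood information and are flagged non-informative.

Ties in $\hat\beta$ are broken lexicographically by gene identifier, so a
ranking is a deterministic function of its inputs.

## Normalization

Counts are filtered (a gene must average at least `minMean = 0.1` reads
per sample — i.e. one read per ten samples; the bound itself is kept) and
converted to log2 counts per million with the voom offsets,

$$x_{gi} = \log_2\!\frac{(c_{gi} + 0.5)\,10^6}{\mathrm{lib}_i + 1},$$

via `limma::voom`. The voom mean–variance precision weights are computed
and stored, but the Cox stage consumes only the log-CPM values: nothing in
the ranking model requires precision-weighted partial likelihoods, and the
unweighted fit is the defensible default. The weights are available for
sensitivity analysis.

## The enrichment statistic

Given a ranked list of $N$ genes and a pathway with $N_h$ members in the
universe, the running sum advances by $|s|^p / \sum_{\text{hits}} |s|^p$
at each hit and retreats by $1/(N - N_h)$ at each miss ($p = 1$, the
classic weighted statistic; exposed as `exponent`). Both cumulative
distributions end at 1, so the walk ends at 0 and the enrichment score
(ES) — the extremum of largest absolute value — lies in $[-1, 1]$. An
exact tie between the positive and negative extremum resolves to the
positive one; the comparison uses a $10^{-12}$ tolerance so that
mathematical ties cannot flip sign on floating-point rounding. The leading
edge is the set of hits at or before the positive peak (ES > 0) or at or
after the negative trough (ES < 0).

## Null model, NES and p-values

The ranking is preranked by construction, so the null model samples gene
sets of the observed size uniformly from the ranked universe
(gene-sampling null); one null sample is shared across all same-size
pathways in a run, and all draws are seeded. The normalized enrichment
score divides the observed ES by the mean $|ES|$ of same-sign null draws,
and the p-value is the add-one-corrected same-sign exceedance proportion,
always in $(0, 1]$.

Permutation precision is adaptive: every pathway starts at `nperm = 1000`
draws and any pathway with $p < 10/\text{nperm}$ is re-evaluated at
tenfold more, up to `npermMax` (default $10^6$), so small p-values are
resolved without spending large budgets on null pathways. The reported
`log2err` is the Monte-Carlo standard error of $\log_2 p$ implied by the
permutation count, $\sqrt{(1-p)/(p\,n)}/\ln 2$; it is **not** comparable
to the split-sample error estimate that multilevel implementations report.
Benjamini–Hochberg adjustment runs across all tested pathways, and the
package-wide default significance level is `alpha = 0.15`, the
conventional threshold for enrichment screens of this kind.

Pathway size bounds default to `minSize = 3` and `maxSize = 500` after
intersection with the ranked universe; real collections contain
informative pathways with fewer than ten members, so the lower bound is
deliberately permissive.

## The fold-change mode

For matched case-control designs the same engine runs on a log2
fold-change ranking. Counts are scaled by median-of-ratios size factors,
per-gene negative binomial dispersions are estimated by a
method-of-moments start refined with a per-gene likelihood step (floored
at $10^{-8}$), and fold changes come from an NB Wald GLM (log link,
intercept + condition, log size-factor offsets, optional pair-indicator
block). There is deliberately no dispersion shrinkage toward a trend and
no fold-change shrinkage: the fold changes serve as an enrichment ranking,
not as publication-grade effect estimates, and parity with heavier
differential-expression machinery is a non-goal. Genes with all-zero
counts in one condition get a 0.5 pseudo-mean fallback and are flagged.

## The FDR audit

To check that the whole pipeline controls its false discovery rate, the
audit shuffles the per-sample `(time, status)` **pairs** jointly across
samples B times (default 100), breaking the expression–outcome association
while preserving the survival marginal exactly — shuffling time and status
independently would fabricate censoring patterns no cohort can produce —
and reruns the full pipeline each time. A pathway's estimated FDR is the
fraction of replicates with padj below alpha. Within the audit the
permutation count is fixed (not adaptive): resolving p-values far below
alpha is wasted work when only the alpha threshold matters.

# The synthetic-data generator

Every stage is testable offline against
`simulateSurvivalDataset()` / `simulateCaseControlDataset()`, which
emulate a TCGA-like renal carcinoma cohort:

* **Counts**: negative binomial, gene means log-normal (median 50 reads,
  log-sd 1.5 — a typical bulk RNA-seq spread), common dispersion 0.3,
  mild log-normal library-size variation (sd 0.2). These values were
  chosen once as realistic and are not tuned.
* **Survival**: exponential baseline hazard; each sample's hazard is
  multiplied by $\exp(\sum_g \beta_g z_{gi})$ where $z$ is the per-gene
  *standardized* log-CPM, so `effect_beta` reads as a log hazard ratio per
  SD of normalized expression. A constant baseline is the simplest model
  consistent with a proportional-hazards generative story that makes no
  assumption about the hazard's time profile.
* **Censoring**: independent uniform, with the upper bound solved
  numerically so the realized censoring fraction hits the target; the
  default 0.69 mirrors a cohort with roughly 360 of 520 subjects censored.
* **Pathways**: planted signal sets contain exactly the signal genes;
  the remaining sets are uniform draws from the gene universe.

What the generator does **not** emulate: gene–gene correlation (real
pathways are co-expressed even under the null, which inflates enrichment
variance), batch effects, varying per-gene dispersions, non-proportional
hazards, and informative censoring. Tests passing on this generator
therefore certify the machinery — estimator consistency, null calibration,
FDR control under exchangeable outcomes — not robustness to those
real-data pathologies.

# Numerical and design choices

* **Parameter recovery is assessed gene-wise.** The hazard model above is
  marginal per gene. In a recovery experiment where 200 genes carry
  simultaneous independent effects of variance 0.25 in one cohort, each
  marginal fit omits the other genes' contribution to the linear predictor
  (variance $\approx 50$), and the non-collapsibility of the Cox model
  attenuates the fitted coefficients to a slope far below 1 — a property
  of marginal fitting, not an estimator defect. The recovery contract is
  therefore evaluated over 200 cohorts each carrying a single signal gene
  (n = 300 each), where the marginal model is correctly specified; the
  slope of $\hat\beta$ (rescaled to per-SD units) on $\beta_{true}$ then
  sits within $[0.9, 1.1]$.
* **Orientation auto-detection** for count files prefers the axis whose
  labels overlap the survival table's sample ids and refuses to guess on a
  tie — silent transposition is the classic failure mode for this format.
* **Status recoding** accepts 0/1, TRUE/FALSE and case-insensitive
  alive/dead; anything else errors. Rows with non-positive or missing
  follow-up time are dropped with a count.
* **Degenerate enrichment inputs**: a gene set covering the whole universe
  has no defined miss increment and errors; a set whose members all carry
  zero-valued statistics falls back to equal hit weights.
* **Determinism**: every stochastic stage (null sampling, adaptive
  escalation, outcome shuffles, generators) derives its streams from the
  user seed; identical seeds and inputs give bit-identical tables.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run, by choice, at desk scale:
the exhaustive ES oracle on a 10-gene universe (1022 subsets), the Cox
grid-search oracle on 8-sample cohorts, null calibration with 2000 genes
and 100 pathways at n = 300, the FDR audit with 600 genes, 100 pathways
and B = 50 at n = 150, and the planted-pathway power study with 1020 genes
at n = 300 over 100 seeds (20 seeds in the test suite's smoke variant).

# A worked example

```{r example, eval = FALSE}
sim <- simulateSurvivalDataset(n_samples = 120, n_genes = 300,
                               n_pathways = 10, pathway_size = 15,
                               effect_beta = 0.8, seed = 11)
se <- SurvivalExperiment(sim$counts, sim$survival)
se <- filterLowExpression(se)
nm <- logcpmVoom(se)
ranked <- rankByLhr(nm, survTime(se), survStatus(se))
res <- runEnrichment(ranked, sim$pathways, seed = 3)
significant(res)
topTables(res)
plotEnrichment(ranked, sim$pathways[[1]], title = names(sim$pathways)[1])
```

Or, end to end with files on disk (also available from the shell through
the `survgsea` script in `inst/scripts/`):

```{r pipeline, eval = FALSE}
runSGSEA("counts.csv", "survival.csv", "pathways.gmt",
         outDir = "sgsea_out", seed = 1)
```

# Known limitations

* Proportional-hazards assumption checks are deliberately omitted: the
  pipeline fits thousands of marginal models and uses their coefficients
  as a ranking, not for per-gene inference; a permutation-based audit of
  the end result replaces per-model diagnostics.
* The gene-sampling null treats genes as exchangeable; co-expression
  within real pathways makes this null anti-conservative to an extent the
  synthetic tests cannot measure.
* Fold-change mode is a plain NB Wald GLM; strongly outlying counts or
  very small groups deserve a dedicated differential-expression package.
* `log2err` is a Monte-Carlo quantity tied to the permutation count, not
  an algorithmic error bound.
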
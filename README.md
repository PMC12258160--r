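# survGSEA — survival-based gene set enrichment analysis

Most enrichment tools ask which pathways differ between two experimental
groups. For many diseases the more pressing question is which pathways are
associated with a **censored clinical outcome** — overall survival in a
tumor cohort, where every sample is a case and a large fraction of
patients are alive at last follow-up. survGSEA answers that question for
bulk or pseudobulk RNA-seq: it fits one Cox proportional-hazards model per
gene on normalized expression,

    h(t | x_i) = h0(t) · exp(β_i · x_i),

ranks all genes by the fitted log hazard ratio β̂ (top = associated with
mortality, bottom = with survival), and tests gene sets for concentration
at the extremes of that ranking with a weighted Kolmogorov–Smirnov-like
running-sum statistic, calibrated by a seeded gene-sampling permutation
null with adaptive precision. Benjamini–Hochberg adjustment is applied
across pathways and the conventional `padj < 0.15` screen flags
significant ones.

The package is for translational genomics researchers and biostatisticians
with a count matrix, per-sample time-to-event data and a GMT pathway
collection. It also provides:

* a standard fold-change mode (negative binomial Wald GLM between two
  conditions, optionally paired) that feeds the same enrichment engine,
* an outcome-permutation **FDR audit** — shuffle the (time, status) pairs
  across samples B times, rerun the whole pipeline, and report how often
  each pathway is falsely called significant,
* a significance-partition comparison between a survival-based and a
  fold-change-based run (Venn counts),
* top-pathway tables and enrichment-plot data/figures,
* a synthetic-data generator emulating a TCGA-like renal carcinoma cohort
  (NB counts, proportional-hazards survival, ~69% censoring, planted
  pathways), so the full pipeline is testable offline,
* a command-line front end (`inst/scripts/survgsea`) with `sgsea`,
  `gsea`, `audit-fdr`, `compare`, `simulate` and `plot` subcommands.

## Worked example

```r
library(survGSEA)

sim <- simulateSurvivalDataset(n_samples = 120, n_genes = 300,
                               n_pathways = 10, pathway_size = 15,
                               effect_beta = 0.8, seed = 11)
se     <- SurvivalExperiment(sim$counts, sim$survival)
se     <- filterLowExpression(se)          # mean >= 0.1 reads/sample
nm     <- logcpmVoom(se)                   # voom log2-CPM (+ weights)
ranked <- rankByLhr(nm, survTime(se), survStatus(se))
ranked
#> CoxRankedList of 300 genes (mode: lhr, 0 excluded)
#>   top:    g00256=1.15, g00036=0.756, g00067=0.685
#>   bottom: g00148=-0.401, g00158=-0.623, g00196=-0.624

res <- runEnrichment(ranked, sim$pathways, seed = 3)
res
#> EnrichmentResults: 10 pathways, 1 significant at padj < 0.15
#>   pathway     pval     padj   NES size
#> 1  PW_001 2.94e-05 0.000294  1.95   15
#> 2  PW_006 7.24e-02 0.362000  1.38   15
#> ...
```

Reading the output: gene `g00256`'s expression carries a log hazard ratio
of 1.15 per log2-CPM unit (higher expression, higher mortality risk).
Pathway `PW_001` — the planted hazard-associated set in this simulation —
has enrichment score 0.80 and normalized enrichment score 1.95: its genes
concentrate at the mortality end of the ranking, with permutation p-value
2.9e-05 (resolved by adaptive escalation to 10^4 draws) and padj 2.9e-04,
far below the 0.15 screen. A negative NES would indicate association with
better survival. `topTables(res)` extracts the top-10 tables per
direction and `plotEnrichment(ranked, sim$pathways[["PW_001"]])` draws the
running-sum figure.

The same analysis runs from files on disk (counts CSV in either
orientation, survival CSV, GMT):

```sh
inst/scripts/survgsea sgsea --counts counts.csv --survival survival.csv \
    --gmt pathways.gmt --out sgsea_out --seed 1
```

Every output directory contains a `config.json` with the resolved
parameters and seed sufficient to regenerate it exactly.

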
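# pathmarker

Pathway-gene biomarker discovery from joint preclinical and clinical
expression screens.

## The problem

Regressions trained to predict drug sensitivity (IC50) from baseline tumor
cell-line expression routinely fail to predict the clinical outcome
(progression-free survival, "months to progression") of patients treated
with the same drug. `pathmarker` is for computational biologists who want
to mine a cell-line panel *and* a treated patient cohort together: it
screens very many small random expression models and keeps only the ones
that jointly predict both datasets, then organizes the recurring genes into
pathways and distills a compact biomarker panel.

## The method

For each of many random draws of $n_c$ tumor cells and $n_g$ genes
(defaults 30 and 300), a linear ridge regression of IC50 on unscaled
expression is fitted,

$$\hat\beta = \arg\min_\beta\; \|y - b_0 - X\beta\|^2 + \lambda\|\beta\|^2 ,$$

with $\lambda$ chosen per draw from the principal components of the
training subset ($\lambda = k\hat\sigma^2 / \sum_{j\le k}\hat\alpha_j^2$,
$k$ components covering 90% of the design variance). A draw survives the
**dual filter** only if the natural-log p-values of two Pearson
correlations — in-sample predicted IC50 vs per-cell mean model-gene
expression ($\ln p_{\mathrm{IC50}} < -11$), and predicted patient
chemosensitivity vs months to progression ($\ln p_{\mathrm{clinical}} <
-6$) — beat their thresholds, the mean-threshold ppv/npv of the patient
scores reach 0.45, and both predictions span at least 80% of the relevant
observed range.

Genes recurring across accepted models are tested for gene-set overlap
enrichment (hypergeometric, BH FDR ≤ 0.05, sets sharing ≥ 2 genes). Each
pathway gets a signed **fitness score** $H$: the tie-corrected
Kruskal–Wallis statistic comparing per-gene clinical response statistics
(Welch t between the upper/lower 20% PFS tails) of in-pathway vs
out-of-pathway genes, positive when pathway genes are over-expressed in
responders, zero below 5 scored genes. Leave-one-out deltas
$\Delta_g = H - H_{-g}$, averaged over pathways, rank individual genes; the
panel keeps genes with response $p < 0.2$ and $\Delta$ in the upper/lower
40th percentiles. The panel is evaluated with random forests (optimized
responder/non-responder split, out-of-bag class errors, AUC vs 0.5 over 50
seeds), SVD impact values, and a fitting-free pooled t-statistic
per-patient classifier built from the positive- and negative-fitness gene
pools. A synthetic-data generator with a planted driver signature makes the
whole pipeline testable offline.

## Worked example

Run the bundled end-to-end pipeline on synthetic data (about 15 s):

```r
library(pathmarker)
cfg <- list(out_dir = "demo_out",
            synthetic = list(seed = 7),
            campaign = list(n_samples = 6000, ln_pval_ic50_max = -6,
                            ln_pval_clinical_max = -4, seed = 5),
            aggregate = list(min_models = "auto"),
            evaluate = list(n_trees = 200, n_seeds = 10))
res <- run_pipeline(cfg)
```

which logs:

```
[pipeline] generating synthetic dataset
[pipeline] sampling campaign: 6000 draws
[pipeline] 140 accepted models
[pipeline] auto min_models = 31
[pipeline] 47 candidate genes (>=2 models); mean-prediction r = -0.942
[pipeline] 4 enriched pathways (q <= 0.05)
[pipeline] 3 pathways with nonzero H
[pipeline] 9 panel genes
[pipeline] RF split k = 14; responder error 16.0%, AUC 0.96
```

Reading the numbers: 140 of 6000 random 30-cell × 300-gene ridge models
passed the dual filter; the average of their patient predictions correlates
at r = −0.94 with months to progression (negative because a lower predicted
IC50-scale score means a more drug-sensitive, longer-surviving patient).
The 47 most frequently selected genes are enriched in 4 gene sets — all of
them pathways the generator planted with driver genes — and the 9-gene
panel distilled from their fitness contributions classifies responders with
16% out-of-bag error and AUC 0.96. Stage outputs (`models.jsonl`,
`enrichment.tsv`, `fitness.tsv`, `panel.tsv`, `network.sif`, ...) are
written under `demo_out/`; a rerun with the same config and seed is
byte-identical.

A thin command-line wrapper is available at
`inst/scripts/pathmarker-cli.R` (`simulate`, `campaign`, `pipeline`
subcommands).

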
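---
title: "Methods: screening ridge models for pathway-gene biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening ridge models for pathway-gene biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A drug's preclinical signature — the association between baseline gene
expression and IC50 across a tumor cell-line panel — rarely transfers
directly to the clinic. A regression trained to predict IC50 from cell-line
expression can fit the preclinical data excellently and still predict the
progression-free survival (PFS, months to progression) of treated patients
no better than chance. `pathmarker` implements a screening strategy that
confronts this head-on: instead of fitting one model and hoping it
transfers, it samples an enormous number of small random models and keeps
only those that *jointly* predict the preclinical and the clinical data.
The genes recurring in the surviving models, organized into pathways, are
the biomarker candidates.

# The screening model

Each draw selects $n_c$ tumor cells (default 30) and $n_g$ genes
(default 300) uniformly at random and fits a linear ridge regression of
IC50 on the unscaled expressions of those genes:

$$\hat\beta = \arg\min_\beta \|y - b_0 - X\beta\|^2 + \lambda\|\beta\|^2,$$

with the intercept unpenalized. Because $n_g \gg n_c$, the solve uses the
kernel (dual) form $\beta = X_c'(X_cX_c' + \lambda I)^{-1}y_c$, which is
algebraically identical to the primal solution and costs $O(n_c^3)$ rather
than $O(n_g^3)$ per draw. The penalty $\lambda$ is chosen per model from the
training subset alone, by principal-component regression: with
$\hat\alpha_j$ the regression coefficients of the response on the normalized
components, $k$ the number of components reaching 90% of the design
variance, and $\hat\sigma^2$ the residual variance of the $k$-component fit,

$$\lambda = \frac{k\,\hat\sigma^2}{\sum_{j\le k}\hat\alpha_j^2}.$$

$\lambda$ is invariant to rescaling the response and tends to zero as the
response becomes noiseless.

## Dual filtering

Each fitted model is scored on both sides:

* **Preclinical**: Pearson correlation of the in-sample predicted IC50
  against the per-cell mean expression of the model's genes; its two-sided
  p-value is `pval_IC50`.
* **Clinical**: the model's coefficients applied to each patient's baseline
  expression give a predicted chemosensitivity score (on the IC50 scale);
  its Pearson correlation with months to progression gives `pval_clinical`.

A model is accepted only if (defaults in parentheses):

1. $\ln p_{\mathrm{IC50}}$ is below its threshold ($-11$);
2. $\ln p_{\mathrm{clinical}}$ is below its threshold ($-6$);
3. the positive and negative predictive values of the mean-threshold
   dichotomization of the patient scores against the mean-dichotomized
   observed response both reach their minima ($0.45$) — predicted responders
   are patients below the mean score (lower IC50-scale score = more
   sensitive), observed responders are patients above the mean PFS;
4. the range of the in-sample predicted IC50 reaches 80% of the observed
   IC50 range over the model's cells, and the range of the patient scores
   reaches 80% of the in-sample predicted range.

All p-values are natural logs; $\ln p$ is floored at $-745$ (the smallest
representable double) so perfect correlations do not produce $-\infty$.
Thresholds are printed-convention choices of the screen, not fitted
quantities; the ppv/npv thresholds are applied as minima, since accepted
models are the *good* classifiers. The clinical range rule compares patient
scores to the in-sample predicted IC50 because both live on the IC50 scale;
the observed PFS is in months and not comparable. Cross-validation within a
draw is deliberately omitted: the screen's selection already uses the
clinical data, and the output is explicitly a *discovery* set, not a
validated predictor.

## Aggregation

Accepted models are aggregated three ways: the element-wise mean of their
patient predictions (whose correlation with PFS summarizes the screen),
per-gene appearance counts (candidate genes = genes in at least
`min_models` accepted models; the pipeline also offers `"auto"`, the upper
97.5% tail of a Poisson with the observed selection density, which matters
when the accepted set is large relative to the gene universe), and Fisher
exact enrichment of the accepted models for cell identities or tissue types
over (cell, model) selection slots.

# Pathway scoring

Candidate genes are tested for overlap enrichment against a gene-set
collection (hypergeometric upper tail over the shared universe, sets with
fewer than 2 shared genes excluded, Benjamini-Hochberg control at
$q \le 0.05$). For interpretation, the pathway $\times$ gene membership
matrix is clustered in both dimensions (Minkowski distance, exponent 2 by
default, Ward linkage) and meta-clusters are read off the row dendrogram.

## The fitness score H

Each gene receives a clinical response statistic: by default the Welch
t-statistic comparing its expression between the upper and lower 20% tails
of PFS (responders minus non-responders), alternatively the Pearson
correlation with PFS — both modes are kept because either is defensible and
they agree in sign on informative genes. A pathway's fitness is the
tie-corrected two-group Kruskal-Wallis statistic comparing the ranks of the
in-pathway statistics against all out-of-pathway statistics, signed
positive when the in-pathway mean statistic is larger (pathway genes
over-expressed in responders), negative otherwise. A pathway scoring fewer
than 5 genes gets $H = 0$: below that the rank statistic is too unstable to
interpret. The out-group is the full scored gene set passed in, not only
enriched genes, so $H$ measures the pathway against its actual background.

Gene contributions are leave-one-out: $\Delta_g = H - H_{-g}$, recomputed
with the gene removed from the scored set, averaged over all supplied
pathways containing the gene. Only genes with a modest individual response
association ($p \le 0.2$) are reported — a weakly associated gene can still
move $H$, but is not an interpretable biomarker.

# The biomarker panel and its evaluation

Panel genes are those with response $p < 0.2$ whose $\Delta$(fitness) falls
in the upper or lower 40th percentile of the whole set of $\Delta$ scores
(a per-tail reading of the percentile rule fails the score's own worked
arithmetic; the whole-set reading is used). Genes are routed into a
positive or negative pool by the sign of the summed fitness of their
contributing pathways.

Evaluation uses random forests (500 trees): patients are ordered by PFS,
the responder class size $k$ is chosen by minimizing the unweighted mean of
the two out-of-bag class errors over candidate splits (averaged over
seeds), and the chosen split is evaluated over 50 seeded forests with
stratified 70/15/15 sample/validation/test partitions: per-class errors
from the out-of-bag votes (holdout errors are available as an option), AUC
from class-probability votes on the test partition, and a one-sample t-test
of the AUC list against 0.5. When every seed returns the identical AUC the
t-test is degenerate; the reported p is 0 if that constant differs from 0.5
and NA otherwise. Subsample sensitivity repeats the evaluation on stratified
subsamples of decreasing size. SVD impact values summarize each gene's
share of the panel's expression variance over the components covering 90%
of it (the cutoff is a parameter; "impact" has no canonical formula, this
is a declared one).

Finally, the pooled t-statistic classifier needs no fitting at all: for
each patient it is the Welch t comparing the patient's negative-pool
expressions to the positive-pool expressions; its correlation with PFS
summarizes how well the two pools alone separate outcomes. The network
export writes cliques over the genes of pathways in the upper and lower
20th percentile tails of the signed $H$, edges weighted by $H$,
deduplicated keeping the largest-|H| provenance, in SIF or GraphML.

# The synthetic study conditions

The generator plants exactly the structure the screen is designed to
detect, and nothing else:

* Expressions are marginally standard normal. A signature of 30 driver
  genes (half positive, half negative weights, magnitudes
  $U(0.5, 1.5)/\sqrt{30}$) shares a per-sample latent factor with
  correlation $\rho = 0.4$ — a co-regulated driver program, and the reason
  individual signature genes are detectable by marginal correlation.
* Every other gene carries a weak loading (0.02) on the same factor,
  emulating the global expression programs of real transcriptome data.
  Without it, the per-cell mean expression of 300 random genes is pure
  noise and the preclinical filter could never fire; the value is set so a
  typical model's mean-expression correlation with the driver is moderate
  ($r \approx 0.3$ at 30 cells), making the $-11$ screening threshold rare
  and the $-6$ relaxed threshold reachable.
* IC50 is the weighted signature sum plus Gaussian noise (sd 0.5);
  months to progression is $12 - 1.5 \times$ the same sum plus noise, so
  predicted chemosensitivity anti-correlates with survival.
* The clinical platform is scaled by a factor 3 relative to the
  preclinical one, applied after the response link so every correlation and
  rank statistic is unchanged. This mirrors unscaled cross-platform data
  and is what makes the clinical-side 80% range rule satisfiable: honest
  out-of-sample ridge predictions shrink to roughly a third of the
  in-sample spread (we measured a median ratio of 0.33), so on a common
  scale the rule would reject every model.
* Gene sets are random; six planted pathways each contain 10 signature
  genes of a single sign (a pathway representing the driver program), the
  rest fillers. Mixed-sign pathways would have self-cancelling rank shifts
  and near-zero $H$ by construction.
* Tissue labels are uniform and independent of response by default, with
  an option biasing sensitive cells toward one tissue to exercise the
  Fisher enrichment under the alternative.

Defaults are 2000 genes, 120 cells, 30 patients, effect size 1.5 — large
enough for the planted signal to be recoverable, small enough that a
10,000-draw campaign, the fitness scan and the forest evaluation run in
minutes. What passing tests on these data show is that the machinery
recovers a linear, shared, block-correlated signal under Gaussian noise;
they say nothing about probe effects, batch structure, nonlinear dose
response, censoring of progression times, or misannotated gene sets, none
of which the generator attempts to mimic.

# Numerical and design notes

* Determinism: every stochastic stage takes a seed; the campaign is a
  single sequential RNG stream, so identical configurations are
  byte-identical on rerun (the pipeline writes no timestamps into stage
  outputs). Checkpoint files store the draw counter and RNG state as JSON.
* Ties in the Kruskal-Wallis statistic get average ranks and the standard
  tie correction; clustering uses `stats::hclust(method = "ward.D2")`
  (Ward on distances), whose tie behavior is inherited.
* Degenerate inputs fail loudly: constant vectors in correlations, empty
  predicted classes in ppv/npv, all-constant feature matrices in the
  forests (a case the underlying forest implementation does not terminate
  on), zero-variance matrices in the SVD. A model with any undefined
  statistic simply fails the dual filter.
* The Fisher enrichment 2x2 table is built over (cell, model) selection
  slots — selections of label cells vs others, against unselected slots —
  which uses all selection information and reduces to a per-cell binomial
  test asymptotically.
* `gene_set_collection()` intersects sets with the universe eagerly and
  reports drops, so enrichment margins are always consistent.

# Known limitations

* The screen's acceptance rate depends strongly on the two-sided p-value
  thresholds; there is no internal FDR control over draws (the null
  calibration is the permuted-response campaign instead).
* Candidate-gene frequency selection loses selectivity when many models
  are accepted over a small gene universe (counts saturate); the `"auto"`
  slice mitigates but does not remove this.
* Months to progression is treated as a plain scalar: no censoring, no
  survival model.
* The pooled-t classifier assumes both pools are non-empty and reasonably
  sized; a study where all discovered pathways share one fitness sign
  yields no classifier (the pipeline reports and skips).
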
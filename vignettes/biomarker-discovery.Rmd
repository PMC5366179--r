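---
title: "Multi-class biomarker discovery with cedeg: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-class biomarker discovery with cedeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cedeg)
```

## The problem

Large multi-centre expression cohorts — the motivating case is a leukaemia
bone-marrow study with 2096 samples across 18 diagnostic subtypes prepared in
11 laboratories — pose two problems that two-class differential-expression
machinery does not address. First, non-biological variation tied to the
preparation centre (the *batch effect*) can dwarf disease signal and must be
removed without erasing class differences. Second, with many classes the
notion of "differentially expressed" splinters: a gene may separate one class
from some others but not all, so a single p-value per gene is not an answer.

`cedeg` implements a complete pipeline for this setting. Its central objects
are:

* **CE-DEG** (class-enhanced differentially expressed gene) for class $c$: a
  gene whose adjusted pairwise post-hoc p-value is below $\alpha$ for *every*
  pair $(c, c')$, $c' \ne c$. A gene may be a CE-DEG for several classes.
* **Biomarker** for class $c$: a CE-DEG for $c$ that additionally shows *no*
  significant difference between any pair of the remaining classes. Biomarker
  sets are therefore disjoint across classes by construction.

A definitional subtlety: "differentiates a class from all the others" can be
read pairwise (significant against each other class separately) or pooled
(significant against the union of the other classes). The pairwise reading is
what the post-hoc machinery actually tests and is what `ce_deg_sets()`
implements; the pooled one-vs-rest reading is strictly weaker for unbalanced
classes (a huge class dominates the pooled mean) and is not offered as a
biomarker definition here.

## Pipeline stages and their assumptions

### Preprocessing (`background_correct`, `quantile_normalize`, `summarize_median_polish`)

The preprocessing core is the RMA decomposition: linear-scale intensities are
modelled as exponential signal plus Gaussian noise, corrected to the posterior
expected signal; arrays are quantile-normalised to a common distribution; and
probe-level values are summarised per gene by Tukey median polish (row/column
median sweeps, tolerance $10^{-6}$, at most 20 iterations; the gene summary is
the overall effect plus the per-sample column effect). The normal+exponential
parameters are estimated per array by saddle-point maximum likelihood, which
on simulated data recovers the true signal mean to well under 5% — the ad hoc
moment rules (density mode plus tail moments) were measurably biased and are
used only conceptually to describe the model. Frozen-parameter variants of
RMA need externally estimated probe vectors; this package instead estimates
everything from the cohort at hand, which is the honest equivalent when no
frozen reference is available. Pipelines starting from already-summarised
matrices skip this module entirely.

### Batch adjustment (`combat_adjust`, with `pca_diagnostic`, `kw_batch_test`, `twoway_anova_screen`)

Batch correction uses the parametric empirical-Bayes location/scale model
(ComBat): gene-wise least squares with batch indicators and the biological
class as a protected covariate, standardisation, per-batch per-gene
location/scale estimates shrunk toward moment-matched batch-level priors
(normal for location, inverse-gamma for scale), then removal of the shrunk
effects. Class is always passed as a covariate so class-mean differences are
preserved in expectation; batches confounded with class are rejected with an
error naming the offending levels, and single-sample batches are errors.

Verification is built in: PCA score plots before/after, a per-gene
Kruskal–Wallis test against batch, and a per-gene two-way ANOVA
(batch × subtype with interaction, Type-II sums of squares — the design is
heavily unbalanced, and Type II tests each main effect adjusted for the other
without letting the imbalance redistribute explained variance). One point
deserves emphasis because it affects how the verification numbers should be
read: after empirical-Bayes adjustment the *estimated* batch locations have
been subtracted, so adjusted batch means are closer to equal than under an
independent null. The post-adjustment significant fraction therefore falls
*below* the nominal $\alpha$, typically to nearly zero — which is exactly the
pattern the verification tests assert (from >50% of genes batch-significant
on the simulated conditions down to at most $\alpha$).

### Adaptive filtering (`amplitude_filter`, `variance_filter`)

Fixed-fraction filters ("drop the lowest 50%") are too blunt for an 18-class
cohort, where modest subtype-specific signal is easy to discard. The adaptive
filter instead decomposes a per-gene statistic into a 1-D Gaussian mixture
and removes genes assigned to the uninformative component(s):

1. **Amplitude step** — statistic: per-gene mean log2 expression. Keep genes
   MAP-assigned to the (at most) three components with the highest means;
   the low-intensity background component is removed.
2. **Variance step** — statistic: log per-gene sample variance. Remove genes
   MAP-assigned to the lowest-mean (lowest-variance) component; zero-variance
   genes are removed outright.

The EM fitter uses ten k-means-seeded restarts, a variance floor of
$10^{-6}\,\mathrm{var}(x)$, and convergence at a log-likelihood change below
$10^{-8}$ (cap 500 iterations). The mixture order is chosen by BIC over
$k \in \{1,\dots,6\}$, ties to the smaller $k$ — the originating analysis does
not state its order-selection rule, and BIC is the standard choice for 1-D
Gaussian decompositions. MAP hard assignment (rather than a posterior
threshold) keeps the rule reproducible. When the selected order is 1 the
filters warn and remove nothing. "Amplitude" is interpreted as the per-gene
mean log2 expression; a per-gene maximum would weight single-sample spikes
and was rejected.

### Assumption-routed testing (`choose_test_branch`, `anova_gate`, `dunnett_vs_control`, `kruskal_wallis_gate`, `games_howell_pairwise`)

Normality is checked per group by Shapiro–Wilk and variance homogeneity by
Brown–Forsythe (median-centred Levene) — the conventional pair when no
specific tests are named. Routing is per analysis, not per gene: the checks
run gene-wise and the analysis goes parametric only if at least half the
genes pass both (under perfectly Gaussian data with six groups about 70% pass
at $\alpha = 0.05$, so Gaussian data route parametric; heavy-tailed noise in
even a few groups routes the analysis non-parametric). The branch can also be
forced in the configuration.

* **Parametric branch** (case-control analysis): one-way ANOVA gate, then
  Dunnett many-to-one comparisons against the control group. The family-wise
  adjusted p-value is the probability that the maximum absolute component of
  a multivariate-t vector (correlation
  $\rho_{ij} = \sqrt{n_i n_j / ((n_i+n_0)(n_j+n_0))}$, pooled df) exceeds the
  observed statistic, evaluated by seeded quasi-Monte-Carlo integration with
  $10^5$ points, making results reproducible to reported precision. The
  family is per gene: the adjustment controls the per-gene family-wise error
  rate across the many-to-one comparisons.
* **Non-parametric branch** (all-pairs analyses): tie-corrected
  Kruskal–Wallis gate, then Games–Howell pairwise comparisons — Welch
  statistic, Welch–Satterthwaite df, referred to the studentized range
  distribution with $k$ groups ($p = P(Q_{k,\nu} \ge t\sqrt2)$). With two
  groups this reduces exactly to the Welch t-test, which the test suite
  asserts to $10^{-6}$.

No across-gene multiplicity correction is applied beyond the per-gene
family-wise post-hoc control; the per-gene $\alpha$ defaults to 0.05. This
mirrors the analysis the pipeline reproduces, which reports none; users who
want an across-gene FDR can apply `p.adjust` to the gate p-values.

### Selection and set statistics (`ce_deg_sets`, `select_biomarkers`, `dice_coefficient`, `fisher_enrichment`)

CE-DEG and biomarker selection are pure set logic on the gene × class-pair
significance matrix (see definitions above). Set similarity is summarised by
the Dice coefficient $2|A\cap B|/(|A|+|B|)$ with a nonparametric gene-level
bootstrap interval: universe genes are resampled with replacement, the
coefficient recomputed on the induced multiset memberships, and percentile
bounds taken. The bootstrap was chosen because the originally cited interval
construction is not recoverable; it is distribution-free and seed-exact.
Term overrepresentation is a two-sided Fisher exact test over a user-supplied
universe — by default the genes surviving the adaptive filter, since that is
the population from which any discovery was possible. Term databases are the
user's to supply; nothing is downloaded.

### Cross-validation study (`repeated_stratified_cv` and friends)

The classification study runs stratified k-fold cross-validation (default
30-fold, 3 repetitions) with a linear-kernel, $C=1$ SVM using one-vs-one
multiclass voting — the conventional choice for $p \gg n$ expression data;
no kernel or hyperparameter tuning is in scope. Feature selection is re-run
inside every training fold, so the held-out fold never influences it (the
suite asserts this by instrumenting the selector). Classes smaller than $k$
simply appear in only some folds; every sample is held out exactly once per
repetition. Integer confusion counts are accumulated across repetitions and
divided by the repetition count, which is why published tables of this design
contain fractional cells. Two selectors are provided: the CE-DEG selector
(Kruskal–Wallis gate + Games–Howell, union of per-class CE-DEG sets) and the
baseline union of top-100 pairwise t-test genes, optionally followed by
greedy decorrelation at $|r| \ge 0.5$ — the conventional "large" effect size
for correlations, used to drop redundant features in priority order. The
minimum-error feature count is chosen over a log-spaced grid
$\{1, 2, 5, 10, 20, 50, 100, \dots\}$ (ties to the smaller size); the grid is
a runtime/bias compromise, as an exhaustive scan adds nothing at these scales.

## The synthetic-data generator

`simulate_dataset()` defines the study conditions every recovery test runs
under. It emulates, on the log2 scale:

$$x_{gs} = \mu_g + \beta_{g,k(s)} + \gamma_{g,b(s)} + \delta_{g,b(s)}\,\epsilon_{gs}$$

* $\mu_g$ from a four-component Gaussian mixture (weights 0.35/0.30/0.20/0.15,
  means 3.5/6.5/8.5/10.5, SDs 0.4/0.7/0.7/0.7): one low-intensity background
  component plus three signal components, the shape the amplitude filter is
  built for.
* class effects $\beta$: planted biomarkers are shifted by ±`effect_size` in
  exactly one class; planted CE-DEG genes in two classes with opposite signs,
  so they are CE-DEGs for both but biomarkers for neither.
* batch effects: additive $\gamma_{gb} \sim N(0, 0.5^2)$ and multiplicative
  log-normal $\delta_{gb}$ (log-SD 0.1) on the residual — the additive +
  multiplicative structure matches the empirical-Bayes batch model, so
  parameter recovery is a fair test rather than a gift.
* residuals: Gaussian with SD 0.5 for signal genes and 0.15 for background
  genes (background is both dim and quiet); classes listed in
  `heavy_tail_classes` get scaled t(3 df) residuals with the same variance,
  which is what trips the normality check and routes analyses
  non-parametric.
* the default class profile is the 18-class cohort profile scaled by 1/7
  with a floor of 10 samples per class (total ≈ 330) — imbalance preserved,
  desk-scale runtime kept; batches are assigned at random so batch and class
  are never confounded by construction.

What the generator does *not* emulate: gene–gene correlation beyond the
planted structure, probe-level spatial artefacts, intensity-dependent
variance, and label noise. Passing recovery tests therefore demonstrate that
the machinery is correct under its stated model, not that real cohorts will
yield these sensitivities.

## Numerical choices and degenerate inputs

* Constant genes: Kruskal–Wallis and pairwise tests return $p = 1$; zero
  within-group variance with unequal means returns $p = 0$.
* Zero-variance genes go straight to the variance filter's removal set.
* Quantile normalisation of a single column warns and returns the input.
* Single-batch input to the batch adjustment warns and returns the input.
* Median polish ties follow the standard mean-of-middles median; on
  continuous data ties occur with probability zero.
* All Monte-Carlo machinery (Dunnett integration, bootstrap, EM restarts,
  fold assignment) is seeded; identical seeds give identical reports.

## Problem sizes used in the shipped checks

The recovery suites run at desk scale, chosen as the smallest sizes at which
the asserted effects are comfortably identifiable: 2000 genes for the batch
and filter recovery studies (three to four batches, 60 samples per class for
batch recovery), 400 genes × six classes × 30 samples over five seeds for
biomarker recovery at effect size $2\times$ the residual SD, $10^4$
replicates for the family-wise error simulation, and a 300-gene six-class
dataset for the cross-validation study. The published-cohort arithmetic
(class merging, regulation percentages, sensitivity tables) is exact and
instantaneous.

## Known limitations

* The EB batch model assumes additive + multiplicative batch action on
  every gene; batch effects that reorder genes (rank interactions) are
  outside it.
* The studentized-range reference for Games–Howell is asymptotic in the
  Welch df; at very small group sizes it drifts from a permutation oracle by
  up to ~0.1 in p, as the suite documents.
* The biomarker definition is deliberately strict (significance against every
  other class, silence among all remaining pairs); with many classes the
  expected yield is small — on the full 18-subtype published cohort it was
  four genes.
* One-vs-rest pooled CE-DEG definitions, surrogate-variable batch
  estimation, non-parametric EB priors, FDR across genes and moderated
  (shrunken-variance) statistics are out of scope.
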
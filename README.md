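# cedeg — class-enhanced differential expression and biomarker discovery

`cedeg` is an R package for biomarker discovery in **multi-class** gene
expression studies: cohorts with many diagnostic classes (the motivating
setting is a 2096-sample, 18-subtype leukaemia bone-marrow cohort prepared in
11 centres), where batch effects must be removed before inference and where
"differentially expressed" has to be sharpened into per-class notions.

## The statistics at the core

With classes $c = 1, \dots, k$ and adjusted pairwise post-hoc p-values
$p_{g}(c, c')$ per gene $g$:

* a **CE-DEG** (class-enhanced DEG) for class $c$ is a gene with
  $p_g(c, c') < \alpha$ for *every* other class $c'$ — it separates $c$ from
  each other class in pairwise comparisons (a gene may be a CE-DEG for
  several classes);
* a **biomarker** for class $c$ is a CE-DEG for $c$ with
  $p_g(c', c'') \ge \alpha$ for *every* pair of remaining classes — it
  separates $c$ and nothing else. Biomarker sets are disjoint by
  construction.

The pairwise machinery is assumption-routed: one-way ANOVA gating with
Dunnett many-to-one comparisons (family-wise adjusted via the multivariate-t
distribution) when normality/homoscedasticity hold, or a Kruskal–Wallis gate
with Games–Howell pairwise comparisons (Welch statistic, Welch–Satterthwaite
df, studentized-range reference) otherwise. Upstream: RMA-style
preprocessing, parametric empirical-Bayes (ComBat) batch adjustment with
PCA/Kruskal–Wallis/two-way-ANOVA verification, and a two-step adaptive gene
filter based on 1-D Gaussian-mixture decomposition of per-gene mean
expression (amplitude step) and log variance (variance step). Downstream:
Dice set-similarity with bootstrap confidence intervals, Fisher-exact term
enrichment, and a repeated stratified cross-validation study with a linear
SVM. A synthetic-data generator with planted ground truth
(`simulate_dataset()`) makes every stage testable.

## Worked example

```r
library(cedeg)

cfg <- simulation_config(n_genes = 800,
                         class_sizes = c(ALL = 40, AML = 35, CLL = 30, CTR = 25),
                         n_batches = 3, effect_size = 1.5,
                         n_biomarkers_per_class = 5, n_ce_degs = 10, seed = 42)
d <- simulate_dataset(cfg)
report <- run_pipeline(d$matrix, d$annotation, analysis_config(seed = 42))
print(report)
```

```
Multi-class biomarker discovery pipeline
gene counts per stage:
             input   amplitude_filter    variance_filter case_control_gated 
               800                495                 32                 30 
batch-significant gene fraction: 0.949 before, 0.000 after adjustment

case-control DEG summary:
  class total up down up_pct down_pct
1   ALL    17  6   11  35.29    64.71
2   AML    19 10    9  52.63    47.37
3   CLL    20  6   14  30.00    70.00

main-class analysis (parametric branch): 4 CE-DEG-bearing classes, 19 biomarkers
subtype analysis (parametric branch): 19 biomarkers
```

Reading it: 95% of genes showed significant batch structure before
adjustment and none after; the amplitude filter removed the planted
low-intensity background component (800 → 495), the variance step collapsed
the uninformative constant-variance blob (495 → 32, keeping all 30 planted
differential genes), and the case-control analysis then reports per-class
DEG counts split by direction. Checking the biomarker calls against the
generator's ground truth:

```r
found <- unlist(report$main_pairs$biomarkers)
truth <- d$truth$gene_id[!is.na(d$truth$biomarker_class)]
sum(truth %in% found)   # 19 of the 20 planted biomarkers
```

Individual stages are exported and composable: `background_correct()`,
`quantile_normalize()`, `summarize_median_polish()`, `combat_adjust()`,
`amplitude_filter()`, `variance_filter()`, `pairwise_significance()`,
`ce_deg_sets()`, `select_biomarkers()`, `dice_matrix()`,
`fisher_enrichment()`, `repeated_stratified_cv()`, `confusion_metrics()`.
See the vignette in `vignettes/biomarker-discovery.Rmd` for the models,
assumptions and design decisions.

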
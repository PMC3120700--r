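# hmvboost

Histone modification/variant (HMV) profiles — the tag maps of marks such as
H3K4me3, H3K27ac or H3K79me3 around promoters and along gene bodies — carry
enough information to tell tissue/cell-type specifically regulated genes
from housekeeping genes. `hmvboost` implements that analysis end to end for
computational epigenomics work: defining the gene sets from expression
data, turning tag tracks into nucleosome-resolved feature tables, training
a boosting classifier that doubles as a feature selector, and evaluating it
the way such studies must be evaluated — balanced resampling,
cross-validation, and control-region baselines.

## The model in brief

**Gene sets.** For expression $e_t$ over $T$ tissues, with
$p_t = e_t/\sum e_t$, the overall Shannon entropy
$H = -\sum_t p_t \log_2 p_t$ and the categorical entropy
$Q_t = H - \log_2 p_t$ score tissue specificity: specific genes satisfy
$H < 5$ and $Q_t < 9$ bits; housekeeping genes must exceed overall-entropy
floors in two independent panels ($H > 6.2$ and $H > 8.9$ bits).

**Features.** Tags are counted on a fixed TSS-relative grid of 26
nucleosome intervals (6 upstream to 20 downstream; core positions
-2 [-370, -196] … +5 [675, 859], outer ones extended by 150 bp), one
column per (mark, nucleosome). Gene-body tables carry per-mark sums and
per-bp averages over the first exon, first intron and whole body plus a
20-window tiled count after the first exon. Control tables repeat the
featurization 50 kb upstream of the TSS.

**Classifier.** Discrete AdaBoost over decision stumps: per round the
stump minimizing weighted error over all (feature, threshold, polarity)
candidates joins the ensemble with vote
$\alpha = \tfrac12\ln((1-\epsilon)/\epsilon)$. The round-1 feature is the
"top predictive feature" tallied across resampling replicates.

**Evaluation.** Each replicate balances classes by subsampling negatives,
runs stratified 5-fold cross-validation (sensitivity, PPV, F-score), and
is compared against control-region-trained classifiers by a two-sided
Wilcoxon rank-sum on per-replicate F-scores.

A synthetic-data module generates expression panels, a toy genome and
overdispersed tag tracks with planted (mark, region) effects, so the whole
pipeline is testable without any external data.

## Worked example

```r
library(hmvboost)

## entropy scores for one gene expressed 1:3 across two tissues
p <- relative_expression(c(1, 3))
#> [1] 0.25 0.75
overall_entropy(p)
#> [1] 0.8112781
categorical_entropy(p, overall_entropy(p), 2)
#> [1] 1.226316
```

Evaluating an externally defined gene set against an entropy-defined truth
(392 predicted genes, 454 true positives, 66 shared) and rendering at the
two-decimal truncation used for printed tables:

```r
universe  <- sprintf("g%04d", 1:5000)
truth     <- universe[1:454]
predicted <- c(universe[1:66], universe[1000:1325])
ev <- evaluate_external_geneset(predicted, truth, universe)
ev$metrics
#> sensitivity         ppv     f_score
#>   0.1453744   0.1683673   0.1560284
ev$truncated
#> sensitivity         ppv     f_score
#>        0.14        0.16        0.15
```

A complete synthetic study — plant three informative marks among six,
call gene sets by entropy, featurize promoters, and evaluate against
control regions:

```r
design <- simulation_design(n_specific = 100, n_housekeeping = 150,
                            n_marks = 6, seed = 42)
res <- run_tcs_pipeline(design, replicates = 10, rounds = 20,
                        control = TRUE, seed = 43)
res
#> tcs_pipeline (promoter features): 100 specific vs 150 housekeeping genes
#> replicate_report over 10 balanced resamples
#>   sensitivity  0.959 ± 0.013
#>   ppv          0.998 ± 0.004
#>   f_score      0.978 ± 0.008
#>   top feature counts: M03_p8=4, M03_p6=3, M02_p2=2, M03_p2=1
#>   signal vs control: p = 0.000179 *
res$report$mark_counts
#> M03 M02
#>   8   2
```

The classifier recovers the planted classes almost perfectly (mean F-score
0.978 over ten balanced resamples), the top-selected features all belong to
planted informative marks (`M03`, a gene-body mark whose signal shows
downstream of the TSS, and the promoter mark `M02`), and the
control-region baseline is significantly worse (`*` marks
$10^{-5} \le p < 0.01$; with ten replicates a rank-sum p-value cannot go
below $10^{-4}$, so more replicates are needed for the strictest band).

Other entry points: `coreboost()` (the classifier, with `predict`,
`summary`, `coef`, `plot` and JSON persistence), `split_sets()` (PCA
grouping of marks into Set I/II), `transfer_evaluate()` and `jitter_tss()`
(cross-dataset application and TSS-resolution experiments),
`redundancy_experiment()` (mark-removal analysis), and `make_dataset()`
(write a self-contained synthetic bundle in BED/BED12/TSV).

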
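# delirmetab

An R pipeline for **matched case-control targeted metabolomics**, built
around the design used to search for plasma markers of postoperative
delirium: cases (DEL) and controls (CNT) matched into pairs, sampled
preoperatively (PREOP) and on postoperative day 2 (POD2), acquired over
several mass-spectrometry runs with interleaved pooled quality-control (QC)
injections and spiked internal standards.

It is written for analysts who have an SRM-quantified intensity table
(samples × metabolites) — or no data at all: a first-class synthetic cohort
generator with a ground-truth ledger makes every stage testable and lets you
study the pipeline's operating characteristics (sensitivity, false discovery
rate, fold-change bias) before touching real samples.

## What the pipeline computes

**Preprocessing.** A metabolite is *present* if measured in ≥ 50% of the
samples of at least one phenotypic group (PREOP-CNT, PREOP-DEL, POD2-CNT,
POD2-DEL). Signal drift is corrected per metabolite by regressing the
pooled-QC series on the global injection order (random-forest regression by
default, after QC-RFSC; a smoothing spline is available) and dividing each
sample by the median-anchored fitted factor, bridging runs through the QC
series. Remaining gaps are filled by k-nearest-neighbour imputation (k = 10,
inverse-distance weights over co-observed standardized channels). Loading
variation is removed by NOMIS normalization: each analyte's log2 values are
regressed on the centred log2 internal-standard channels, keeping residual +
mean. A QC audit reports the relative standard deviation,
RSD% = 100·SD/mean, per metabolite before and after.

**Univariate consensus testing.** Per metabolite and timepoint, the per-pair
log2(DEL/CNT) ratios feed three tests — paired *t*, Wilcoxon signed-rank
(exact for n ≤ 25), and the exact two-sided sign/binomial test — each
BH-adjusted across metabolites. A metabolite is a *consensus* call when ≥ 2
tests pass α = 0.05 (nominal p at PREOP, BH q at POD2, following the
convention that few metabolites survive BH preoperatively). `AVG_p` is the
mean of the passing raw p-values. Robustness is assessed by repeatedly
dropping 10% of the pairs and recording how often the call survives. The
fold change is the one-step Tukey biweight of the paired log2 ratios
(c = 5), reported signed: FC = −2 means two-fold down in DEL.

**Multivariate modelling.** After a PCA/Mahalanobis outlier screen, an
OPLS-DA model (authored here: sequential orthogonal-component estimation and
deflation, then one predictive component) yields R²X, R²Y, cross-validated
Q² (sevenfold, pairs kept together in folds), VIP scores
(VIP_j = √(J·w_j²) on the predictive component, so mean VIP² = 1),
response-permutation p-values for R²Y and Q², and CV-ANOVA
(F = [(SS−PRESS)/df₁]/[PRESS/df₂], df₁ = 1+n_ortho, df₂ = N−1−df₁).
Metabolites with VIP > 2 form a panel classified by a linear-kernel SVM
under leave-pair-out cross-validation, summarized by a pooled ROC and AUC.

**Pathway enrichment.** Consensus metabolites are mapped into a GMT pathway
library; each pathway of size K in a universe of N compounds, with n mapped
inputs and `Hits` inside, gets the exact hypergeometric upper-tail p,
`Expected` = K·n/N, BH FDR across the library, and a topology `Impact` — the
summed normalized betweenness centrality of the hit compounds in the
pathway graph.

## Worked example

```r
library(delirmetab)
library(dplyr)

lib <- read_pathway_library(
  system.file("extdata", "toy_pathways.gmt", package = "delirmetab"),
  system.file("extdata", "toy_pathway_edges.tsv", package = "delirmetab"))

# spike ten pathway-coherent metabolites at |log2 FC| = 1 at POD2
spiked <- sort(unique(unlist(lib$sets[1:2])))[1:10]
cfg <- pipeline_config(
  cohort = cohort_config(n_pairs = 20, n_runs = 2, n_metabolites = 120,
                         effect_metabolites = spike_effects(spiked, rep(c(1, -1), 5), "POD2"),
                         technical_cv = 0.1, seed = 42),
  level = c(PREOP = "nominal", POD2 = "BH"),
  n_ortho = c(PREOP = 1, POD2 = 2), n_perm = 199,
  pathway_library = lib, seed = 42)
report <- run_pipeline(cfg)
report
#> <pipeline_report>
#>   PREOP: 6/117 consensus metabolites; R2Y = 0.860, Q2 = -0.590; panel AUC = 79.2%
#>   POD2: 10/117 consensus metabolites; R2Y = 0.968, Q2 = 0.730; panel AUC = 99.8%
```

Nothing was spiked at PREOP, so its model does not cross-validate
(Q² < 0) and its 6 nominal-level consensus calls are the false-positive
cost of the lenient PREOP convention. At POD2 the ten spiked metabolites
are exactly the ten consensus calls:

```r
report$univariate$POD2 |> filter(consensus) |> arrange(AVG_p) |>
  select(metabolite_id, AVG_p, FC, VIP) |> head(5)
#>   metabolite_id      AVG_p    FC   VIP
#> 1 met_003       0.00000127  2.09  3.40
#> 2 met_008       0.00000127  2.07  3.25
#> 3 met_038       0.0000199   1.72  2.85
#> 4 met_048       0.0000205  -1.89  3.02
#> 5 met_006       0.0000256  -2.03  3.16

report$enrichment$POD2 |> head(3)
#>   pathway_id Total Expected  Hits     raw_p      FDR Impact
#> 1 path_01       16     1.44     7 0.0000319 0.000637  0.361
#> 2 path_02       12     1.08     4 0.0119    0.119     0.316
#> 3 path_15       20     1.80     4 0.0789    0.526     0.207

truth_eval(report$univariate$POD2, report$truth, "POD2")
#>   sensitivity   fdr fc_bias n_spiked n_detected
#> 1           1     0  0.0372       10         10
```

The estimated fold changes sit within 0.04 log2 units of the spiked truth,
and the pathway the spikes were drawn from tops the enrichment table
(7 hits against 1.44 expected, FDR 6.4e-4).

`autoplot(report$multivariate$POD2$model)` draws the OPLS-DA score plot,
`autoplot(report$multivariate$POD2$svm)` the panel ROC curve, and
`plot_rsd_audit()` the QC RSD distributions before and after preprocessing.

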
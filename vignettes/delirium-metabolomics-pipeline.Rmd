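---
title: "Methods: a matched case-control targeted-metabolomics pipeline"
author: "delirmetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a matched case-control targeted-metabolomics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delirmetab)
```

## The design being modelled

The pipeline targets a nested matched case-control metabolomics study:
subjects who developed postoperative delirium (DEL) are matched one-to-one
with controls (CNT), and plasma from both is assayed at two timepoints,
preoperative (PREOP, candidate *risk* markers) and postoperative day 2
(POD2, candidate *disease* markers). Targeted SRM quantification yields a
samples × metabolites intensity matrix. Acquisition is batched over
instrument runs; each run opens with conditioning injections and carries
blanks, repeated injections of one pooled QC plasma, and spiked internal
standards alongside the study samples. The analysis never sees raw spectra:
its contract starts at the quantified table.

Matching makes the pair the unit of inference: every test operates on the
within-pair log2(DEL/CNT) ratio, which cancels the pair-level biological
component that matching induces and halves the variance relative to a
two-group comparison. No covariate adjustment beyond the matching is
attempted.

## The synthetic cohort generator

Because matrices from such studies are rarely deposited, the generator is a
first-class module: it produces cohorts with the statistical structure the
analysis assumes, plus a ledger of every injected artefact, so each stage
can be validated by parameter recovery rather than by fixture files.

On the log2 scale, the value for subject $s$ of pair $p$, metabolite $m$ is

$$x_{s m} = \mu_m + a_{p m} + e_{s m} + \delta_m(t)\,[s \in \mathrm{DEL}]
          + \ell_s + \gamma_m\,A_r\,g_r(u_s) + \varepsilon_{s m}$$

with base abundance $\mu_m \sim U(10, 20)$ (instrument units span roughly
$2^{10}$–$2^{20}$); a pair-shared effect $a_{pm}$ and individual effect
$e_{sm}$ whose variances split the between-subject SD $\sigma_b$ by the
within-pair correlation $\rho$ (so matched subjects correlate at $\rho$); a
true effect $\delta_m(t)$ applied to DEL at timepoint $t$; a per-sample
loading factor $\ell_s \sim N(0, \sigma_\ell^2)$ multiplying **every**
channel including the internal standards (the identifying assumption of
internal-standard normalization); a smooth per-run drift curve $g_r$ of the
injection position $u_s$, scaled by amplitude $A_r$ and metabolite
sensitivity $\gamma_m \sim U(0.5, 1.5)$; and technical noise with
$\mathrm{sd}(\log_2 x) = \mathrm{CV}/\ln 2$. Pooled QCs carry no biological
terms; internal standards carry no biological terms or effects. Blanks sit
~9 log2 units below the pool. Missingness is then applied: left censoring
whose probability ramps from 0 at the metabolite's `mnar_quantile` intensity
to 1 at its minimum (mimicking limit-of-detection dropout that imputation
must tolerate), plus uniform MCAR dropout. Standards are exempt — they are
spiked at high concentration, and normalization requires them observed
everywhere.

Defaults are the study conditions: 52 pairs × 2 timepoints = 208 study
samples; six runs of which five carry 10 pairs each (with 13 QCs, 4 blanks,
3 conditioning injections — 60 injections, a realistic autosampler load) and
an abridged sixth run carries the remaining 2 pairs with proportionally
fewer QCs (floor, minimum 3); 315 channels including 3 internal standards;
`mnar_quantile = 0.04` and `mcar_rate = 0.01`, which together give ~2–3%
missingness; $\sigma_b = 0.5$, $\rho = 0.6$, CV = 5%, $\sigma_\ell = 0.2$,
drift amplitude 0.3 (all log2 where applicable) — values a plasma SRM
practitioner would call ordinary. A pair's four samples always share a run,
with DEL/CNT injected adjacently: batching by pair prevents pair–run
confounding, which is the matched design's intent.

What the generator does **not** emulate: peak-shape and integration
artefacts, isotope interference, correlated metabolite modules
(pathway-level covariance), heavy-tailed biological variation, and real
clinical covariates. Passing recovery tests therefore demonstrates that the
pipeline's machinery is correct and calibrated under its stated model — not
that real plasma data satisfy that model.

## Preprocessing: order and choices

The stage order is **presence filter → drift correction → imputation →
normalization**. Filtering first avoids spending model capacity on
channels that are mostly absent; drift is corrected before imputation so the
imputer sees drift-free values (the alternative order is available via
`impute_first = TRUE`; on simulated cohorts the two differ negligibly
because the kNN pool is dominated by complete cells).

*Presence* is boundary-inclusive: measured in ≥ 50% of at least one
phenotypic group. A measured zero counts as measured; only explicit missing
cells do not.

*Drift correction* fits, per metabolite, the pooled-QC intensities against
the **global** injection index across all runs jointly — the QC series is
what bridges runs, and no additional per-run location/scale adjustment is
applied. The default regressor is a 500-tree random forest (seed-controlled);
since forests cannot extrapolate, and splines can but shouldn't, predictions
outside the QC span clamp to the nearest fitted value. The correction factor
is anchored at the median fitted QC value, which preserves each metabolite's
QC mean to within ~1% and can never produce negative intensities (division
by a positive factor; non-positive fitted factors fall back to 1).
Metabolites missing in more than half the QCs are left uncorrected and
flagged rather than corrected from too thin a series.

*Imputation* is kNN in sample space: distances are Euclidean over
co-observed channels after per-metabolite standardization, normalized by the
number of co-observed channels; weights are inverse distance, with exact
twins (zero distance) taking all the weight; k = 10. These are the
conventional choices behind the bare name "knn", and they are exposed as
arguments.

*Normalization* regresses each analyte's log2 values on the centred log2
standards jointly (OLS, intercept included), keeping residual + mean.
With three standards sharing a single loading factor the joint regression is
the identified estimator; an "optimal subset" search was considered and
rejected — it adds a data-dependent selection step with nothing to select at
this design size, and collinear standards are already dropped via QR with a
warning. Standards leave the analyte set afterwards, so downstream stages
never test them.

## Univariate layer

All three tests run on log2 ratios (consistent with multiplicative error
and with the fold-change machinery). Incomplete pairs are deleted pairwise
per metabolite — pairing is preserved without re-imputation. Conventions
that needed fixing: the sign test is two-sided by doubling the smaller
exact tail (capped at 1); the Wilcoxon drops zero ratios and is exact for
n ≤ 25 without ties, normal-approximated with tie correction otherwise; a
zero-variance ratio vector yields p = 1 when all ratios are exactly zero
(no evidence) and an undefined p otherwise. BH families are one test × one
timepoint across present metabolites. The consensus rule (≥ 2 of 3 at
α = 0.05) uses nominal p at PREOP and BH q at POD2; `AVG_p` averages the
**raw** p-values of the passing tests. Split-robustness removes 10% of the
*pairs* (not samples — removing samples would break pairs) uniformly at
random, reruns the battery, and calls a metabolite robust at ≥ 50% survival.

The fold change is the one-step Tukey biweight of the paired log2 ratios
with c = 5 and a guard eps = 1e-4 added to the scaled MAD, so a constant
vector returns exactly that constant and a zero-MAD vector with one gross
outlier down-weights the outlier to zero. The signed mapping
($b \ge 0 \Rightarrow 2^b$, else $-2^{-b}$) makes −2 mean two-fold down;
both $b$ and the signed FC are reported, since signed-FC magnitudes below 1
are not interpretable under this convention.

## Multivariate layer

OPLS-DA is authored in the package: with X centred and unit-variance scaled
(the metabolomics default; Pareto and centre-only are options) and y coded
±1, each orthogonal component takes $w \propto X^\top y$, splits the X
loading into its part along $w$ and the orthogonal remainder $w_o$, and
deflates $X \leftarrow X - t_o p_o^\top$; a single predictive component is
then extracted. Q² uses sevenfold cross-validation with the two members of
a pair always in the same fold (pair-level random effects would otherwise
leak across the split) and class-stratified assignment otherwise; PRESS is
measured against the globally centred class response. CV-ANOVA uses
df₁ = 1 + n_ortho and df₂ = N − 1 − df₁ (the convention is echoed in the
output, since the literature varies), with F clamped at zero — under a null
model cross-validation makes PRESS exceed the total SS, so the statistic is
conservative there by construction. Permutation p-values use the
(1 + exceedances)/(1 + n) estimator and deliberately break the pair
structure. VIP is computed on the predictive component only (the
class-discriminating part), making mean VIP² = 1 an exact identity; an
option includes orthogonal components weighted by explained X variance.
The number of orthogonal components is an explicit user choice (1 at PREOP,
2 at POD2 by convention in the pipeline defaults); an automatic
add-while-Q²-improves rule was considered and left out — with these sample
sizes it chases noise, and the explicit choice is auditable.

The PCA/Mahalanobis screen flags samples whose squared distance in the
first two PC scores exceeds the χ²₂ quantile at α = 0.025 and removes them
before OPLS-DA. The VIP > 2 panel feeds a linear-kernel SVM (cost 1,
features standardized within each training fold) under leave-pair-out
cross-validation; held-out decision values are pooled into one ROC and the
AUC is cross-validated, not resubstitution — per-fold orientation is fixed
on training data only.

## Enrichment layer

Name mapping is case-insensitive exact matching after stripping punctuation
and whitespace; unmapped names are reported, never silently dropped. The
universe defaults to all compounds of the loaded library, overridable with
the assay panel. The raw p is the exact hypergeometric upper tail; FDR is
BH across the *library* size m, so reporting only the top rows does not
change the adjustment (untested pathways are assumed to rank after the
reported ones). Topology impact — the summed exact-betweenness weight of the
hit compounds, normalized per pathway — is reported alongside, never
combined with, the p-value; inventing a combined score would manufacture a
statistic with no sampling theory. A pathway with no graph reports impact
NA; a graph whose betweenness is identically zero (a single edge) falls
back to uniform node weights.

## Numerical and reproducibility choices

Log base 2 everywhere a log is taken. Missing is a distinct state: empty
string or NA on disk, never zero. Report tables sort by ascending `AVG_p`
with ties broken by metabolite id and use fixed numeric formatting, so
identical analyses produce byte-identical files (the pipeline manifest
records md5 checksums). One global seed expands into per-stage substreams
via stable hashing of the stage name, so any stage re-runs identically in
isolation; internal seeding snapshots and restores the caller's RNG state,
so library calls never perturb a user's own random stream.

## Validation study sizes

The shipped validation studies use: oracle sweeps at enumerable sizes (sign
test 2ⁿ for n ≤ 12, Wilcoxon for n ≤ 10, hypergeometric draws for N ≤ 15);
50 random models for the VIP and orthogonality identities; 200 null cohorts
(52 pairs × 250 metabolites, no missingness, zero effects) for test
calibration, with 20 of them carrying 49-permutation validation; and 20
spiked cohorts (20 effects at |log2 FC| = 1, CV 10%, drift amplitude 0.5,
~3% missingness) for end-to-end recovery, preprocessed with the spline
drift regressor and scored against the ledger. Two calibration facts are
worth knowing rather than hiding: the exact sign test at n = 52 has a
maximum achievable two-sided size of 0.0365 (discreteness — it can never
attain 0.05), and null CV-ANOVA p-values pile up near 1 (PRESS > SS under
overfitting), which is the statistic's documented conservatism, not an
implementation artefact.

## Limitations

Real cohorts bring correlated metabolite blocks, non-Gaussian biology,
matrix effects, and batch phenomena richer than a smooth drift curve; none
of these are in the generator, so calibration results transfer to real data
only to the extent the model holds. The enrichment layer is only as good as
the supplied library and name mapping; the bundled toy library exists for
testing and demonstration, not biology. OPLS-DA here is binary-class with a
single predictive component; multi-class and kernel variants are out of
scope.
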
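---
title: "Methylation progression analysis and consensus prognostic signatures"
author: "methprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation progression analysis and consensus prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methprog)
```

## Scope and model

`methprog` implements a complete analysis stack for Illumina 450K-style DNA
methylation beta values across breast cancer progression (normal breast
tissue, ductal carcinoma in situ, invasive carcinoma). A beta value is the
fraction of methylated molecules at a CpG — methylated signal divided by
total signal — so all methylation inputs live on $[0, 1]$.

The stack has five analytical stages, each usable on its own:

1. **Gene-region collapse.** Each gene-mapped CpG belongs to one of six
   functional subregions — TSS1500 (1,500–201 bp upstream of the TSS,
   boundaries inclusive), TSS200 (200 bp upstream through the TSS), 5'UTR,
   first exon, body (other exons and introns), 3'UTR. Per gene × subregion,
   the methylation level is the **median** beta of member CpGs, computed
   per sample over observed members; intergenic CpGs are dropped. The
   even-count median is the mean of the two central values, and a CpG
   annotated to several genes contributes to each — both standard
   conventions for many-to-many 450K annotation.

2. **SAM-style differential methylation.** For target $i$ the moderated
   statistic is
   $$d_i = \frac{\bar{x}_{i2} - \bar{x}_{i1}}{s_i + s_0},$$
   with $s_i$ the pooled standard error of the group-mean difference and
   $s_0$ a fudge factor shared across targets that prevents small-variance
   targets from dominating. Significance comes from label permutations
   (default 100; when fewer distinct two-group arrangements exist they are
   enumerated exhaustively): for each observed $|d_i|$ the expected
   false-call count is the number of permuted $|d^*|$ values at or above
   it, averaged over permutations, and the q-value is that count divided
   by the number of observed statistics at or above the cutoff, capped at
   1 and monotonized so q never increases with $|d|$. A target is *called*
   only under the dual rule: $q < 0.01$ **and** an absolute difference of
   group **medians** of at least 0.1 (10 percentage points of
   methylation). The statistic follows the mean-based SAM convention while
   the effect filter is median-based, which makes the call robust to
   single outlying samples. In multiclass mode $d$ is an F-like ratio
   (root between-group mean square over pooled within-group SD plus
   $s_0$), and the effect filter uses the maximum pairwise difference of
   group medians. Two-cohort designs are supported by
   `concordant_calls()`: only targets called in both cohorts with the same
   direction of change are reported.

3. **Cis methylation–expression (eQTM) correlation.** Every (CpG, gene)
   pair with the CpG within 100 kb of the gene's TSS (boundary inclusive;
   distances strand-oriented, negative upstream) is tested for non-zero
   Pearson correlation, two-sided p from the t distribution on
   $n - 2$ df, with Bonferroni control at 0.05; the correction factor $m$
   is the number of pairs actually tested, computed separately for the
   CpG-level and the region-level analyses since they answer different
   questions. Gene-direction summaries use the "at least one CpG"
   convention, so a gene may legitimately appear in both the positively
   and the negatively correlated sets.

4. **Unsupervised structure.** Samples are clustered on
   $1 - \mathrm{Pearson}$ correlation distance (centered correlation,
   range $[0, 2]$) over the 500 most variable gene regions (sample
   variance; ties broken by target id for determinism), with average
   linkage (UPGMA). Cluster composition against tissue type or intrinsic
   subtype is reported descriptively as a cross-tabulation, without a
   test.

5. **Survival and the prognostic signature**, described next.

## Survival machinery

`km_fit()`, `logrank_test()`, `cox_fit()` and `ph_check()` are implemented
from first principles. The Cox model maximizes the Efron-corrected partial
likelihood by Newton–Raphson with step-halving; Efron rather than Breslow
tie handling is the default of the surrounding software ecosystem and is
exact in the continuous-time limit. Standard errors come from the observed
information; Wald 95% intervals are reported on the hazard-ratio scale.
The score test at the null is retained because, for a single binary
covariate on tie-free data, it equals the log-rank statistic — a classical
identity the test suite checks to $10^{-6}$. Non-convergence within 100
iterations and monotone-likelihood separation ($|\hat\beta| > 15$) are
flagged rather than silently accepted. Missing covariate values are
handled complete-case per model, with a message giving the count.

The proportional-hazards diagnostic regresses scaled Schoenfeld residuals
on a transform of event time (default: the Kaplan–Meier transform
$1 - \hat S(t^-)$, the default of the ecosystem's `cox.zph`), giving a 1-df
chi-square per covariate and a global test on $p$ df — the
Grambsch–Therneau construction built from this package's own residuals and
information matrix.

Breast-cancer-specific death is the sole event; any other end of follow-up
is treated as censoring by the caller. This is an assumption, not a
competing-risks analysis.

## The consensus Lasso–Cox signature

`meth_signature()` is the package's central fitting function. The
procedure:

1. **Pre-selection**: keep CpGs with at least one cis correlation at
   nominal (uncorrected) $p < 0.05$ (`preselect_probes()`), focusing the
   regression on CpGs with evidence of a functional link to expression.
2. **Repeated cross-validated Lasso–Cox**: 100 repetitions of 10-fold
   cross-validated L1-penalized Cox regression on the raw betas. The only
   randomness across repetitions is the fold reassignment (seeded per run
   from the master seed); the data are fixed.
3. **Consensus**: probes nonzero in at least 80% of runs form the
   signature — the 80-of-100 boundary is inclusive — and each member's
   coefficient is the mean over the runs in which it was present.
4. **Risk index**: patient $i$ is scored with the exact linear form
   $$\mathrm{index}_i = \sum_{g=1}^{n} \beta_g \, X_{gi},$$
   no centering or rescaling, and dichotomized at the **training median**,
   which is stored and carried unchanged to validation cohorts. The
   dichotomization rule is a package choice (the most common convention);
   it is exposed via the `cut` argument.
5. **Evaluation**: Kaplan–Meier curves and log-rank p for high vs low
   risk, the univariate hazard ratio, a multivariate Cox model adjusting
   for ER status, TP53 mutation, T status (indicators for level 2 and
   "3 or 4" against reference 1) and lymph node status, the PH
   diagnostic, and the four-stratum node × risk classification.

### Penalty rule and scaling — a deliberate design choice

Two defaults differ from the most common `cv.glmnet` habits, for reasons
the package's own validation exposed:

* **`lambda_rule = "lambda.1se"`** (the sparsest penalty within one
  standard error of the minimum cross-validated deviance), not
  `lambda.min`. Because the consensus runs reshuffle folds on *fixed*
  data, any noise probe selected at the deviance-minimizing penalty tends
  to be selected in *every* run — presence filtering cannot remove it.
  In simulations with 10 strong planted CpGs among 500 nulls (n = 200),
  `lambda.min` admits on the order of 30 null probes at ≥80% presence,
  while the one-standard-error rule yields clean recovery (9–10 of 10
  planted, no false members). Sparser rules are the standard remedy in
  stability-selection practice; `lambda.min` remains available.
* **`standardize = FALSE`**: the penalty acts on raw beta units. The risk
  index multiplies raw $X_{gi}$, so coefficients and penalty then share
  one scale; it also stops near-constant probes from being inflated by
  internal standardization. Betas all live on $[0,1]$, so the scales are
  already comparable.

The per-run penalty path is computed once on the full data (50 values,
`lambda.min.ratio = 0.05`) and reused across runs, which keeps 100
repetitions inside a minute at the simulated problem sizes without
affecting the one-standard-error selection, which lives in the upper part
of the path. The penalized solver itself is `glmnet` — the established
coordinate-descent implementation with exact zeros — while the consensus
aggregation, presence rule, index and evaluation are this package's own.
At `lambda = 0`, `lasso_cox()` agrees with the package's independent
Newton–Raphson fit to $10^{-4}$, which the test suite asserts.

## The synthetic cohort generator

`simulate_cohort()` produces beta, expression, clinical and annotation
tables with recorded ground truth, so that every stage has a recoverable
target. What it emulates, and the defaults:

* **Cohort structure**: 46 normal, 22 DCIS, 186 invasive samples —
  the tissue composition of a progression series. Counts are free
  parameters.
* **Background betas**: per-CpG means from a bimodal mixture
  (Beta(2,10) island-like low / Beta(10,2) open-sea-like high, equal
  weight), sampled with Beta precision 50 (per-sample SD ≈ 0.05–0.07),
  reproducing the U-shaped marginal distribution of 450K arrays.
* **Differential CpGs**: a beta shift of 0.2 (configurable) planted in
  DCIS+IBC (normal→DCIS contrast) or IBC only (DCIS→IBC contrast); the
  direction points away from the nearer boundary, so the realized
  group-mean difference equals the nominal effect without clipping.
* **eQTM couplings**: expression = intercept + slope × beta + N(0, 0.4),
  slope magnitude 3 (log-expression units per beta unit), negative for
  promoter-subregion CpGs and positive for body/3'UTR CpGs. This puts
  planted cis correlations at $|r| \approx 0.4$–$0.5$ — the
  strong-eQTM regime.
* **Prognostic signature**: planted CpGs are variably methylated (means
  uniform on 0.3–0.7, Beta precision 8 — prognostic information requires
  between-patient variability), with signed coefficients of magnitude
  2–4. Survival is exponential with log-hazard
  `log_hr_per_index_unit` (default 1.5) per unit of the *centered* true
  index; baseline hazard log(2)/60 per month (60-month median survival).
  Censoring is an independent exponential whose rate is tied to the
  **baseline** hazard, `censor_rate/(1 - censor_rate) × λ0`, so the event
  fraction is monotone in `censor_rate` and is not starved by the
  heavy-tailed realized hazards. Signature CpGs are a subset of the eQTM
  CpGs so that expression-based pre-selection can retain them, as in the
  real design.
* **Two-cohort designs**: `simulate_two_cohorts()` draws two sample
  realizations from one planted structure, with an additive per-CpG batch
  offset (SD 0.02) per cohort — emulating a fresh-frozen discovery cohort
  plus an FFPE validation cohort that share biology but not noise.

What it does **not** emulate: probe-level artefacts (type I/II chemistry,
cross-reactive probes), tumor purity and cell-type composition, copy
number, correlated CpG blocks, or non-exponential survival. Passing the
recovery tests therefore demonstrates correctness of the procedures under
clean planted signal, not performance on real cohorts.

## Numerical choices and degenerate inputs

* **SAM q-values** use the *mean* permuted false-call count. With the
  median, the count for the top-ranked target collapses to zero in about
  half of complete-null datasets (the permutation maximum falls below the
  observed maximum with probability ≈ 0.5), yielding spurious q = 0
  calls; the mean is the usual estimator of the expected number of false
  calls and eliminates the artefact without costing power.
* **Fudge factor** $s_0$: candidates are the {0, 5, …, 95} percentiles of
  $s$; each is scored by the coefficient of variation of window-wise
  `mad(d)` across ten $s$-quantile windows, and the smallest candidate
  within 5% of the minimal CV is chosen. The tolerance matters: for
  homoscedastic data the CV profile is almost flat with a drift toward
  large $s_0$, and the tie-break keeps the (innocuous) moderation small.
  All-constant matrices get $s_0 = 0$ with a warning.
* **Group label order** is canonical (C-locale sort), so the sign of the
  two-class $d$ is reproducible and flips under label swap; permutations
  are drawn against a canonically sorted sample order, making q-values
  exactly invariant to column order at a fixed seed.
* **KNN imputation** uses RMS distance over the samples where both probes
  are observed (scaling by overlap size keeps probe pairs with different
  overlaps comparable), averages the k = 10 nearest donors observed at the
  target sample, warns and uses all donors when fewer than k exist, and
  clips imputed values to $[0,1]$ to preserve the beta-value invariant.
  Observed values are never altered.
* **Probe filtering** removes probes with *more than* 50% missing values
  — a probe missing in exactly half its samples is retained.
* **Zero-variance** pairs are skipped (and logged) in correlation, are an
  error in clustering (a flat profile has no correlation distance), and
  yield $d = 0$ in SAM.
* **Ties** in survival times use the Efron correction everywhere;
  simultaneous events at one time are handled jointly in the product-limit
  estimator and in the hypergeometric log-rank variance (factor
  $(n_j - d_j)/(n_j - 1)$).

## Problem sizes in the validation suite

The test suite and the acceptance script run entirely on synthetic data,
sized for single-CPU laptop-scale runs: differential-methylation recovery
on 2,000 CpGs × 100 samples with 100 permutations; consensus-signature
recovery on 510 probes × 200 patients with the full 100-repetition
procedure (repeated over three seeds in the tests); survival oracles at
n ≤ 500. The full suite completes in a few minutes; the acceptance script
in well under one.

## Known limitations

* The eQTM engine tests each pair independently; no attempt is made to
  model linkage between neighbouring CpGs or shared regulatory structure.
* The Cox implementation targets the small-p regime of clinical adjustment
  models (p ≤ a few dozen); it is not optimized for high-dimensional
  designs, which belong to the penalized path.
* `ph_check` approximates the classical scaled-Schoenfeld slope test; its
  null level and power are validated by simulation, but it is not
  numerically identical to every `cox.zph` variant.
* Consensus presence fractions are conditional on the fixed training
  cohort; they measure stability to fold assignment, not to resampling of
  patients.
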
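# methprog

DNA methylation analysis across breast cancer progression, with a
consensus Lasso–Cox prognostic signature.

`methprog` is an R package for Illumina 450K-style beta-value data
(β = methylated signal / total signal, the fraction of methylated
molecules at a CpG) over a progression series of breast tissue — normal,
ductal carcinoma in situ (DCIS), and invasive breast carcinoma (IBC). It
is written for epigenomics analysts who want the complete, tested chain
from beta matrix to prognostic risk groups:

* **Gene-region collapse** — per gene × functional subregion (TSS1500,
  TSS200, 5'UTR, first exon, body, 3'UTR), the median beta of member
  CpGs; intergenic CpGs dropped.
* **SAM-style differential methylation** — moderated statistic
  d = (mean₂ − mean₁)/(s + s₀) with permutation q-values (100
  permutations, exhaustive enumeration when feasible) and the dual call
  rule *q < 0.01 and |difference of group medians| ≥ 0.1*; two-class and
  multiclass modes; two-cohort concordance filtering with direction
  agreement.
* **Cis eQTM correlation** — Pearson tests of every (CpG, gene) pair
  within 100 kb of the TSS (boundary inclusive, strand-oriented
  distances), Bonferroni control at 0.05, direction summaries by
  subregion or TSS-distance bin.
* **Clustering** — top-500 variable regions, 1 − Pearson correlation
  distance, average linkage (UPGMA), with Newick export.
* **Survival machinery from first principles** — Kaplan–Meier, log-rank,
  Cox proportional hazards (Newton–Raphson, Efron ties, Wald CIs, score
  test), scaled-Schoenfeld proportional-hazards diagnostics.
* **Consensus Lasso–Cox signature** — expression-correlated
  pre-selection (nominal p < 0.05), 100 repetitions of 10-fold
  cross-validated L1-penalized Cox regression differing only in fold
  assignment, membership at ≥ 80% presence with run-averaged
  coefficients, and the linear risk index

  &nbsp;&nbsp;&nbsp;&nbsp;indexᵢ = Σ₉ β₉ · X₉ᵢ

  dichotomized at the training median, carried unchanged to validation
  cohorts.
* **Synthetic cohorts with planted truth** — `simulate_cohort()`
  generates beta/expression/clinical/annotation tables with recorded
  differential CpGs, signed eQTM couplings, and a survival-linked CpG
  signature, so every stage can be validated end to end.
* **KNN imputation and probe filtering** for validation-style matrices
  with missing values (drop probes > 50% missing, impute with k = 10
  nearest probes, clip to [0, 1]).

The package ships a published-style 18-CpG prognostic methylation
signature as a coefficient table
(`system.file("extdata", "signature18.tsv", package = "methprog")`) for
use with `compute_index()`.

## Worked example

```r
library(methprog)

cfg <- simulate_config(n_normal = 30, n_dcis = 20, n_ibc = 100,
                       n_cpgs = 800, n_diff_normal_dcis = 60,
                       n_diff_dcis_ibc = 20, n_eqtm = 40,
                       n_signature = 8, seed = 2024)
cohort <- simulate_cohort(cfg)

# differential methylation, normal vs DCIS
grp  <- setNames(cohort$clinical$tissue, cohort$clinical$sample_id)
keep <- grp %in% c("normal", "DCIS")
dm   <- sam_test(cohort$beta[, names(grp)[keep]], grp[keep], seed = 1)
sum(dm$called)
#> [1] 60        # exactly the 60 planted CpGs

# eQTM pre-selection and consensus signature on the invasive tumors
pairs  <- build_cis_pairs(cohort$annotation, cohort$tss)
corr   <- correlate_pairs(cohort$beta, cohort$expression, pairs)
probes <- preselect_probes(corr)          # 80 CpGs at nominal p < 0.05
tum    <- cohort$clinical$tissue == "IBC"
sig    <- meth_signature(t(cohort$beta[probes, tum]),
                         cohort$clinical$time[tum],
                         cohort$clinical$event[tum], seed = 1)
sig
#> Consensus Lasso-Cox methylation signature: 8 CpGs (100 runs, presence >= 80%)
#>            coefficient presence
#> cg00000089     -3.3432     1.00
#> cg00000118     -1.3658     1.00
#> cg00000172      1.9035     1.00
#> cg00000425     -1.0296     0.98
#> cg00000453      2.6898     1.00
#> cg00000535     -3.6402     1.00
#> cg00000597      0.8383     0.97
#> cg00000615     -1.6040     1.00
#> training: n = 100, events = 46, median index cut = -3.0556

# risk groups and survival evaluation
risk <- predict(sig, cohort$beta[, tum], type = "group")
evaluate_signature(risk, cohort$clinical)
#> Signature evaluation on 100 samples
#>   log-rank (high vs low): chi-square = 60.2, p = 8.37e-15
#>   univariate HR (high vs low): 16.9 (95% CI 6.58-43.3)
#>   adjusted model:
#> Cox proportional hazards (Efron ties): n = 100, events = 46
#>                  HR       CI95        p
#> er_pos     1.464820 0.782-2.74 2.33e-01
#> tp53_mut   1.413245  0.713-2.8 3.21e-01
#> t2         1.187421 0.609-2.32 6.14e-01
#> t3or4      1.283321 0.569-2.89 5.48e-01
#> node_pos   1.240931  0.66-2.33 5.03e-01
#> risk_high 20.462724  7.59-55.2 2.43e-09
#>   node x risk strata log-rank p = 4.55e-13
```

The eight signature members are exactly the eight planted prognostic
CpGs; the adjusted hazard ratio for the risk classification dwarfs the
(null) clinical covariates, and combining lymph node status with the risk
group sharpens the stratification further — the behavior the procedure is
designed to exhibit when a true methylation signal is present.

`run_pipeline()` orchestrates the same stages against TSV inputs (or the
simulator) with a YAML config, writing per-stage TSVs and a JSON manifest
with seeds and input checksums.

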
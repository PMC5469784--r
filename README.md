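# mvdep

Benchmarking missing-value imputation and differential-expression detection
for label-free quantitative proteomics.

## What this is for

Label-free proteomics matrices have few replicates (typically three per
condition) and many missing values that are abundance-dependent (MNAR): the
lower a peptide's abundance, the likelier it is lost. Whether you should
impute before testing for differentially expressed proteins (DEPs) — and
with which method — depends on the missing-value fraction and the statistic
used. `mvdep` lets you study exactly that, on synthetic spike-in-style data
where the truth is known:

1. **Simulate** a two-group log-intensity matrix: background proteins at a
   1:1 ratio, a DEP fraction shifted by `log(3)` (a 1:3 spike-in).
2. **Mask** it with the graded MNAR mechanism: per replicate, proteins are
   split by abundance 3:4:3 into grades I/II/III and the NA budget
   (`round(fraction × cells)`) is allocated 6:3:1 to the grades, low
   abundance first.
3. **Impute** with mean (MeI), k-nearest-neighbour (kNNI, k = 10),
   abundance-distribution (ADI: positive draws from `N(μ_j, σ_j)` of an
   abundance-quantile pool, averaged over 100 repeats), or multiple
   imputation by chained equations (MuI, m completions averaged) — or leave
   the holes in ("ignore").
4. **Detect** DEPs with Welch's t
   (`t(i) = (x̄₁ − x̄₂)/√(s₁²/n₁ + s₂²/n₂)`), an exhaustive label-permutation
   test, the SAM statistic `d(i) = (x̄₁ − x̄₂)/(s(i) + s₀)` with an
   automatically selected fudge factor, or a reproducibility-optimized
   modified-t family `d_α = (x̄₁ − x̄₂)/(α₁ s(i) + α₀)` tuned by bootstrap
   top-list overlap (ROTS-style).
5. **Score** everything: BH q-values, TPR/FPR/FDR with g- and f-scores,
   ROC with partial AUC at specificity > 0.95, detection rate / mean rank
   of the known positives, and imputation fidelity (minimum per-replicate
   Pearson r, MAD, MSD).

## Worked example

```r
library(mvdep)

sim    <- generate_complete(simulation_params(n_proteins = 1000, seed = 42))
grades <- assign_grades(sim$matrix)
masked <- inject_missing(sim$matrix, grades,
                         missingness_params(0.05, seed = 43))
masked
#> ExpressionMatrix: 1000 proteins x 6 replicates (log scale)
#> groups: g1 (n=3), g2 (n=3)
#> missing: 300 / 6000 cells (5.0%)

imp <- impute_knn(masked)
fid <- imputation_fidelity(sim$matrix, imp)
#  r = 0.9986, mean ln(MSD) = -0.837   -> imputed values track the truth

res   <- sam_test(imp, c("g1", "g2"), seed = 44)
truth <- sim$truth$de_labels[res$protein_id]
confusion_metrics(res$p_value < 0.05, truth)
#  TPR = 0.990, FPR = 0.034, FDR = 0.075
roc_pauc(-res$p_value, truth)$pauc
#  0.0459 of a 0.05 maximum
detection_rate_mean_rank(res$p_value, truth, window = 300)
#  DR = 0.957, MR = 146.0
```

So at 5% missingness, kNN imputation followed by SAM recovers 99% of the
true DEPs at p < 0.05 while keeping the false-positive rate at 3%, and its
ranking uses 92% of the achievable partial-ROC area. The full grid
(`run_benchmark()`) and the chained-equations m-sweep (`run_m_sweep()`)
automate this over missing-value fractions 5–45%, all methods, and both
cutoffs, writing `metrics.tsv`, `fidelity.tsv`, `msweep.tsv` and a seed
manifest.

A caveat worth knowing before you read any benchmark table: with three
replicates per group an exhaustive two-sided permutation test has only 20
label assignments and its smallest possible p-value is 0.1, so permutation
columns legitimately report zero calls at p < 0.05 — a granularity fact,
not a bug. See the vignette (`vignettes/benchmarking-missing-values.Rmd`)
for this and the other design decisions.

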
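# icombat

Batch-effect correction for DNA methylation array data with an
**incremental** mode: new batches are corrected against the frozen
parameters of an earlier fit, so samples corrected months ago keep exactly
the values they had — bit for bit — after every later addition.

## Who this is for

Analysts of methylation array studies (EWAS, epigenetic-clock evaluation)
where samples accumulate over time: longitudinal cohorts, clinical trials
with baseline and end-of-study measurements, multi-site collections
integrated one cohort at a time. Conventional all-at-once correction
re-touches every sample whenever a batch is added; any quantity already
derived from the earlier samples silently drifts. Here it cannot.

## The model

Per batch *i*, sample *j*, CpG site *g*, on the M-value scale
(Y = log2((M+η)/(U+η))):

    Y_ijg = α_g + X_ij' β_g + γ_ig + δ_ig ε_ijg,   ε_ijg ~ N(0, σ_g²)

* α_g — site mean; β_g — biological covariate effects (protected);
* γ_ig, δ_ig — additive and multiplicative batch effects;
* identifiability: Σ_i n_i γ_ig = 0.

Fitting is the classical three-step empirical-Bayes procedure: per-site
OLS for the global parameters; standardization and method-of-moments
hyperpriors (γ_ig ~ N(γ̄_i, τ̄_i²), δ_ig² ~ InvGamma(ζ̄_i, θ̄_i)) with the
per-site batch effects shrunk to the coupled fixed point

    γ*_ig = (n_i τ̄_i² γ̂_ig + δ²*_ig γ̄_i) / (n_i τ̄_i² + δ²*_ig)
    δ²*_ig = (θ̄_i + ½ Σ_j (Z_ijg − γ*_ig)²) / (n_i/2 + ζ̄_i − 1)

and correction Y* = σ̂_g/δ̂*_ig (Z − γ*_ig) + α̂_g + X'β̂_g.

The incremental step standardizes a new batch with the *stored* α̂, β̂, σ̂,
estimates that batch's effects and hyperpriors from its own samples alone,
solves the same fixed point, and appends the result to the model store —
no stored parameter is recomputed. See the methods vignette
(`vignettes/icombat-methods.Rmd`) for the full derivation and the
numerical choices.

## Worked example

```r
library(icombat)

ds    <- simulate_methylation("S1", seed = 7)   # 500 sites, 4 batches
parts <- split_existing_new(ds)                 # batches 1-3 vs batch 4

fit <- combat_fit(parts$existing$Y, parts$existing$sheet)
fit$model
#> icombat_model: 500 sites, 3 batch(es) [B1, B2, B3], 2 covariate column(s)

res <- icombat_correct(parts$new[[1]]$Y, parts$new[[1]]$sheet, fit$model)
res$model
#> icombat_model: 500 sites, 4 batch(es) [B1, B2, B3, B4], 2 covariate column(s)

combined <- cbind(unclass(fit$corrected), unclass(res$corrected))
combined <- combined[, colnames(ds$Y)]
g <- ds$sheet$covariates$group; a <- ds$sheet$covariates$age
for (m in c("raw", "corrected")) {
  st <- site_regression(if (m == "raw") ds$Y else combined, g, a)
  r <- tpr_fpr(st, ds$truth_signal)
  cat(sprintf("%-10s TPR = %.3f, FPR = %.3f, GC lambda = %.3f\n",
              paste0(m, ":"), r$tpr, r$fpr, gc_lambda(st)))
}
#> raw:       TPR = 0.500, FPR = 0.004, GC lambda = 2.160
#> corrected: TPR = 0.780, FPR = 0.058, GC lambda = 1.253

pairwise_correlation(combined, unclass(combat_fit(ds$Y, ds$sheet)$corrected))
#> [1] 0.9973035
```

Reading: on the uncorrected draw the per-site group test is badly
miscalibrated (genomic-control λ 2.16, i.e. test statistics inflated ~2x
by batch structure) and underpowered; after correction λ drops to 1.25 and
the true-positive rate over the 50 signal sites rises from 0.50 to 0.78 at
a false-positive rate near the nominal 0.05. The incrementally corrected
batch-4 values agree with a joint all-batch correction at cell-wise
correlation 0.997, while the batch-1–3 values are untouched (maximum
absolute change exactly 0 — verified per replicate by the test suite).

A file-based workflow with the same operations is available through the
CLI wrapper (`inst/cli/icombat.R`): subcommands `simulate`, `fit`
(`--matrix --samples --covariates --out --model`), `add-batch`,
`evaluate`, `convert`.

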
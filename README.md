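# lipidisc

Targeted lipidomics cohort analysis: geometric-mean statistics, enzyme
activity indices, OPLS-DA discriminant modeling with iterative variable
selection, and Spearman correlation networks.

## The problem

Targeted plasma lipidomics panels quantify dozens to hundreds of
non-esterified fatty acids (NEFA), oxylipins and endocannabinoids (NAEs,
MAGs, lipoamino acids) in two clinical groups — here a type 2 diabetic
versus a non-diabetic cohort. Concentrations are approximately log-normal
and strongly intercorrelated, group sizes are small and unbalanced, and the
scientific questions are layered:

1. **Which lipids change, and by how much?** Effect sizes are percent
   changes in geometric mean, ΔGM = 100·(GM₁ − GM₀)/GM₀, tested per lipid
   by Mann–Whitney U with Benjamini–Hochberg FDR control at q = 0.1.
2. **What do the changes say about enzymes?** Plasma product:substrate
   ratios proxy desaturase/elongase activity — e.g. the stearoyl-CoA
   desaturase (SCD) index averages 16:1n7/16:0 and 18:1n9/18:0. Because the
   geometric mean is multiplicative, GM(product/substrate) =
   GM(product)/GM(substrate) exactly.
3. **Does the panel predict disease state?** A NIPALS PLS-DA model is
   optimized by iterative variable selection (IVS): features are randomly
   partitioned into subsets, each subset is greedily pruned (backward
   deletion) and re-grown (forward addition) against cross-validated Q² =
   1 − PRESS/TSS, the optimized subsets are unioned, and the cycle repeats
   to convergence. The best of an ensemble of independent runs is refit as
   an OPLS-DA model, which collapses all class-predictive variation onto a
   single latent variable for interpretable score and loading plots;
   performance is reported as Q² and AUROC under repeated stratified
   2/3–1/3 external validation, with selection-induced optimism quantified
   by embedded split/select/test validations.
4. **How do variable relationships rewire?** Per-group Spearman
   correlation matrices feed parameter connectivity networks: variables
   embedded by multidimensional scaling of 1 − |ρ| distances, edges drawn
   at per-group significance thresholds, and metabolite classes outlined
   by Hotelling T² 95% ellipses.

Because subject-level data of the motivating study were never deposited,
the package ships a calibrated synthetic cohort generator
(`default_study_spec()`) that emulates the study's structure — two groups
of n = 12 and 43, log-normal concentrations anchored at the published
group geometric means, pathway-coupled product/substrate ratios, and
clinical covariates rank-coupled to lipid totals — so the whole chain is
testable end to end.

## Worked example

```r
library(lipidisc)

cohort <- generate_cohort(default_study_spec(), seed = 1)
univ <- summarize_cohort(cohort, q = 0.1)
format_univariate(univ)[univ$metabolite %in%
  c("Total NEFA", "16:0", "18:1n9", "A-EA"), ]
#>   metabolite group0            group1            delta_gm_pct  p_value fdr_significant
#> 1 16:0       92.7 [55.5, 177]  196 [56, 590]              111  3.08e-5 TRUE
#> 2 18:1n9     45.1 [21, 97]     150 [62.8, 371]            233  5.65e-7 TRUE
#> 3 A-EA       2.09 [1.37, 3.34] 3.57 [1.91, 7.25]           71  2.35e-5 TRUE
#> 4 Total NEFA 301 [188, 469]    644 [275, 1390]            114  7.01e-6 TRUE
```

Palmitate roughly doubles (ΔGM 111%), oleate triples, total NEFA rises
114% — each geometric mean is shown with its observed range, and the FDR
flag marks rejections at q = 0.1 across the whole tested family.

```r
idx <- compute_all_indices(cohort)
idx[idx$is_composite, c("ratio", "gm_group0", "gm_group1", "delta_gm_pct")]
#>             ratio gm_group0 gm_group1 delta_gm_pct
#> 1             SCD    0.6003    0.9648         60.7
#> 2             D6D    0.0803    0.0852          6.1
#> 3          ELOVL2    0.4211    0.7190         70.8
#> 4 ELOVL2/D6D/SPCS    6.3615    3.9800        -37.4
```

The activity indices recover the planted enzyme pattern: SCD up ~60%, D6D
flat, ELOVL2 up, VLCPUFA chain shortening down.

```r
X <- conc_matrix(cohort)
ens <- ivs_ensemble(X, cohort$group, ivs_config(n_runs = 10, seed = 7))
model <- build_final_model(X, cohort$group, ens$best$selected_variables)
model
#> OPLS-DA model: 1 predictive + 1 orthogonal component(s), 15 feature(s)
#>   R2Y = 0.892, training AUROC = 1.000
q_squared(X[, model$features], cohort$group, seed = 7)
#> [1] 0.86
external_validation(X[, model$features], cohort$group, seed = 7)$summary
#>   statistic   mean     sd
#> 1 q2_train   0.848 0.0186
#> 2 q2_test    0.849 0.0241
#> 3 auroc_test 1     0
```

IVS keeps 15 of 47 candidate lipids; the final OPLS-DA model separates the
groups with cross-validated Q² ≈ 0.86 and perfect held-out AUROC on this
synthetic cohort (the planted effects are strong). `tidy(model)` returns
the loading table, `autoplot(model)` the score plot, and
`build_pcn(cohort, group = "diabetic")` / `autoplot()` the connectivity
network. `run_pipeline(pipeline_config(...))` executes the whole chain and
writes a reproducible report bundle (CSV tables, model JSON, GraphML
networks, seed-stamped manifest).

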
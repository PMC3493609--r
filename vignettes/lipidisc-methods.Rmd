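---
title: "Methods: models, parameters and design choices in lipidisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in lipidisc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidisc)
```

lipidisc implements a complete two-cohort targeted-lipidomics analysis
chain. This vignette documents the statistical models, the tunable
parameters and their defaults, the synthetic data generator and its
calibration, and the places where the design was genuinely open and a
choice had to be made.

## Quality control

Reporting criteria act on per-analyte quantification records. A record is
unreportable when its signal-to-noise ratio is below 2, its concentration
is below the lowest calibrant, or its surrogate recovery is below 40%. All
three rules are strict inequalities: a record exactly at a threshold is
kept. Surrogate correction divides the raw concentration by the recovery
fraction before any statistics.

For partly unreportable metabolites two policies are offered
(`mask_unreportable()`): mask offending measurements per subject, or drop
a metabolite panel-wide when more than half of either group is
unreportable (the default). The half-of-either-group rule is our choice;
masked values are represented as `NA`, never as zeros, because every
downstream statistic operates on the log scale.

## Univariate statistics

Concentrations are treated as log-normal, so location is summarized by the
geometric mean (GM) and effect size by the percent change
ΔGM = 100·(GM₁ − GM₀)/GM₀, with the first group level as reference.
Report formatting rounds GMs to three significant figures and ΔGM to the
nearest integer percent.

Group differences are tested by the Mann–Whitney U test, two-sided (both
increases and decreases are of interest). The U statistic always comes
from rank sums with midranks. Two p-value modes exist:

* `approx` (default): normal approximation with tie-corrected variance and
  continuity correction, delegated to `stats::wilcox.test()`.
* `exact`: full enumeration of the permutation null over all
  C(n₁+n₂, n₁) group labelings of the midranks, valid under ties, feasible
  for n₁+n₂ ≤ 20.

Multiplicity is handled by the Benjamini–Hochberg step-up at q = 0.1
(`stats::p.adjust`). The FDR family is one `summarize_cohort()` call — the
whole tested panel, including class-sum rows — a deliberately conservative
and explicit choice since finer per-table families are equally defensible.

Class sums (total NEFA, total SFA, ...) are computed per subject *before*
any averaging, because the GM of sums is not the sum of GMs; sums are only
formed within a uniform unit (µM or nM), enforced at run time. A
metabolite constant in both groups gets p = 1 and a flag rather than an
error.

## Enzyme activity indices

Plasma product:substrate NEFA ratios proxy enzyme activities: SCD
(16:1n7/16:0, 18:1n9/18:0), D6D (18:3n6/18:2n6, 20:3n3/20:4n6), ELOVL2
(22:4n6/20:4n6, 22:5n3/20:5n3) and the combined ELOVL2/D6D/SPCS axis
(22:5n6/22:4n6, 22:6n3/22:5n3). Ratios are formed per subject; GM, range,
ΔGM and the U test then follow the univariate conventions. By
multiplicativity, GM(ratio) = GM(product)/GM(substrate) exactly on
complete data — a property the test suite checks to machine tolerance.

How the two component ratios combine into the named composite index is not
standardized. We use the arithmetic mean of a subject's component ratios:
for the SCD and ELOVL2 indices this convention reproduces the published
composite GMs from their published components (e.g. diabetic SCD
mean(0.04, 1.88) ≈ 0.96). It does not reproduce the published
ELOVL2/D6D/SPCS level (which was presumably computed on unrounded
subject-level data); we retain the per-subject-mean-then-GM path and note
that only that row's ΔGM, not its level, is comparable. Subjects missing
any component are excluded from the composite; nothing is imputed.

## Discriminant modeling

Features are natural-log transformed, centered and scaled to unit variance
(`fit_preprocessor()`), with parameters estimated from training rows only.
The class label is coded 0/1 and centered.

**PLS-DA** is fitted by NIPALS. With a single response the weight step is
closed-form (w ∝ X'y), so each component costs a few matrix products;
components are extracted with iterative deflation, giving mutually
orthogonal score vectors. The fit is deterministic — no random
initialization, fixed deflation order.

**OPLS-DA** removes, one at a time, components orthogonal to the label
(weights built from the loading's residual after projecting out the
predictive direction), then fits exactly one predictive latent variable on
the filtered matrix. Its predictions are identical to those of a PLS-DA
model with one more component — the acceptance suite verifies
max |difference| < 1e-8 over 100 random instances — so the value of OPLS
is interpretability, not accuracy: scores and loadings of the single
predictive component feed the standard displays, oriented so features
elevated in the second class load positive. The default of one orthogonal
component suits a panel dominated by one shared-variation axis; the count
is configurable and can be chosen by maximizing Q².

**Q²** = 1 − PRESS/TSS accumulates squared held-out prediction errors over
cross-validation folds, with preprocessing refitted inside each training
fold and TSS taken about each training fold's mean label. The default is
stratified 7-fold, seed-controlled; a deterministic "blocked" scheme
(interleaved within class, the venetian-blind convention) is available
because CV software differs here and neither is canonical. Folds that lose
a class entirely raise an error rather than silently degrade.

**AUROC** is computed by midrank pair counting and equals the concordance
probability P(score₊ > score₋) + ½P(tie); it is invariant under monotone
transforms of the scores.

**External validation** partitions the cohort, stratified by class, into
three test sets that cover every subject exactly once; each repeat trains
on the complementary two thirds. With 55 subjects the test sets have sizes
{18, 18, 19} — nobody is dropped when n is not divisible. Results are
reported per repeat and as mean ± sd.

## Iterative variable selection

The wrapper (`ivs_run()`) maximizes cross-validated Q² of the inner
two-component PLS-DA model:

1. randomly partition the current feature set into subsets
   (default `ceiling(p/20)` subsets, small enough for exhaustive
   single-move search);
2. within each subset, run backward deletion to convergence (repeatedly
   remove the variable whose removal most improves the objective, while
   any removal improves it by more than the tolerance), then forward
   re-addition of excluded variables, cycling until no move helps;
3. union the optimized subsets and greedily refine the union; accept it if
   the objective gained more than the tolerance, else stop. The outer loop
   is capped at 10 iterations and its accepted objective values form a
   non-decreasing trajectory.

Within one run the CV fold assignment is frozen (derived from the run
seed) so the greedy search compares moves on a noise-free objective; a
re-randomized objective would not converge. Ties on equal gains go to the
lexicographically first variable — documented and seed-independent. The
convergence tolerance defaults to 1e-4 Q² units.

`ivs_ensemble()` runs independent restarts (default 100; smaller
ensembles are used in tests and examples for speed) with seeds derived
affinely from the base seed, so enlarging the ensemble extends rather than
reshuffles it, and returns the maximum-Q² run (ties: fewer variables, then
lower index). `build_final_model()` refits OPLS-DA on the selected
columns.

Feature selection is deliberately **not** nested inside the final model's
cross-validation; `overfitting_estimate()` quantifies the resulting
optimism instead: split 2/3–1/3 stratified, run a full IVS ensemble on the
training part only, compare training Q² with held-out test Q², repeat
(default 7 validations), and report the mean ± sd percent drop. On
signal-free data the drop is large and test Q² collapses below zero; on
noise-free separable data it vanishes.

## Correlation networks

Spearman's ρ is computed per group over all metabolites and clinical
covariates (midranks for ties), with two-sided p-values from the
t-approximation t = ρ√((n−2)/(1−ρ²)) — adequate at the study's group sizes
— or by full permutation enumeration for groups of n ≤ 8 (beyond that the
n! enumeration is impractical; the t-approximation remains the default
everywhere).

The parameter connectivity network embeds variables by multidimensional
scaling of d = 1 − |ρ|, so tightly correlated variables of either sign sit
close. The default embedding refines the classical (Torgerson) solution by
SMACOF stress majorization, which is deterministic from that start;
`method = "classical"` is the pure spectral solution and recovers
planar-realizable inputs exactly. The display is 2-D by default (a 3-D
option exists) and is aligned by a rigid motion only — glucose translated
to the origin, the SFA centroid rotated to the lower-right quadrant — so
no pairwise distance changes.

Edges connect pairs significant at p < 0.05 in the smaller non-diabetic
group and p < 0.01 in the larger diabetic group (the conventional display
thresholds for unequal n); thresholds are configurable, no multiplicity
correction is applied to network edges, and edge sets are nested in p.
Metabolite classes with at least dims + 2 members get Hotelling T²
ellipses: center = mean, shape = covariance, boundary radius² =
dims(k−1)/(k−dims)·F₁₋ₐ(dims, k−dims), times (1 + 1/k) for prediction
(new-point) coverage, the default since the ellipse describes where class
members lie.

The pathway graph maps univariate and ratio results onto annotated
biosynthetic edges: node size ∝ |ΔGM|, edge width ∝ |ΔP:S|, colors encode
FDR-significant increase/decrease; edges without a computed ratio are kept
gray at zero width.

## The synthetic cohort generator

`generate_cohort()` draws from an explicit `cohort_spec()`:

* **Concentration law.** Log-normal per metabolite: the group GM sets the
  log-location, `log_sd` the log-spread. The analysis consumes GMs and
  ranks, so this matches the analysis model by construction. Default
  spreads are back-calculated from published [min, max] ranges under the
  convention that a range spans ±2.5 log-sd.
* **Correlation.** A shared log-scale factor with weight 0.6 (of log
  variance) induces the strong positive inter-metabolite correlation seen
  in fasting NEFA panels; the true correlation structure of any real study
  is not identifiable from published tables, so the weight is
  configuration, not assertion.
* **Pathway couplings.** A product metabolite is its substrate times a
  log-normal ratio whose GM is planted per group — so ratio effect sizes
  are exact calibration anchors. Chained couplings are applied
  substrate-first. With `ratio_log_sd = 0` every subject's ratio equals
  the group ratio GM exactly.
* **Clinical covariates.** Gaussian per group, rank-coupled to a named
  lipid total through a Gaussian copula (Pearson r = 2 sin(πρ/6) on normal
  scores yields the target Spearman ρ); values are winsorized at 2% of the
  group mean because clinical chemistry cannot be negative. Targets
  |ρ| > 0.999 are rejected as infeasible.
* **Moment matching.** Every standard-normal draw is centered and scaled
  within group before use. Sample GMs therefore equal their specification
  exactly at any group size, and derived quantities (class-sum effect
  sizes) are stable across seeds — a variance-reduction device that makes
  small simulated cohorts behave like calibrated ones. The cost is a mild
  distortion of small-sample variability; permutation-based null checks
  are unaffected because subjects remain exchangeable under the null.

`default_study_spec()` encodes the published panel: the individually
reported NEFA, oxylipin, NAE and LAA species at their printed GMs;
substrates reported only through ratios (20:4n6, 20:5n3, and the coupled
products 18:3n6, 20:3n3, 22:5n6, 22:6n3) at GMs derived from the printed
ratios; clinical covariates at the published mean ± sd with the published
glucose–total-NEFA Spearman correlation (0.68) planted; and one
"NEFA-other" remainder pool carrying the gap between the printed total
NEFA GM and the sum of all component GMs (3.94 / 4.31 µM), so component
medians add to the printed totals. Because medians of sums of dependent
log-normals exceed sums of medians, the simulated total-NEFA GM runs a few
percent above the printed level while its percent change reproduces the
printed 114% closely (113.5 ± 0.2 across seeds at n = 2000 per group); the
printed per-species GMs, ratio GMs and the total's ΔGM are the calibration
anchors, printed ranges are not.

What the generator does **not** emulate: instrument drift, batch effects,
censoring at detection limits, medication effects, or the study's true
(unknown) correlation fine structure. Tests passing on synthetic cohorts
therefore validate the algorithmic chain and its calibration — not claims
about any real cohort.

## Numerical choices and degenerate inputs

* Zero-variance features abort preprocessing with the feature named;
  components beyond the informative rank of X abort NIPALS.
* Greedy IVS moves must improve the objective by > 1e-4 (Q² units); the
  trajectory is non-decreasing by construction.
* NIPALS needs no iteration for a single response; orthogonality of score
  vectors holds to 1e-8 after unit-variance scaling of features.
* Constant variables within a group propagate `NA` through correlation
  matrices and are assigned the maximal correlation distance 1.
* All randomness flows through explicit integer seeds (`withr`
  scoped-seed semantics, R's default Mersenne–Twister); identical seeds
  give bitwise-identical cohorts, folds, splits and selections.

## Problem sizes used in validation

The shipped validation suite exercises: worked-example identities on the
published tables (instant); 50 planted-feature recovery repetitions at
n = 12/43 with 21–23 features and 5-run ensembles; 100 random instances
for OPLS/PLS equivalence; 200 label permutations each for FDR and Q² null
calibration; exhaustive oracles at n ≤ 8; ellipse coverage at n = 5000;
and generator fidelity at n = 2000 per group. These sizes were chosen to
make Monte-Carlo error small relative to each acceptance band while
keeping the whole suite comfortably fast on one core.

## Known limitations

* Binary cohorts only — no multi-class discriminants or covariate-adjusted
  (e.g. mixed-model) univariate tests.
* The exact-permutation options are limited to small groups by
  combinatorial growth (U test: n₁+n₂ ≤ 20; Spearman: n ≤ 8).
* The composite ELOVL2/D6D/SPCS level depends on an aggregation convention
  that published tables underdetermine (see above).
* PCN displays in 2-D can place weakly related variables close together
  when the correlation geometry is intrinsically higher-dimensional; the
  stress value reported with every embedding quantifies this.
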
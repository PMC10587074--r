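# potencybench

Diagnostics for compound potency prediction benchmarks.

## The problem

Potency regression benchmarks on ChEMBL-style activity classes (curated
compound sets with measured pIC50 against one target) routinely report that
support vector regression with a Tanimoto kernel, random forests,
nearest-neighbour lookups, and even a constant median predictor all achieve
global mean absolute errors within ~0.1 pIC50 units of each other. This
package implements the analysis that explains the effect, for
cheminformatics method developers who need to know what their benchmark is
actually measuring.

The core of the analysis is **error decomposition by potency sub-range** —
LOW [5, 7), MID [7, 9), HIGH [9, 11] — combined with **sub-range-balanced
training-set ladders** (6, 12, 18, 30, 48, 78, 126, 204, 330 compounds,
equal thirds per sub-range, one fixed balanced test set per trial).
Methods:

- **SVR** with the precomputed Tanimoto kernel K(a,b) = |a∧b|/|a∨b|
  (C ∈ {1, 10, 100, 1000}, 3-fold CV grid search),
- **RFR** on raw 2048-bit ECFP4-style fingerprints (grid over trees, split
  and leaf sizes, feature subsampling),
- **1-NN / 3-NN** Tanimoto nearest-neighbour controls,
- **MR**, median regression: ŷ = median(train) — the MAE-optimal constant,
  i.e. the null model.

Scoring uses MAE, RMSE and squared Pearson correlation (r²), with
two-sided exact Wilcoxon signed-rank tests over the 10 per-trial values for
all C(5,2) = 10 method pairs at the Bonferroni-corrected threshold
α = 0.005.

Because benchmark classes concentrate compounds near the class median
(which falls in pIC50 7–8), MID-sub-range error is low for *every* method
at *every* training-set size — no learning required — and dominates the
global numbers. Learning is visible only in the LOW/HIGH sub-ranges, where
error falls steeply with training-set size.

A synthetic activity-class generator (`synth_config()`,
`generate_benchmark_suite()`) emulates the relevant statistics of curated
classes — unimodal median-centred potency distributions, analogue-series
fingerprint clustering, ≥ 75 compounds per sub-range — so the entire
pipeline runs and is tested without any download. Deposited curated classes
in the same CSV schema load through `read_class_csv()` and `curate()`.

## Worked example

```r
library(potencybench)

suite <- generate_benchmark_suite(
  3, synth_config(min_per_subrange = 135L, n_compounds = 660L), seed = 1)
qualify_classes(suite, 135L)
#> # A tibble: 3 × 7
#>   class_id     n n_low n_mid n_high median_pic50 qualified
#>   <chr>    <int> <int> <int>  <int>        <dbl> <lgl>
#> 1 SYNTH-01   783   238   410    135         7.43 TRUE
#> 2 SYNTH-02   770   197   438    135         7.63 TRUE
#> 3 SYNTH-03   750   135   480    135         7.89 TRUE

cls <- suite[suite$class_id == "SYNTH-01", ]
plan <- random_5050_splits(cls, n_trials = 1, seed = 2)
train <- cls[match(plan$train_ids[[1]], cls$compound_id), ]
test  <- cls[match(plan$test_ids[[1]],  cls$compound_id), ]

svr <- fit_potency_model(train, "SVR", seed = 3)
mr  <- fit_potency_model(train, "MR")
decompose_by_subrange(predict(svr, test))[, c("scope", "n", "mae")]
#> # A tibble: 4 × 3
#>   scope      n   mae
#>   <fct>  <int> <dbl>
#> 1 GLOBAL   391 0.445
#> 2 LOW      119 0.669
#> 3 MID      208 0.239
#> 4 HIGH      64 0.699
decompose_by_subrange(predict(mr, test))[, c("scope", "n", "mae")]
#> # A tibble: 4 × 3
#>   scope      n   mae
#>   <fct>  <int> <dbl>
#> 1 GLOBAL   391 0.955
#> 2 LOW      119 1.09
#> 3 MID      208 0.448
#> 4 HIGH      64 2.35
```

Reading: globally SVR (0.45) looks comfortably better than the null (0.96).
But the decomposition shows the null is nearly as good as SVR for the 208
intermediate-potency compounds (0.45 vs 0.24), and the gap lives almost
entirely in the sparsely populated outer sub-ranges — the part of the class
that global benchmark numbers barely weight. `run_ladder()` extends this to
training-set-size dependence, where MID error is flat for SVR/RFR/MR alike
while LOW/HIGH error starts at the null level (~2 pIC50 units for 6–18
training compounds) and only separates from it as training sets grow.

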
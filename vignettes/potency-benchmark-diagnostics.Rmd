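---
title: "What potency prediction benchmarks measure: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{What potency prediction benchmarks measure: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative potency prediction — regressing pIC50 from a molecular
representation — is usually evaluated on *activity classes*: curated sets of
compounds with measured potency against one protein target. A recurring and
troubling observation in such benchmarks is that methods of very different
complexity (kernel support vector regression, random forests, deep networks)
and near-trivial controls (nearest-neighbour lookup, even a constant
predictor) land within about 0.1 pIC50 units of each other in mean absolute
error. A benchmark that cannot separate a support vector machine from a
constant is not measuring learning.

potencybench implements the diagnostic that explains this: decompose
prediction error by potency *sub-range* — LOW `[5, 7)`, MID `[7, 9)`, HIGH
`[9, 11]` — and vary training-set size with balanced sub-range populations.
The picture that emerges is that typical activity classes are dominated by
intermediate-potency compounds clustered near the class median (itself in
the 7–8 interval). Every method, including median regression, predicts
those compounds well *without learning*; genuine learning is only visible
for weakly and highly potent compounds, where accuracy depends strongly on
training-set size.

## Pipeline and models

The pipeline is: curation (`curate()`, `qualify_classes()`) → fingerprints
(`ecfp4()`, or generated bit vectors) → splits (`random_5050_splits()`,
`balanced_ladder_splits()`, `imbalanced_ladder_splits()`) → regression
(`fit_potency_model()`) → scoring (`decompose_by_subrange()`,
`wilcoxon_pairwise()`), orchestrated by `run_benchmark()` and
`run_ladder()`.

**Representation.** Compounds are 2048-bit binary fingerprints. For real
SMILES, `ecfp4()` computes extended-connectivity fingerprints of bond
diameter 4 with OpenBabel and folds them by bitwise OR to 2048 bits. Bit
assignments are stable within a toolkit version but not across toolkits;
nothing downstream depends on which bits are set, only on Tanimoto
geometry.

**Models.**

* *SVR*: epsilon-insensitive support vector regression on the precomputed
  Tanimoto kernel `K(a, b) = |a∧b| / |a∨b|`, which is positive semidefinite
  on bit vectors. The cost parameter is grid-searched over
  `C ∈ {1, 10, 100, 1000}`; epsilon is fixed at 0.1 (a conventional default;
  the tube width is not a studied parameter here). Fitting uses
  `kernlab::ksvm`. A training set constant to within the tube has the
  all-zero dual solution; it is represented directly as a constant
  predictor.
* *RFR*: random forest regression on the raw bits via `ranger`, searching
  trees `{50, 100, 200}`, minimum samples to split `{2, 3, 5, 10}`, minimum
  samples per leaf `{1, 2, 5, 10}`, and `sqrt`/`log2` feature subsampling
  (`default_grid()`).
* *1-NN / 3-NN*: the potency of the most Tanimoto-similar training
  compound, or the unweighted mean of the top three (averaging is
  unweighted by design; similarity weighting is a different estimator).
  Exact similarity ties are broken by the first compound in a seeded
  shuffle of the training set, making predictions reproducible where a
  naive implementation would depend on input order.
* *MR*: median regression — every test compound receives the training-set
  median. This is the minimiser of MAE among constant predictors, which is
  what makes it the right null: any method that cannot beat it on some
  stratum is not learning on that stratum.

**Model selection.** Grid search uses 3-fold cross-validation on the
training set, minimising MAE (or, as a control, maximising the coefficient
of determination, `cost = "R2"`). When the training set is sub-range
balanced, folds are stratified by sub-range; fold labels cycle across
strata so all folds are populated even with two compounds per sub-range.
Training sets too small to give every fold two compounds fall back to a
single 50/50 train/validation split. Cost ties resolve toward the smaller
`C` or simpler tree — determinism plus parsimony.

**Metrics.** MAE, RMSE, squared Pearson correlation (r²) between observed
and predicted values, and the coefficient of determination (R²) as a
selection control. r² is undefined for constant predictions (MR always is)
and is reported as missing, never as 0. Sub-range records are computed over
test compounds whose *observed* potency falls in the sub-range; the global
MAE is therefore the count-weighted mean of the sub-range MAEs, an identity
the tests assert.

**Significance.** Per-trial metric values of method pairs are compared with
the two-sided Wilcoxon signed-rank test. With ten trials the exact null
distribution matters, so p-values use `stats::psignrank` on the zero-
discarded differences whenever the absolute differences are untied (the
normal approximation with tie correction otherwise). Five methods give
C(5,2) = 10 unordered pairs; the significance threshold 0.005 is the 0.05
family level Bonferroni-corrected for those 10 comparisons.

## Split protocols

* `random_5050_splits()`: ten independent unstratified 50/50 partitions per
  class; odd classes give the extra compound to training.
* `balanced_ladder_splits()`: per trial, nested training sets of sizes
  6, 12, 18, 30, 48, 78, 126, 204, 330 with exactly size/3 compounds per
  sub-range, drawn from a per-sub-range permuted pool of 110. Nesting is a
  design choice: the size-12 set extends the size-6 set, so within a trial
  learning curves reflect added information, not resampling noise
  (`nested = FALSE` draws independently). The test set is fixed per trial:
  compounds outside the 330-pool, balanced with respect to the HIGH
  sub-range, which has the fewest remaining compounds.
* `imbalanced_ladder_splits()`: the control — same total sizes, sampled
  without quotas, test set imbalanced.

Every plan derives its seed from the master seed hashed with class, trial
and protocol (`derive_seed()`), so any table is replayable from
`(input, seed)` alone.

## The synthetic activity-class generator

`generate_activity_class()` emulates the statistical structure of curated
benchmark classes so the full pipeline runs with no external data. It is a
first-class, tested component, not a fixture.

Each class is a set of analogue series. A series owns 10 core fingerprint
bits (set in all members); each compound adds 6 substituent bits from a
shared pool of 384. Potency is

    pIC50 = series base + Σ (per-substituent-bit effects) + N(0, 0.15²),

clipped to [5, 11]. Series bases follow a two-sided mixture: `N(7.5, 0.4)`
with probability 0.65, otherwise `7.5 ± (0.5 + Exp(0.9))` — a central mass
with decaying tails. Per-substituent-bit effects are `N(0, 0.12²)`, drawn
once per class. Defaults were calibrated once to the qualitative shape of
curated classes: unimodal potency distributions with the median inside
[7, 8]; the majority of compounds at intermediate potency; low- and
high-potency bands populated densely near the band edges and sparsely at
the extremes (so the HIGH-band median sits near 9.5, not 10.5, and the
constant predictor's outer-band errors top out around 2 pIC50 units);
within-sub-range pairwise Tanimoto similarity distributions comparable
across sub-ranges, which requires the high-potency band to spread over many
small series rather than a few large ones (top-up sampling founds a new
series in a deficient band with probability 0.6, in batches of 5).

Classes must satisfy the qualification rule (≥ 75 compounds per sub-range
by default; configurable). Top-up sampling is bounded; an unsatisfiable
quota raises an error naming the deficient sub-range.
`generate_benchmark_suite()` perturbs the per-class peak location (± 0.25)
so classes differ in their distributions, as real target sets do.

**What the generator does not emulate.** No chemistry: no valence, no
synthesizability, no matched molecular pairs, no activity cliffs, and
cross-series similarity carries no potency information (in real data,
scaffold families produce weak global structure–potency gradients). Passing
tests on synthetic classes therefore demonstrate that the *pipeline*
reproduces the sub-range mechanism when the data have median-centred
unimodal potency distributions and series-clustered fingerprints; they do
not certify behaviour on any particular real target set. For real data, the
CSV loader (`read_class_csv()` + `curate()`) accepts deposited curated
classes with the same column schema.

## Numerical choices and degenerate inputs

* Sub-range bands are half-open (`[5,7)`, `[7,9)`, `[9,11]`): the
  conventional statement of the bands ("5–6.9, 7–8.9, 9–11") leaves
  (6.9, 7.0) unassigned; half-open intervals cover the continuum. The
  interior boundaries are configurable for sensitivity checks.
* Tanimoto of two all-zero fingerprints is undefined set arithmetic;
  convention: 1.0 (identical objects), configurable to 0.0, always with a
  warning. The generator never emits empty fingerprints.
* Potency clipping at the curation window edges is preferred to rejection;
  the clipped count is recorded as an attribute (`n_clipped`).
* Compounds lacking a molecular mass pass the 1000 Da filter (synthetic
  compounds have no mass).
* All randomness flows through `derive_seed()` (FNV-1a hash, < 2³¹) and a
  pinned RNG kind, so identical inputs give byte-identical outputs across
  platforms and sessions.

## Scaled-down study sizes

The packaged experiments (tests and `scripts/acceptance.R`) run a
desk-scale version of the full design: 3 synthetic classes of ~660+
compounds (≥ 135 per sub-range, so the balanced ladder keeps ≥ 25 test
compounds per sub-range), 10 trials, all five methods. The SVR grid is
searched in full; the RFR search uses `reduced_grid()` — 100 trees and the
corners of the tree-shape range (split 2/10, leaf 1/5) — which preserves
the protocol's ability to adapt tree complexity to training-set size at a
fraction of the 96-combination cost. The full grid remains the default for
`fit_potency_model()`.

## Known limitations

* r² over small sub-range samples is noisy and frequently undefined for
  constant predictors; it is summarised per trial, not pooled, matching how
  such results are usually displayed.
* The exact signed-rank null assumes no ties among absolute differences;
  with ties the implementation switches to the tie-corrected normal
  approximation, adequate at n = 10 only because ties in continuous metric
  values are rare.
* The Bonferroni factor 10 matches the number of method pairs; with a
  different method set the threshold should be re-derived.
* `ecfp4()` depends on the installed OpenBabel; fingerprints serialised to
  CSV are the stable interchange format.

## A minimal run

```{r example, eval = FALSE}
library(potencybench)
suite <- generate_benchmark_suite(3, synth_config(min_per_subrange = 135L,
                                                  n_compounds = 660L),
                                  seed = 1)
bench <- run_benchmark(suite, n_trials = 10, seed = 2, grid = reduced_grid())
ladder <- run_ladder(suite, n_trials = 10, seed = 3, grid = reduced_grid())
plot_ladder(ladder$metrics)
```
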
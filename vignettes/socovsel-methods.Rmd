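---
title: "Multi-block biomarker discovery with socovsel: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-block biomarker discovery with socovsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socovsel)
```

## The model

`socovsel` classifies samples from several blocks of analyte
concentrations — groups of variables measured on different analytical
platforms — using a binary response coded 1 for cases and 0 for controls.
The pipeline has four layers.

**Greedy covariance selection (CovSel).** Given a centered predictor
matrix and a centered response, variables are picked one at a time by the
largest squared covariance with the current response; after each pick both
the predictors and the response are deflated by projecting out the picked
column. The covariance criterion (rather than correlation) means that,
after per-block autoscaling, variables with stronger class separation
dominate regardless of their original measurement units.

**Sequential orthogonalization.** Blocks enter the model in an order that
is itself a tuning parameter. Before block *k* is searched, both the block
and the response are orthogonalized against the span of **all** variables
already selected from earlier blocks, via the projector
`I - S (SᵀS)⁻ Sᵀ` with `S` the accumulated selected columns. Later blocks
can therefore only contribute information the earlier selections do not
already carry; redundancy between platforms is removed by construction
rather than penalized.

**Additive regression and the intercept.** Per stage, ordinary least
squares regresses the current (orthogonalized) response on the stage's
selected, orthogonalized, train-centered columns; the predicted response
is the sum of stage contributions plus a fitted intercept. Because stages
are mutually orthogonal, the stagewise fit equals the joint least-squares
fit on all selected columns. The underlying algebra omits an intercept and
assumes centered data; we fit one anyway so the model remains valid on
uncentered inputs, and it reduces to the response mean (≈ the case
fraction) on autoscaled blocks.

**LDA on the predicted response.** A one-dimensional Gaussian linear
discriminant on the training predictions supplies class means, a pooled
within-class variance (n − 2 denominator) and priors; the decision
threshold is the point of equal discriminant scores — the midpoint of the
class means under equal priors, shifted toward the rarer class's mean
otherwise. Priors default to the empirical class frequencies (the design
is nearly balanced at 11/10); equal priors are available via
`priors = "equal"`. A sample exactly at the threshold is assigned to
class 1.

## Validation design

Model selection (block order and per-block variable counts) and error
estimation are separated by a double cross-validation: the inner loop
(default 5 cancelation groups) scores every candidate on the training
samples of the outer loop; the outer loop (default 21 groups, i.e.
leave-one-out at the design size of 21 samples) provides predictions for
samples that never influenced scaling, selection or coefficients. The
whole procedure is repeated (default 50 times) over fresh random
partitions; with the defaults this yields 1,050 outer models, and we
report mean, SD, min and max over repetitions of the overall accuracy and
of the per-class correct-classification rates. The per-analyte selection
frequency across all outer models is the stability evidence for the final
panel, and the modal block order and complexity summarize what the inner
loop preferred.

Key choices in this layer, and why:

- **Inner-loop score**: the pooled misclassification count over the inner
  folds — the simplest criterion consistent with choosing the smallest
  error. Ties break toward the fewest total selected variables, then the
  earlier entry in the candidate-order list, then lexicographically on
  the complexity tuple; every step is deterministic.
- **Complexity grid**: 0–4 variables per block (the all-zero tuple
  excluded), all block-order permutations. This covers small discriminant
  panels with headroom while keeping the grid at 6 × 5³ − 6 points; a
  custom `grid` or `orders` list can restrict it, and a one-entry grid is
  returned without any cross-validation.
- **Scaling scope**: `scaling = "fold"` (default) refits autoscaling on
  the training rows of every outer and inner fold, so no held-out value
  ever touches the scaler — the leakage-free choice. `scaling = "global"`
  autoscales once on all samples before resampling, reproducing the
  common pretreat-then-validate order of chemometric practice; both modes
  are labeled in the configuration and produce different numbers.
- **Permutation test**: the observed statistic is the rDCV mean accuracy
  at the caller's configuration (a reduced repetition count is sensible
  and recorded in the result); each of the B randomizations permutes the
  labels and recomputes a single DCV run, keeping B = 1,000 tractable.
  The p-value uses the add-one rule, so its floor is 1/(B + 1).
- **Seed ladder**: repetition r runs under `base_seed + r − 1`;
  permutation b under `(base_seed + 104729·b) mod (2³¹ − 1)`. No global
  state is consulted, so identical configurations are bit-reproducible.

## The synthetic generator

`simulate_panel()` emulates the study design the package targets: 21
samples (11 cases, 10 controls) over three serum blocks — 32 amino acids
and derivatives, 23 inflammatory mediators, 4 mitochondrial-derived
vesicle cargo proteins after detection-limit filtering, or the full
assayed 37/31/7 panel with 16 designated analytes fully censored
(`assayed = TRUE`), so `filter_below_lod()` reproduces the 75 → 59
reduction. Mechanics:

- every sample carries a standard-normal latent factor shared across
  blocks with loading `redundancy` (default 0.3), inducing correlation
  within and between blocks;
- each variable is the factor plus independent Gaussian noise, unit
  variance on the latent scale;
- a small planted subset (default 2/2/1 per block, named after plausible
  serum markers at the default widths) adds the standardized effect size
  `effect_size` (default 1.5 SD) to cases **before** any exponentiation,
  so the parameter has the same meaning for both marginal families;
- the lognormal family (default) then places values on plausible per-block
  log-concentration scales with moderate log-scale spreads (0.3/0.4/0.3).
  Larger spreads produce concentration outliers so extreme that
  autoscaled linear discrimination degrades even at large planted shifts,
  breaking the monotone link between `effect_size` and separability that
  the generator is meant to provide; the moderate values keep the effect
  size the dominant dial while remaining within realistic between-subject
  variation for serum analytes.

What the generator does **not** emulate: real covariance structure beyond
one shared factor, age/sex covariates, platform-specific noise models,
partially censored analytes, or — importantly — *complementary* signals
across blocks: all planted variables are proxies of the same class
contrast. Passing tests on this generator therefore demonstrate the
mechanics and honesty of the pipeline (no leakage, correct arithmetic,
chance-level behavior under the null), not that any real panel will be
recovered in full (next section).

## Known limitations

**Redundant informative variables are deliberately pruned.** Because all
planted variables carry the same signal, two of them typically suffice to
fit 21 samples; sequential orthogonalization then removes the remaining
planted variables' apparent signal, and with ~20 inner-loop predictions
the misclassification count frequently reaches zero for several small
complexity tuples, where the parsimony tie-break keeps the smallest. The
modal model on synthetic data thus selects 2–3 variables rather than the
full planted set, and selection frequencies concentrate on the minimal
sufficient subset. On real multi-platform data, where blocks contribute
complementary information, richer complexities win the inner loop; on
exchangeable-proxy data they cannot, and users should read the frequency
table as identifying a minimal panel, not an exhaustive one.

**Degenerate cases.** Zero-variance columns are never selected (their
criterion is 0); a block whose deflated columns are all numerically zero
pads the requested selection with zero-coefficient placeholders inside the
model fit (the exported `covsel_select()` errors instead, as a direct
call requesting more variables than the rank supports is a user mistake).
Inner-loop autoscaling guards fold-constant columns by leaving them at
zero rather than aborting a resampling run; the user-facing `fit_scaler()`
keeps the strict error. All explicit inverses are pseudo-inverses with a
relative singular-value cutoff of 1e−12, chosen because 21 samples make
collinear selections likely.

**Computation.** The inner grid search (all orders × complexity box ×
inner folds) is a C++ kernel that exploits the prefix property of greedy
selection (the c-variable selection is the first c picks of the
c_max-variable selection) and evaluates the whole complexity box of one
order in a single pass per fold; projections use incrementally maintained
orthonormal bases, which equal the pseudo-inverse projections whenever the
selected columns are full rank — the generic case for continuous
concentration data. The R implementation of the fit remains the reference:
outer-loop models are fitted in R, and the test suite asserts exact
agreement of inner-loop error counts between the kernel and an R
re-implementation composed from the public functions. The test suite runs
its resampling checks at reduced sizes (2–10 repetitions, reduced grids)
chosen to exercise every code path while keeping the suite quick; the
figures-of-merit defaults (50 × 21/5) match the design the package
emulates.

## Worked pipeline

```{r example, eval = FALSE}
sim <- simulate_panel(synthetic_config(assayed = TRUE, seed = 42,
                                       effect_size = 2.5))
ds <- filter_below_lod(sim$dataset)          # 75 -> 59 analytes
fit <- run_rdcv(ds, rdcv_config(n_repetitions = 5, base_seed = 42))
glance(fit)                                  # figures of merit
tidy(fit)                                    # selection frequencies
autoplot(fit)                                # per-block frequency chart
pt <- permutation_test(ds, rdcv_config(n_repetitions = 2, base_seed = 42),
                       B = 99)
report_rdcv(fit, "report.md", ds = ds, permutation = pt)
```
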
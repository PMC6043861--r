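---
title: "Processing trajectories for NIR calibration: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing trajectories for NIR calibration: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirtraj)
```

## The problem and the approach

A NIR calibration predicts an analyte concentration from an absorbance
spectrum. Its quality depends jointly on four choices: the spectral
pretreatment, the wavelength regions used, the number of latent factors,
and the calibration method. These choices interact — the best latent-factor
count under a derivative pretreatment is usually not the best under raw
spectra — so optimizing them one at a time (the conventional "stepwise"
routine) explores a tiny, order-dependent slice of the space.

A *processing trajectory* instead enumerates the full Cartesian grid of
combinations, evaluates every path on a held-out validation set, and maps
where the good models live. The output is not just one winner: the
per-band tallies show how robust the modeling problem is (how many paths
reach a usable model), and the comparison with the stepwise baseline
quantifies what greedy optimization leaves on the table. By construction
the exhaustive best can never be worse than the stepwise result, because
the stepwise search ends on a path that is itself a grid point.

## The models

**PLS1 (NIPALS).** Spectra and response are mean-centred (no variance
scaling: absorbance variables share one unit, and autoscaling would
inflate noise channels). Per component the weight vector is the
covariance direction `X'y` normalised to unit length; scores, loadings
and the y-loading follow, and both blocks are deflated. The regression
vector `b = W (P'W)^{-1} q` exploits that `P'W` is unit upper
triangular, so the inverse is a cheap back-substitution, and the
per-component coefficient path comes out of the same decomposition —
that is what makes scoring 1..10 factors in cross-validation affordable.
If deflation degenerates (numerically zero `X'y`), the fit stops early
and flags the model rather than erroring, so a 240-path grid survives
isolated degeneracies.

**Bagging-PLS.** `B` bootstrap resamples (with replacement, same size as
the training set), one PLS1 model each, mean-aggregated predictions. A
resample with a constant response is redrawn (capped) so the ensemble
always has exactly `B` members. The ensemble's validation RMSEP can never
exceed the average member RMSEP (Jensen's inequality for the squared
error of a mean) — the suite asserts this over 20 seeds. Variable
selection runs once, on the full training set, before resampling; all
members share the selected mask. Bagging the selector itself would
confound the comparison between selectors and is out of scope.

**Pretreatments.** Raw passthrough, 9-point Savitzky–Golay smoothing, and
SG first/second derivatives. All are one linear filter family: the SG
kernel is the least-squares projection of a window onto a local
polynomial, evaluated (or differentiated) at the window centre.
Derivatives as SG filters, rather than finite differences, keep the
family consistent and noise-robust. Defaults: window 9, polynomial
order 2 — order 2 is the common chemometric default where only "SG with
9 points" is specified. Output length equals input length: near the
edges the window shrinks to the largest symmetric window that fits, with
the polynomial degree capped at the available point count minus one.
This keeps interval indices aligned across pretreatments (truncation
would shift every interval boundary); its cost is higher variance in the
outermost `(window-1)/2` points, which is immaterial here because
interval scoring always aggregates over many channels. Derivatives are
with respect to the point index — axis spacing is uniform within a
dataset, and only relative model performance matters, so no rescaling is
applied.

**Interval selection.** An equal-width grid (default 20 intervals, the
remainder spread over the first intervals) underlies all three
selectors. Each candidate set is scored by the best RMSECV over factor
counts `1..lv`, where `lv` is the trajectory path's own latent-factor
value — selector and final model thus use a consistent complexity
budget. All candidates within one selector call share a single fold
assignment, so scores are comparable and `SiPLS(combo_size = 1)` is
identically iPLS. BiPLS eliminates backward to a single interval and
returns the global optimum along the elimination path; SiPLS enumerates
all combinations (default pairs) with a hard cap (default 10,000) on the
combination count. Ties are broken toward the lowest interval index /
lexicographically smallest tuple, making every selector fully
deterministic given the seed.

**Metrics.** `RMSEP = sqrt(mean((y - yhat)^2))`;
`RPD = sd(y_val) / RMSEP` with the `n-1` standard deviation and no bias
correction of the error term. "Standard error of prediction over
standard deviation" is ambiguous about bias correction in parts of the
literature; the uncorrected ratio is the more common convention and has
the exactly testable identity `rpd * rmsep = sd(y_val)`. The quality
bands are poor `[0,2)`, fair `[2,3)`, good `[3,3.5)`, very good
`[3.5, Inf)`; the two upper bands are the standard banding for this kind
of assay, the poor/fair split at 2 is an extrapolation used only for
reporting, and the boundary value 3.5 is assigned upward ("greater than
or equal" wins the conflict between "between 3 and 3.5" and "greater
than 3.5").

## Seeding and reproducibility

One master seed in `trajectory_config()` drives everything. The
cross-validation fold assignment derives from it directly and is shared
across all paths, selectors and the stepwise baseline, so candidate
scores are comparable everywhere. Bootstrap draws for a Bagging-PLS path
derive from the master seed plus a deterministic hash of the path's own
(pretreatment, selector, LV, method) coordinates — not from the path's
position in the enumeration — so an identical spec yields a bit-identical
model whether it is evaluated inside the grid, in isolation, or as the
stepwise baseline's final answer. That choice is what makes two report
invariants exact rather than approximate: re-running the best path
reproduces its metrics bit-for-bit, and the stepwise baseline can never
out-perform the grid maximum. All seeded code paths save and restore the
global RNG state.

## The synthetic generator

`generate_synthetic()` draws concentrations uniformly and independently
per component, builds pure spectra as Gaussian bands on the axis, and
returns `X = C S + baseline + noise` with component 1 as the analyte —
a Beer–Lambert linear mixture with a per-sample random polynomial
baseline and i.i.d. Gaussian noise. The tablet-shaped preset
(310 samples x 404 variables, 7,000–10,500 cm⁻¹, four bands near
10,000 / 8,830 / 8,200 / 7,840 cm⁻¹, analyte at 5–10 % w/w, degree-1
baseline at 0.02 AU, noise 0.01 AU ≈ 1 % of peak absorbance) emulates
the acquisition geometry of a public pharmaceutical tablet dataset; the
second preset mirrors a 216 x 2,800 process dataset on a 1,100–2,500 nm
axis whose informative bands sit inside the 1,100–1,900 nm window. The
band widths and concentration ranges were fixed once as field-plausible
values and are not tuned.

What the generator deliberately does not emulate: multiplicative
scatter, heteroscedastic detector noise, instrument drift between
calibration and validation, correlated analyte/excipient concentrations,
and non-linear detector response. Tests passing on synthetic data
therefore demonstrate algorithmic correctness (selectors find planted
bands, the trajectory bookkeeping is exact, dominance holds), not that
any particular real dataset will reach a given RPD. A degree-1 baseline
adds two basis directions to the mixture's rank, which is why the
generator's four-component tablet preset is best fit around six latent
factors rather than four.

## Numerical choices and degenerate inputs

* NIPALS stops a component when `||X'y||` falls below a relative
  tolerance (`1e-12` on the data's scale) and returns the smaller model
  with a warning flag.
* Latent-factor requests are clamped to `min(lv, n_variables,
  n_train - 1)` per fit; cross-validation folds that support fewer
  components than requested are padded with their largest feasible
  prediction so the RMSECV curve is always defined.
* A constant response errors in `fit_pls` but is caught per path: the
  trajectory records a failed `path_result` with the reason and counts
  it in the `failed` band, keeping `sum(class_counts) == n_paths`.
* Perfect predictions make RPD infinite; `rpd()` warns and returns
  `Inf`, which classifies as very good.
* Kennard–Stone breaks distance ties toward the lowest sample index
  (and the lexicographically smallest seed pair), so duplicated spectra
  are allowed and splits are reproducible across platforms.

## Problem sizes in the checks

The packaged checks run on synthetic data sized for a desk machine: the
oracle-equivalence and identity tests use toys of 10–50 samples; the
recovery and dominance properties use 20 replicates of 50–80-sample
datasets with 6–10 intervals; the bookkeeping check runs a 120-path grid
(70 x 100, 10-member ensembles) twice to assert bit-reproducibility; and
the acceptance script runs the full 240-path study grid on the
310 x 404 tablet-shaped preset with 50-member ensembles, which takes a
few minutes on one core.

## Reproducing the original study numbers

The methodology was demonstrated on two laboratory datasets: a public
pharmaceutical tablet set (310 x 404, API % w/w; 207/103 Kennard–Stone
split) and a *Lonicera japonica* ethanol-precipitation set (216 x 2,800,
chlorogenic acid mg/mL, modeled on the 1,100–1,900 nm region with a
144/72 split). The reported best paths were SG(9) + BiPLS + 10 LV +
Bagging-PLS (RMSEP 0.4126 % w/w, RPD 3.2234) for the tablets and
SG(9) + SiPLS + 6 LV + Bagging-PLS (RMSEP 0.0728 mg/mL, RPD 3.9166) for
the process set, against stepwise baselines of raw + iPLS + 3 LV + PLS
(0.5164, 2.5755) and raw + iPLS + 2 LV (0.0891, 3.1966) respectively.

Those datasets cannot be redistributed inside this package, so the
reproduction check in `tests/testthat/test-acceptance.R` activates only
when you place them at `inst/extdata/tablet.csv` and
`inst/extdata/lonicera.csv` in `read_dataset()`'s layout (header row =
`sample_id,reference,<axis positions...>`); it otherwise fails with a
message to that effect. Because the original analysis ran in external
toolboxes whose interval count, cross-validation scheme and ensemble
size are not recorded, the check sweeps `n_intervals ∈ {10, 20, 40}`,
`B ∈ {25, 50, 100}` and 5-fold vs leave-one-out CV, and accepts a
configuration whose four RMSEP/RPD numbers all land within ±15 % of the
reported values. Exact matches are not expected under unrecorded
settings; the tolerance covers the spread those settings induce.

## Known limitations

* PLS1 only (single response); no PLS2, no orthogonal signal correction.
* Selection is restricted to contiguous interval unions; no
  moving-window, genetic-algorithm or per-variable selection.
* No parallel execution: the grid is embarrassingly parallel, but the
  reference implementation stays single-threaded for determinism.
* The stepwise optimizer implements one (documented) step order:
  pretreatment → selector → latent factors → method. Other orders give
  other baselines; all are dominated by the exhaustive grid.
* RPD banding assumes an approximately normal, well-spread validation
  reference distribution; a skewed reference set can make RPD flatter
  than prediction error warrants.
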
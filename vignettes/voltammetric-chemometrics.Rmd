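---
title: "Multivariate calibration of overlapping differential-pulse voltammograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate calibration of overlapping differential-pulse voltammograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltachemo)
```

## The problem and the signal model

Levodopa (LD), carbidopa (CD) and entacapone (ENT) oxidize at a
glassy-carbon electrode at anodic peak potentials of 0.29, 0.28 and
0.46 V. In a differential-pulse scan from 0.00 to +1.30 V at 5 mV steps
(261 points) the LD and CD peaks are separated by only two grid steps and
merge into a single band, with ENT partially overlapping from the right.
Univariate peak-height calibration is impossible for the pair, so
quantification goes through multivariate calibration: a designed set of
ternary mixtures is measured, preprocessed, and regressed against the
nominal concentrations by partial least squares (PLS).

`voltachemo` models each analyte's contribution as a Gaussian in
potential whose apex height is linear in concentration,

$$i_k(E) = (s_k c_k + b_k)\,
  \exp\!\left(-\frac{(E - E_{p,k})^2}{2\sigma_k^2}\right),$$

with slope $s_k$ (current units per mol/L) and intercept $b_k$ taken from
the bundled univariate calibration lines, and a mixture trace as the sum
of the three components plus measurement artifacts. The model is
deliberately phenomenological: it reproduces the statistical structure
the calibration pipeline must cope with (severe overlap, bilinearity,
drift, shift, noise), not the electrode kinetics. Butler–Volmer
mechanisms, pH and scan-rate dependence are out of scope.

### Peak widths

The Gaussian standard deviations default to 0.030 V (LD), 0.050 V (CD)
and 0.045 V (ENT). Two considerations fix these values. First, LD
oxidation at the bare electrode is reversible while CD and ENT are
irreversible; reversible two-electron pulse-voltammetric peaks are
narrow, irreversible ones broad, so a width contrast between the
co-located LD/CD pair is physically expected. Second, the contrast is
what makes the pair mathematically separable in *shape*: with equal
widths the difference between the LD and CD component spectra collapses
(to first order in their 10 mV separation $d$) onto the derivative
direction, $g_C \approx g_L - d\,g_L'$, which is exactly the direction a
one-grid-step alignment error excites — a residual shift of half the
peak separation then becomes indistinguishable from swapping LD and CD
concentration, and no amount of data or latent variables can undo it.
With distinct widths the LD−CD contrast acquires a curvature component
that no rigid shift can mimic, and downstream PLS can absorb occasional
one-step alignment residuals. Equal widths remain available through
`analyte_peak_spec()` for studying exactly this degeneracy.

## The synthetic-data generator

`generate_mixture_set()` adds three artifact classes controlled by
`artifact_spec()`:

* **Baseline drift** — a smooth shape (exponential decay by default,
  `exp(-3u)` over the scan; linear and quadratic alternatives) whose
  per-sample amplitude is drawn uniformly in ±50 % around
  `baseline_scale`. The default scale is 20 % of the largest noiseless
  apex in the set.
* **Potential jitter** — one rigid shift of all peak centres per sample,
  drawn from N(0, `jitter_sd`) and rounded to whole grid steps.
  The default `jitter_sd` = 0.01 V (two steps) is of the same order as
  the run-to-run scatter of the measured peak potentials of these
  analytes.
* **White noise** — i.i.d. Gaussian, default standard deviation 0.05 %
  of the largest noiseless apex.

The noise default deserves its own paragraph, because it is a
calibration, not an arbitrary knob. For a linear signal model the best
possible concentration error of *any* unbiased estimator is set by the
matched filter: with pure-component spectra $S$ the error covariance is
$\sigma^2 (S^\top S)^{-1}$. At 1 % relative noise this floor alone puts
the CD relative prediction error near 10 % — far above the sub-percent
errors a well-conditioned pulsed-voltammetric method achieves after
preprocessing, because pulse sampling suppresses capacitive background
and instrument noise is nanoamps against microamp peaks. At 0.05 %
relative noise the achievable error after full preprocessing lands
around one percent, which is the regime this method family operates in
and the regime all pipeline-level tests and defaults assume.

What the generator does **not** emulate: non-Gaussian and asymmetric
peak shapes, potential-dependent peak widths, adsorption-driven
amplitude drift between runs, correlated (1/f) noise, and non-rigid
(peak-specific) shifts. Passing tests therefore demonstrate that the
pipeline recovers the truth under the stated statistical structure; they
do not certify performance on a real electrode, where shape model error
adds to the budget.

## Preprocessing stages

### airPLS baseline correction

`whittaker_smooth()` solves
$\min_z \sum_i w_i (y_i - z_i)^2 + \lambda \lVert D^{(2)} z\rVert^2$
exactly by a sparse banded factorisation; `airpls_baseline()` rewraps it
in the adaptive reweighting loop: weights start at 1, points above the
running fit are zeroed, points below get weight
$\exp(t\,\lvert d_i\rvert / \sum_{d<0} \lvert d\rvert)$, the endpoints
are pinned to the maximum weight, and iteration stops when the
negative-residual mass falls below 0.1 % of the total absolute signal or
at 15 iterations (the iteration count is a cap combined with this
convergence test, the standard reading of the algorithm). Defaults
λ = 10⁵, order 2, 15 iterations. λ is defined on the index grid, not in
volts: users who change the grid density should rescale λ by roughly the
fourth power of the point-density ratio. The corrected signal is
`y - baseline` exactly, so the decomposition is lossless by
construction. One practical limit worth knowing: with λ = 10⁵ the
smoother cannot follow very sharp baseline curvature near the first few
points of the scan, so a fast-decaying background leaves a small
residual spike at the trace start.

### icoshift alignment

Traces are split into consecutive intervals of `interval_width` points
(default 800 — wider than the 261-point trace, so the whole trace is one
interval and alignment is a single rigid shift per sample); each
interval is shifted by the integer in ±`max_shift` maximising the inner
product with the mean-centred target segment, edges refilled with the
edge value. Ties break toward smaller then more negative shifts so an
aligned segment stays put. The default target is the average
voltammogram, recomputed and realigned until a fixed point (≤ 5 passes):
a single pass against the smeared average of misaligned traces reliably
leaves one-step errors that the sharpened target of a second pass
resolves.

Two intrinsic limitations of correlation-to-consensus alignment on this
chemistry are documented rather than hidden. First, the cross-correlation
of the merged LD/CD band has a nearly flat top, and when a sample's
LD/CD ratio differs strongly from the target's, the discrete argmax can
genuinely sit one step off even for perfectly aligned data (a gain of
only ~0.1–0.2 % in correlation, against ≥ 1 % for undoing a real
one-step misalignment). The optional `min_gain` margin (the "flat-top
guard") exploits that gap to keep alignment inert on already-aligned
data; it is off by default because under realistic artifacts it also
freezes genuine one-step corrections against partially blurred targets.
Second, as a consequence, on jittered ternary sets a few samples per
design (typically 2–6 of 25) settle one step off the consensus offset.
With the width-contrasted peak model these residuals are absorbed by the
PLS step at the cost of some precision on CD; with equal widths they
would be fatal (see above). Sub-step (interpolated) shifts are a
non-goal, matching the insertion/deletion model of the reference
algorithm.

### Savitzky–Golay filtering and scaling

`sg_coefficients()` derives the convolution weights from the local
polynomial least-squares fit (window 15, order 2, first derivative by
default — the derivative removes any additive offset that survives
baseline correction). Edge points refit the polynomial on the truncated
asymmetric window so the trace keeps its length; derivatives are scaled
by the grid step, giving current units per volt. Window and order are
not dictated by the reference workflow (the SIMCA-internal settings are
unrecoverable); 15/2/1 suppresses the synthetic noise floor while
leaving the 30–50 mV peaks intact, and all three are configurable.

The pipeline applies SG to the spectra first and a single column-scaling
step afterwards, defaulting to pareto scaling
($x \mapsto (x - \bar x)/\sqrt{s}$) on the X block inside the PLS fit —
the source workflow states both "autoscaling then SG" and "pareto
scaled" in different places; pareto-at-the-PLS-stage is the reading
adopted, with `center` and `autoscale` available. The Y block is
autoscaled, which also makes predictions exactly invariant to the units
of each analyte's concentrations.

## Design, split and calibration

`brereton_design(5, 3)` builds the 25-run multilevel partial factorial
over the field of order 5: runs are indexed by pairs $(a, b)$, factor
$j$ takes level $b + f_j a$ in field arithmetic, so the first factor
cycles the base level sequence and the others are its cyclic
permutations. Every level appears exactly five times per factor and all
pairwise factor correlations are exactly zero — these invariants, not a
specific row order, are the contract. Prime orders 2, 3, 5, 7 use
modular arithmetic; order 4 uses GF(4). Level codes map affinely onto
each analyte's univariate linear range (code −2 at the low end, +2 at
the high end).

The 16/9 calibration/validation split is a seeded draw that retries (up
to 1000 candidates) until both subsets contain every level of every
factor, recording whether full balance was reached; the authors' actual
membership is unpublished, so a reproducible seeded split is the honest
substitute.

`pls_fit()` is classical NIPALS PLS2: the inner loop converges when the
score vector changes by less than 1e-10 relative (cap 500, a hit is
recorded but the component kept), deflation is by the X-scores, and
coefficients assemble as $B = W (P^\top W)^{-1} Q^\top$ on the scaled
blocks. NIPALS rather than SIMPLS because the score-space diagnostics
need both $T$ and $U$. Component extraction stops early if either
deflated block hits numerical zero. Cross-validation is leave-one-out by
default (deterministic and standard at n = 16; seeded venetian-blind
k-fold available), refitting scaling and model per fold; the LV count is
the smallest whose pooled (root-mean-square across analytes) RMSECV is
within `lv_tol` = 2 % of the curve minimum — the operational form of
"not significantly greater than the model with one more factor". On the
default synthetic study this rule lands on seven latent variables: three
concentration directions plus components absorbing residual shift and
baseline structure.

## Validation statistics

* `error_stats()`: RMSE $= \sqrt{\sum (y_{pred}-y_{act})^2/n}$ and
  REP% $= 100\,\mathrm{RMSE}/\bar y_{act}$, with the identity between
  them enforced on every report.
* `cv_anova()`: the response scaled to unit variance (total corrected
  SS = n−1), residual SS from the cross-validated predictions,
  regression SS by difference; MS = SS/DF, F = MS_reg/MS_res, upper-tail
  F probability, and a SD column equal to √MS (the most defensible
  reading of that column). The degrees-of-freedom convention for
  cross-validated ANOVA is contested, so DF_regression is a parameter
  (default ⅘ of DF_total, rounded); `cv_anova_from_ss()` assembles the
  table from explicit SS/DF when those are known.
* `permutation_test()`: 40 permutations by default; R² on the training
  fit and Q² = 1 − PRESS/SS by the same CV scheme, regressed against the
  absolute correlation between permuted and original response with the
  original model included at correlation 1. A valid model shows its
  original Q² above every permuted one and a negative Q² intercept. Note
  that with hundreds of variables and 16 samples the *training* R² of
  permuted models stays near 1, so the R² intercept is high by
  construction; Q² carries the validity signal.
* `leverages()` and `hotelling_t2()`: projector diagonals of the T and U
  blocks (so X-leverages sum to the LV count and lie in [0, 1]), and
  $T^2_i = \sum_a t_{ia}^2/s_a^2$ with the small-sample critical value
  $\frac{A(N-1)(N+1)}{N(N-A)} F_{1-\alpha}(A, N-A)$.
* `standardized_residuals()`: raw residual divided by the
  root-mean-square residual (the n-denominator form, so alternating unit
  residuals standardize to exactly ±1), flags at |z| > 2, plus
  normal-probability plotting coordinates.

Validation **recovery** is reported per analyte as
$100\,\overline{y}_{pred}/\overline{y}_{act}$ (ratio of means). The
per-sample ratio is not used because the design's lowest ENT level
(3.2 µmol/L) is an order of magnitude below the typical absolute
prediction error's parent scale, making per-sample ratios at that level
arbitrarily noisy; the ratio of means is the stable pooled estimator of
the same quantity.

## Greenness and method comparison

`eco_scale()` subtracts summed penalty points from 100 and classifies
(100 ideal; > 75 great green; 50–75 acceptable; < 50 inadequate). The
item catalogs for the direct voltammetric method (score 90) and the
comparison HPLC method (score 77) ship as data frames; the full
eco-scale reagent catalog does not — penalties are user inputs.
`pooled_t_test()` and `variance_ratio_test()` work from
mean/SD/variance/n summaries; F is always the larger variance over the
smaller. Tabulated critical values are inputs, not computed defaults:
the bundled comparison uses the printed 2.132 and 6.39, and the fact
that 2.132 corresponds to 4 rather than the pooled 8 degrees of freedom
is preserved as given, not second-guessed.

## The pipeline and the preprocessing ladder

`run_pipeline()` chains design → simulation → airPLS → icoshift → SG →
split → CV/LV selection → fit → prediction → validation suite → a
fixed-ratio dosage-form emulation (a 200:50:200 mass ratio mapped into
the linear ranges, three replicate "tablet" measurements preprocessed
with the calibration-set alignment target and predicted as unknowns).
Everything derives from one seed; the same configuration reproduces
every output byte for byte, and `write_pipeline_config()` /
`read_pipeline_config()` round-trip the configuration through JSON. With
an output directory, every intermediate matrix is written as CSV along
with a JSON report and a manifest of parameters and file hashes.

`reproduce_preprocessing_ladder()` refits the calibration at four states
— raw, airPLS, airPLS + icoshift, + SG — reselecting the LV count at
each state. On default synthetic data the pooled relative error
collapses from tens of percent on raw drifting, jittered data to the
percent level after the full chain; the baseline-only stage can be
*worse* than raw (the corrected-but-misaligned state exposes the shift
problem more than the raw one), which is characteristic of this
workflow. ENT, riding alone at 0.46 V, is often predicted adequately
even from raw data; the ladder's value is what it does to the merged
LD/CD pair. The airPLS → icoshift order follows the workflow listing;
the opposite order is one configuration change.

## Problem sizes and determinism

The test suite runs the full study at its native size (25 mixtures × 261
points, 16/9 split) — single runs take a few seconds — and uses reduced
repetition counts where repetition is the point: 5-seed recovery checks,
10-seed permutation-validity checks at 12–15 permutations, 40-seed
slope-unbiasedness checks. Oracle-equivalence tests (Whittaker vs dense
solve, alignment vs brute force, SG vs explicit least squares, NIPALS vs
pseudo-inverse, leverage/T² vs dense algebra) run on ≤ 20-sample
instances. All stochastic stages restore the caller's RNG state, so
library code never perturbs a user's random stream.

## Known limitations

* Correlation alignment cannot resolve sub-step shifts and can leave
  one-step residuals on extreme-composition samples (see above); CD,
  the broadest and most overlapped peak, pays the precision cost, and
  its validation REP can exceed the 2 % that LD and ENT reliably reach.
* The CV-ANOVA DF convention and the Table-style SD column follow one
  defensible reading; other software may differ.
* The eco-scale classifier implements the published thresholds verbatim,
  which leave a boundary ambiguity at exactly 75 points (classified
  acceptable here).
* The generator's Gaussian, rigid-shift world is a model; see the
  generator section for what is deliberately not emulated.
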
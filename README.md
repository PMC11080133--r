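# voltachemo

Chemometric resolution of overlapping differential-pulse voltammograms.

Levodopa (LD), carbidopa (CD) and entacapone (ENT) — the standard triple
therapy for Parkinson's disease — all oxidize on a glassy-carbon electrode
between 0.2 and 0.6 V, with the LD and CD anodic peaks only 10 mV apart
(Ep 0.29, 0.28 and 0.46 V). Their differential-pulse voltammograms (DPV)
therefore cannot be resolved peak by peak. `voltachemo` implements the
complete multivariate-calibration workflow that quantifies all three
analytes from a single scan, for analysts who want a tested, scriptable
version of a pipeline usually spread across MATLAB and SIMCA:

1. **Synthetic DPV generation** — Gaussian oxidation peaks whose apex is
   linear in concentration (`slope * c + intercept`, per-analyte
   calibration-line parameters bundled), plus drifting baseline, per-run
   potential jitter and white noise, on the 0.00–1.30 V / 5 mV grid
   (261 points).
2. **airPLS** baseline correction — adaptive iteratively reweighted
   penalized least squares: a Whittaker smoother
   (min Σ wᵢ(yᵢ−zᵢ)² + λ‖D²z‖², λ = 10⁵, ≤ 15 reweighting iterations)
   whose weights converge onto the signal's lower envelope.
3. **icoshift** alignment — interval-wise rigid integer shifts maximising
   cross-correlation with the average voltammogram (the default 800-point
   interval spans the whole 261-point trace, i.e. one rigid shift per
   sample).
4. **Savitzky–Golay** first-derivative filtering (window 15, order 2) and
   pareto scaling.
5. **Brereton design** — the 5-level × 3-factor cyclic partial factorial:
   25 mixtures, every level balanced, factor columns exactly orthogonal;
   split 16 calibration / 9 validation.
6. **NIPALS PLS2** with leave-one-out RMSECV latent-variable selection
   (smallest A with pooled RMSECV within 2 % of the curve minimum).
7. **Validation suite** — RMSECV/RMSEP and REP% (RMSE as a percentage of
   the mean nominal level), nominal-vs-predicted R², CV-ANOVA F-test on
   cross-validated residuals, response-permutation testing (R²/Q²
   intercepts), leverages diag T(TᵀT)⁻¹Tᵀ and diag U(UᵀU)⁻¹Uᵀ,
   Hotelling T², standardized residuals with normal-probability
   coordinates.
8. **Greenness and method comparison** — analytical eco-scale scoring
   (100 − penalty points) and pooled-variance t / variance-ratio F tests
   between two methods' recovery summaries.

## Worked example

```r
library(voltachemo)

cfg    <- pipeline_config(seed = 1)   # the default synthetic study
report <- run_pipeline(cfg)

report$n_lv
#> [1] 7

round(report$validation$recovery, 2)         # 100 * mean(pred)/mean(nominal)
#>     LD     CD    ENT
#>  99.88 100.50 100.44

signif(sapply(report$validation$per_analyte,
              function(s) c(RMSEP = s$rmse, REP_percent = s$rep_percent)), 3)
#>                   LD       CD      ENT
#> RMSEP       4.51e-06 7.76e-06 2.06e-06
#> REP_percent 1.20e+00 3.53e+00 1.31e+00

round(sapply(report$permutation, function(p) p$q2_intercept), 2)
#>    LD    CD   ENT
#> -1.57 -1.25 -1.48
```

Seven latent variables are selected (three concentrations plus components
absorbing residual shift and baseline structure). Validation-set
recoveries sit within ±0.5 % of nominal; the RMSEP values are in mol/L,
and REP% expresses them relative to the mean nominal level of the 9
validation mixtures. Negative permutation Q² intercepts confirm the model
is not a chance correlation. `reproduce_preprocessing_ladder(cfg)` refits
the model on raw, baseline-corrected, aligned and derivative-filtered
data and shows the relative error collapsing from tens of percent (raw)
to the percent level (fully preprocessed).

The greenness and comparison tools work directly from printed summaries:

```r
eco_scale(eco_items_voltammetric())
#> <eco_scale_sheet> 10 penalty points, score 90 (great green)

tt <- pooled_t_test(method_summary(99.76, 0.79, n = 5),
                    method_summary(100.13, 0.65, n = 5), t_critical = 2.132)
sprintf("t = %.2f on %d df: %s", tt$t, tt$df, tt$verdict)
#> [1] "t = -0.81 on 8 df: no significant difference"
```

## Documentation

The methods vignette (`vignettes/voltammetric-chemometrics.Rmd`) explains
the signal model, every preprocessing stage and its parameters, the
design and PLS machinery, the validation statistics, the synthetic
generator's calibration, and the package's known limitations — including
the one-grid-step ambiguity intrinsic to correlation alignment of heavily
overlapped peaks.
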
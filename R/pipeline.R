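#' Pipeline configuration
#'
#' Assembles the full configuration of the synthetic-study pipeline:
#' potential grid, analyte peak parameters, measurement artifacts,
#' preprocessing settings (airPLS, icoshift, Savitzky-Golay), calibration
#' design and split, PLS/cross-validation settings and validation options.
#' The object is a plain nested list of scalars and vectors so that it
#' round-trips losslessly through its JSON file representation
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' Every stochastic stage derives its seed from the single `seed` field.
#'
#' @param seed master integer seed.
#' @param grid list(start, stop, step) in volts.
#' @param analytes list of per-analyte parameter lists (name, ep, width,
#'   slope, intercept, linear_range); default the bundled LD/CD/ENT set.
#' @param artifacts list(baseline_kind, baseline_scale, jitter_sd,
#'   noise_sd); `NULL` scale entries mean the generator's relative
#'   defaults.
#' @param airpls list(lam, max_iter, diff_order, conv_ratio).
#' @param icoshift list(interval_width, max_shift, target_mode, fill_mode,
#'   passes, min_gain); see [icoshift_params()].
#' @param sg list(window, polyorder, deriv).
#' @param design list(n_levels, n_factors).
#' @param split list(n_cal, n_val).
#' @param pls list(max_lv, scheme, k, lv_tol, x_scaling, y_scaling).
#' @param validation list(alpha, n_perm, run_permutation).
#' @param tablet list(ratio, frac, n_rep) for the fixed-ratio dosage-form
#'   emulation (mass ratio mapped into the linear ranges; `n_rep`
#'   replicate measurements), or `NULL` to skip it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            grid = list(start = 0, stop = 1.3, step = 0.005),
                            analytes = NULL,
                            artifacts = list(baseline_kind = "exponential",
                                             baseline_scale = NULL,
                                             jitter_sd = 0.01,
                                             noise_sd = NULL),
                            airpls = list(lam = 1e5, max_iter = 15,
                                          diff_order = 2, conv_ratio = 1e-3),
                            icoshift = list(interval_width = 800,
                                            max_shift = "best",
                                            target_mode = "average",
                                            fill_mode = "edge",
                                            passes = 5, min_gain = 0),
                            sg = list(window = 15, polyorder = 2, deriv = 1),
                            design = list(n_levels = 5, n_factors = 3),
                            split = list(n_cal = 16, n_val = 9),
                            pls = list(max_lv = 8, scheme = "loo", k = 7,
                                       lv_tol = 0.02, x_scaling = "pareto",
                                       y_scaling = "autoscale"),
                            validation = list(alpha = 0.05, n_perm = 40,
                                              run_permutation = TRUE),
                            tablet = list(ratio = c(200, 50, 200),
                                          frac = 0.5, n_rep = 3)) {
  if (is.null(analytes)) {
    analytes <- lapply(unname(default_analyte_specs()), function(s)
      list(name = s$name, ep = s$ep, width = s$width, slope = s$slope,
           intercept = s$intercept, linear_range = s$linear_range))
  }
  structure(list(seed = as.integer(seed), grid = grid, analytes = analytes,
                 artifacts = artifacts, airpls = airpls,
                 icoshift = icoshift, sg = sg, design = design,
                 split = split, pls = pls, validation = validation,
                 tablet = tablet),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  raw$analytes <- lapply(raw$analytes, function(a) {
    a$linear_range <- as.numeric(a$linear_range)
    a
  })
  if (!is.null(raw$tablet)) raw$tablet$ratio <- as.numeric(raw$tablet$ratio)
  do.call(pipeline_config, raw)
}

# materialise config sub-lists into the stage parameter objects
config_specs <- function(config) {
  specs <- lapply(config$analytes, function(a)
    analyte_peak_spec(a$name, ep = a$ep, slope = a$slope,
                      intercept = a$intercept,
                      linear_range = a$linear_range, width = a$width))
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  specs
}

config_stage_params <- function(config) {
  list(
    grid = potential_grid(config$grid$start, config$grid$stop,
                          config$grid$step),
    airpls = airpls_params(config$airpls$lam, config$airpls$max_iter,
                           config$airpls$diff_order,
                           config$airpls$conv_ratio),
    icoshift = icoshift_params(config$icoshift$interval_width,
                               config$icoshift$max_shift,
                               config$icoshift$target_mode,
                               config$icoshift$fill_mode,
                               passes = config$icoshift$passes,
                               min_gain = config$icoshift$min_gain),
    sg = sg_params(config$sg$window, config$sg$polyorder, config$sg$deriv))
}

# per-analyte prediction statistics on a validation block
validation_stats_block <- function(pred, nominal) {
  analytes <- colnames(nominal)
  stats <- lapply(seq_along(analytes), function(j)
    error_stats(pred[, j], nominal[, j]))
  names(stats) <- analytes
  recovery <- vapply(seq_along(analytes), function(j)
    100 * mean(pred[, j]) / mean(nominal[, j]), numeric(1))
  names(recovery) <- analytes
  list(per_analyte = stats, recovery = recovery)
}

#' Run the full synthetic calibration study
#'
#' Executes the whole workflow on synthetic data: design generation,
#' mixture-set simulation, airPLS baseline correction, icoshift alignment,
#' Savitzky-Golay filtering, calibration/validation split, cross-validated
#' latent-variable selection, PLS fitting, validation-set prediction, and
#' the validation/diagnostic suite (error statistics, CV-ANOVA, optional
#' permutation test, leverages, Hotelling T2, standardized residuals),
#' plus a fixed-ratio dosage-form emulation predicted as unknowns.
#' Deterministic given the configuration.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every intermediate matrix
#'   (CSV), the reports (JSON) and a manifest with parameters and stage
#'   file hashes are written there.
#' @return The report: a nested list with elements `design`, `split`,
#'   `n_lv`, `cv`, `calibration`, `validation`, `diagnostics`, `cv_anova`,
#'   `permutation` (if enabled) and `tablet`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sp <- config_stage_params(config)
  specs <- config_specs(config)

  design <- brereton_design(config$design$n_levels, config$design$n_factors)
  ranges <- lapply(specs, function(s) s$linear_range)
  conc <- map_levels_to_concentrations(design, ranges)

  art <- artifact_spec(baseline_kind = config$artifacts$baseline_kind,
                       baseline_scale = config$artifacts$baseline_scale,
                       jitter_sd = config$artifacts$jitter_sd,
                       noise_sd = config$artifacts$noise_sd,
                       seed = config$seed)
  gen <- generate_mixture_set(conc, specs, art, sp$grid)

  corrected <- airpls_correct_set(gen$set, sp$airpls)
  ali <- icoshift_align(corrected, sp$icoshift)
  filtered <- sg_filter_set(ali$set, sp$sg)

  split <- split_calibration_validation(conc, config$split$n_cal,
                                        config$split$n_val,
                                        seed = config$seed)
  cal_i <- match(split$cal, conc$samples)
  val_i <- match(split$val, conc$samples)
  Xcal <- filtered$matrix[cal_i, , drop = FALSE]
  Xval <- filtered$matrix[val_i, , drop = FALSE]
  Ycal <- conc$values[cal_i, , drop = FALSE]
  Yval <- conc$values[val_i, , drop = FALSE]

  cv <- cross_validate(Xcal, Ycal, max_lv = config$pls$max_lv,
                       scheme = config$pls$scheme, k = config$pls$k,
                       seed = config$seed,
                       x_scaling = config$pls$x_scaling,
                       y_scaling = config$pls$y_scaling)
  n_lv <- select_n_lv(cv, tol = config$pls$lv_tol)
  fit <- pls_fit(Xcal, Ycal, n_lv = n_lv,
                 x_scaling = config$pls$x_scaling,
                 y_scaling = config$pls$y_scaling)

  pred_cal <- pls_predict(fit, Xcal)
  pred_val <- pls_predict(fit, Xval)
  cal_stats <- validation_stats_block(pred_cal, Ycal)
  val_stats <- validation_stats_block(pred_val, Yval)

  lev <- leverages(fit)
  t2 <- hotelling_t2(fit, alpha = config$validation$alpha)
  resid_diag <- lapply(seq_len(ncol(Yval)), function(j)
    standardized_residuals(pred_val[, j], Yval[, j]))
  names(resid_diag) <- conc$analytes

  anova_tables <- lapply(seq_len(ncol(Ycal)), function(j) {
    y <- Ycal[, j]
    ys <- (y - mean(y)) / stats::sd(y)
    res_scaled <- (cv$pred[[n_lv]][, j] - y) / stats::sd(y)
    cv_anova(ys, res_scaled)
  })
  names(anova_tables) <- conc$analytes

  perm <- NULL
  if (isTRUE(config$validation$run_permutation)) {
    perm <- lapply(seq_len(ncol(Ycal)), function(j)
      permutation_test(Xcal, Ycal[, j], n_lv = n_lv,
                       n_perm = config$validation$n_perm,
                       seed = config$seed + j,
                       scheme = config$pls$scheme, k = config$pls$k))
    names(perm) <- conc$analytes
  }

  tablet <- NULL
  if (!is.null(config$tablet)) {
    tablet <- predict_tablet(config, specs, sp, fit, ali$target)
  }

  report <- list(
    config = unclass(config),
    design = design, concentrations = conc, split = split,
    n_lv = n_lv, cv = list(rmsecv = cv$rmsecv, scheme = cv$scheme),
    calibration = cal_stats, validation = val_stats,
    diagnostics = list(leverage = lev, hotelling = t2,
                       residuals = resid_diag),
    cv_anova = anova_tables, permutation = perm, tablet = tablet,
    predictions = list(calibration = pred_cal, validation = pred_val))

  if (!is.null(out_dir)) write_run_outputs(report, gen, corrected, ali,
                                           filtered, out_dir)
  report
}

# fixed-ratio dosage-form emulation: replicate unknowns at a mass ratio
# mapped into the linear ranges, measured with the study artifacts and
# preprocessed with the calibration-set alignment target
predict_tablet <- function(config, specs, sp, fit, target) {
  ratio <- as.numeric(config$tablet$ratio)
  frac <- config$tablet$frac * ratio / max(ratio)
  concs <- vapply(seq_along(specs), function(k) {
    r <- specs[[k]]$linear_range
    r[1] + frac[k] * (r[2] - r[1])
  }, numeric(1))
  n_rep <- config$tablet$n_rep
  tab <- conc_table(matrix(rep(concs, each = n_rep), nrow = n_rep),
                    samples = paste0("T", seq_len(n_rep)),
                    analytes = vapply(specs, `[[`, character(1), "name"))
  art <- artifact_spec(baseline_kind = config$artifacts$baseline_kind,
                       baseline_scale = config$artifacts$baseline_scale,
                       jitter_sd = config$artifacts$jitter_sd,
                       noise_sd = config$artifacts$noise_sd,
                       seed = config$seed + 104729L)
  gen <- generate_mixture_set(tab, specs, art, sp$grid)
  corrected <- airpls_correct_set(gen$set, sp$airpls)
  ali <- icoshift_align(corrected, sp$icoshift, target = target)
  filtered <- sg_filter_set(ali$set, sp$sg)
  pred <- pls_predict(fit, filtered$matrix)
  rec <- sweep(pred, 2, concs, `/`) * 100
  list(nominal = concs, predictions = pred,
       recovery_mean = colMeans(rec),
       recovery_sd = apply(rec, 2, stats::sd))
}

write_run_outputs <- function(report, gen, corrected, ali, filtered,
                              out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_conc_table(report$concentrations, p("concentrations.csv"))
  write_voltammogram_set(gen$set, p("voltammograms_raw.csv"))
  write_voltammogram_set(corrected, p("voltammograms_airpls.csv"))
  write_voltammogram_set(ali$set, p("voltammograms_aligned.csv"))
  write_voltammogram_set(filtered, p("voltammograms_filtered.csv"))
  utils::write.csv(ali$shifts, p("shift_table.csv"))
  utils::write.csv(report$cv$rmsecv, p("rmsecv.csv"))
  utils::write.csv(report$predictions$validation, p("predictions_validation.csv"))
  summary <- list(
    seed = report$config$seed,
    n_lv = report$n_lv,
    cv_scheme = report$cv$scheme,
    split = report$split,
    validation_recovery = as.list(report$validation$recovery),
    validation_rmsep = lapply(report$validation$per_analyte,
                              function(s) s$rmse),
    validation_rep_percent = lapply(report$validation$per_analyte,
                                    function(s) s$rep_percent),
    permutation_q2_intercepts = if (!is.null(report$permutation))
      lapply(report$permutation, function(x) x$q2_intercept) else NULL,
    tablet_recovery = if (!is.null(report$tablet))
      as.list(report$tablet$recovery_mean) else NULL)
  jsonlite::write_json(summary, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(config = report$config,
                   package_version = as.character(
                     utils::packageVersion("voltachemo")),
                   files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' RMSEP at each preprocessing stage
#'
#' Refits the calibration at four preprocessing states of the same
#' synthetic data set — raw, baseline-corrected (airPLS), additionally
#' aligned (icoshift), and additionally derivative-filtered (SG) — and
#' reports the validation-set RMSEP and REP% per analyte at each stage,
#' with the LV count reselected by cross-validation at every stage.
#'
#' @param config a [pipeline_config()].
#' @return Data frame with columns `stage`, `analyte`, `rmsep`,
#'   `rep_percent`, `n_lv`; stages ordered raw, airpls,
#'   airpls_icoshift, airpls_icoshift_sg.
#' @export
reproduce_preprocessing_ladder <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  sp <- config_stage_params(config)
  specs <- config_specs(config)
  design <- brereton_design(config$design$n_levels, config$design$n_factors)
  conc <- map_levels_to_concentrations(design,
                                       lapply(specs, function(s)
                                         s$linear_range))
  art <- artifact_spec(baseline_kind = config$artifacts$baseline_kind,
                       baseline_scale = config$artifacts$baseline_scale,
                       jitter_sd = config$artifacts$jitter_sd,
                       noise_sd = config$artifacts$noise_sd,
                       seed = config$seed)
  gen <- generate_mixture_set(conc, specs, art, sp$grid)
  corrected <- airpls_correct_set(gen$set, sp$airpls)
  ali <- icoshift_align(corrected, sp$icoshift)
  filtered <- sg_filter_set(ali$set, sp$sg)
  stages <- list(raw = gen$set$matrix,
                 airpls = corrected$matrix,
                 airpls_icoshift = ali$set$matrix,
                 airpls_icoshift_sg = filtered$matrix)

  split <- split_calibration_validation(conc, config$split$n_cal,
                                        config$split$n_val,
                                        seed = config$seed)
  cal_i <- match(split$cal, conc$samples)
  val_i <- match(split$val, conc$samples)
  out <- NULL
  for (nm in names(stages)) {
    X <- stages[[nm]]
    Xcal <- X[cal_i, , drop = FALSE]; Xval <- X[val_i, , drop = FALSE]
    Ycal <- conc$values[cal_i, , drop = FALSE]
    Yval <- conc$values[val_i, , drop = FALSE]
    cv <- cross_validate(Xcal, Ycal, max_lv = config$pls$max_lv,
                         scheme = config$pls$scheme, k = config$pls$k,
                         seed = config$seed,
                         x_scaling = config$pls$x_scaling,
                         y_scaling = config$pls$y_scaling)
    n_lv <- select_n_lv(cv, tol = config$pls$lv_tol)
    fit <- pls_fit(Xcal, Ycal, n_lv = n_lv,
                   x_scaling = config$pls$x_scaling,
                   y_scaling = config$pls$y_scaling)
    pred <- pls_predict(fit, Xval)
    for (j in seq_len(ncol(Yval))) {
      es <- error_stats(pred[, j], Yval[, j])
      out <- rbind(out, data.frame(stage = nm, analyte = conc$analytes[j],
                                   rmsep = es$rmse,
                                   rep_percent = es$rep_percent,
                                   n_lv = n_lv))
    }
  }
  rownames(out) <- NULL
  out
}
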
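#' Analyte peak specification
#'
#' Describes one analyte's oxidation peak: a Gaussian of standard deviation
#' `width` (V) centred at the anodic peak potential `ep`, whose apex height
#' is linear in concentration, `slope * conc + intercept` (current units,
#' concentration in mol/L).  The bundled defaults
#' ([default_analyte_specs()]) carry the univariate calibration parameters
#' of levodopa (LD), carbidopa (CD) and entacapone (ENT) on a glassy-carbon
#' electrode.
#'
#' @param name analyte label.
#' @param ep anodic peak potential (V).
#' @param slope calibration slope (current units per mol/L).
#' @param intercept calibration intercept (current units).
#' @param linear_range length-2 numeric, (low, high) linear range in mol/L.
#' @param width Gaussian standard deviation of the peak (V).  The default
#'   0.045 V makes the 0.29/0.28 V pair overlap almost completely and the
#'   0.46 V peak overlap partially, as in measured ternary mixtures.  The
#'   bundled analytes override it per analyte: levodopa oxidizes reversibly
#'   (two-electron, narrower pulse-voltammetric peak, 0.030 V) while
#'   carbidopa and entacapone are irreversible at the glassy-carbon surface
#'   (slower electron transfer, broader peaks, 0.050 and 0.045 V).  The
#'   width contrast between the co-located LD/CD pair is what makes their
#'   severely overlapped signals separable in shape and not only in the
#'   0.01 V positional offset.
#' @return An object of class `analyte_peak_spec`.
#' @export
analyte_peak_spec <- function(name, ep, slope, intercept, linear_range,
                              width = 0.045) {
  stopifnot(is.character(name), length(linear_range) == 2)
  if (width <= 0) stop("peak width must be > 0", call. = FALSE)
  if (linear_range[1] >= linear_range[2]) {
    stop("linear_range low must be below high", call. = FALSE)
  }
  structure(list(name = name, ep = ep, width = width, slope = slope,
                 intercept = intercept,
                 linear_range = as.numeric(linear_range)),
            class = "analyte_peak_spec")
}

#' Default analyte peak specifications (LD, CD, ENT)
#'
#' Univariate calibration parameters of the three anti-parkinsonian drugs:
#' peak potentials 0.29, 0.28 and 0.46 V; slopes 0.0681, 0.0576, 0.0611
#' current units per mol/L; intercepts -2.76e-7, 4.39e-6, 2.09e-5; and their
#' respective linear ranges.
#'
#' @return Named list of three [analyte_peak_spec()] objects.
#' @export
default_analyte_specs <- function() {
  list(
    LD  = analyte_peak_spec("LD",  ep = 0.29, slope = 0.0681,
                            intercept = -2.76e-7,
                            linear_range = c(4.00e-5, 9.00e-4),
                            width = 0.030),
    CD  = analyte_peak_spec("CD",  ep = 0.28, slope = 0.0576,
                            intercept = 4.39e-6,
                            linear_range = c(6.48e-5, 4.63e-4),
                            width = 0.050),
    ENT = analyte_peak_spec("ENT", ep = 0.46, slope = 0.0611,
                            intercept = 2.09e-5,
                            linear_range = c(3.20e-6, 4.00e-4),
                            width = 0.045))
}

#' Measurement-artifact specification
#'
#' Controls the non-bilinear structure added to synthetic mixture sets:
#' a smooth per-sample baseline drift, a rigid per-sample potential shift
#' (jitter, rounded to whole grid steps), and additive white noise.
#'
#' `baseline_scale` and `noise_sd` may be `NULL`, meaning "relative to the
#' data": the baseline amplitude is then 20 % and the noise standard
#' deviation 0.05 % of the largest noiseless apex in the generated set.
#' The noise default places the pipeline in the regime a differential-pulse
#' instrument with current-pulse averaging operates in, where the relative
#' prediction error after full preprocessing lands around the one-percent
#' mark while raw drifting, jittered data are off by tens of percent; the
#' methods vignette derives this calibration.  Negative simulated currents
#' are allowed; nothing is clipped.
#'
#' @param baseline_kind one of `"none"`, `"linear"`, `"exponential"`,
#'   `"polynomial"`.
#' @param baseline_scale baseline amplitude in current units, or `NULL` for
#'   the relative default.
#' @param jitter_sd standard deviation of the per-sample potential shift (V);
#'   shifts are rounded to an integer number of grid steps.  Default 0.01 V
#'   (two 5 mV steps).
#' @param noise_sd additive noise standard deviation in current units, or
#'   `NULL` for the relative default.
#' @param seed integer seed; same seed, same set, bit for bit.
#' @param jitter_steps optional integer vector of per-sample shifts in grid
#'   steps, overriding the random jitter (recycled across samples).  Used to
#'   inject known shifts.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(baseline_kind = c("exponential", "linear",
                                            "polynomial", "none"),
                          baseline_scale = NULL, jitter_sd = 0.01,
                          noise_sd = NULL, seed = 1L, jitter_steps = NULL) {
  baseline_kind <- match.arg(baseline_kind)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0",
                                               call. = FALSE)
  structure(list(baseline_kind = baseline_kind,
                 baseline_scale = baseline_scale,
                 jitter_sd = jitter_sd, noise_sd = noise_sd,
                 seed = as.integer(seed), jitter_steps = jitter_steps),
            class = "artifact_spec")
}

#' Artifact specification with every artifact disabled
#'
#' Convenience wrapper: no baseline, no jitter, no noise.  The generated set
#' is then exactly bilinear in the design.
#'
#' @param seed integer seed (unused when nothing is random; kept for
#'   interface symmetry).
#' @return An [artifact_spec()].
#' @export
no_artifacts <- function(seed = 1L) {
  artifact_spec(baseline_kind = "none", baseline_scale = 0, jitter_sd = 0,
                noise_sd = 0, seed = seed)
}

#' Pure-component voltammogram
#'
#' The noiseless, baseline-free trace of a single analyte at concentration
#' `conc`: a Gaussian at `spec$ep` whose apex equals
#' `spec$slope * conc + spec$intercept`.
#'
#' @param spec an [analyte_peak_spec()].
#' @param conc concentration in mol/L, `>= 0`.
#' @param grid a [potential_grid()].
#' @return A [voltammogram()].
#' @export
component_signal <- function(spec, conc, grid = potential_grid()) {
  stopifnot(inherits(spec, "analyte_peak_spec"))
  if (!is.finite(conc) || conc < 0) {
    stop("concentration must be finite and >= 0", call. = FALSE)
  }
  amp <- spec$slope * conc + spec$intercept
  e <- grid$potentials
  voltammogram(grid, amp * exp(-(e - spec$ep)^2 / (2 * spec$width^2)))
}

# Evaluate the smooth baseline shape on [0, 1]; amplitude applied by caller.
baseline_shape <- function(kind, u) {
  switch(kind,
         none        = numeric(length(u)) * 0,
         linear      = 1 - u,
         exponential = exp(-3 * u),
         polynomial  = (1 - u)^2,
         stop("unknown baseline kind: ", kind, call. = FALSE))
}

#' Generate a synthetic mixture voltammogram set
#'
#' Builds one voltammogram per design row as the sum of the per-analyte
#' component signals (each rigidly shifted in potential by that sample's
#' jitter), plus a smooth drifting baseline and additive white noise per the
#' [artifact_spec()].  With artifacts disabled the output is exactly
#' bilinear: `matrix = C %*% S` plus the concentration-independent intercept
#' spectra.
#'
#' Per-sample baseline amplitudes are drawn uniformly in
#' `[0.5, 1.5] * baseline_scale` so the baseline drifts from run to run.
#' Output is deterministic given `artifacts$seed`.
#'
#' @param design a [conc_table()]; its analyte names must match `specs`.
#' @param specs named list of [analyte_peak_spec()], as from
#'   [default_analyte_specs()].
#' @param artifacts an [artifact_spec()].
#' @param grid a [potential_grid()].
#' @return List with `set` (the [voltammogram_set()]), `clean` (noiseless,
#'   unshifted, baseline-free matrix), `jitter_steps` (per-sample integer
#'   shifts), `noise_sd` and `baseline_scale` actually used.
#' @export
generate_mixture_set <- function(design, specs = default_analyte_specs(),
                                 artifacts = artifact_spec(),
                                 grid = potential_grid()) {
  stopifnot(inherits(design, "conc_table"), inherits(artifacts, "artifact_spec"))
  spec_names <- vapply(specs, function(s) s$name, character(1))
  if (!setequal(design$analytes, spec_names) ||
      length(design$analytes) != length(specs)) {
    stop("design analytes do not match the analyte peak specs", call. = FALSE)
  }
  specs <- specs[match(design$analytes, spec_names)]
  n_s <- length(design$samples)
  n_p <- grid$n_points

  clean <- matrix(0, n_s, n_p)
  for (k in seq_along(specs)) {
    for (i in seq_len(n_s)) {
      clean[i, ] <- clean[i, ] +
        component_signal(specs[[k]], design$values[i, k], grid)$current
    }
  }
  ref <- if (n_s > 0) max(abs(clean)) else 1
  noise_sd <- if (is.null(artifacts$noise_sd)) 5e-4 * ref else artifacts$noise_sd
  base_scale <- if (is.null(artifacts$baseline_scale)) 0.2 * ref else
    artifacts$baseline_scale

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(artifacts$seed)

  if (!is.null(artifacts$jitter_steps)) {
    steps <- rep_len(as.integer(artifacts$jitter_steps), n_s)
  } else if (artifacts$jitter_sd > 0) {
    steps <- as.integer(round(stats::rnorm(n_s, 0, artifacts$jitter_sd) /
                                grid$step))
  } else {
    steps <- integer(n_s)
  }
  amps <- base_scale * stats::runif(n_s, 0.5, 1.5)
  u <- (grid$potentials - grid$start) / (grid$stop - grid$start)
  shape <- baseline_shape(artifacts$baseline_kind, u)

  mat <- matrix(0, n_s, n_p)
  for (i in seq_len(n_s)) {
    row <- numeric(n_p)
    dj <- steps[i] * grid$step
    for (k in seq_along(specs)) {
      sh <- specs[[k]]
      amp <- sh$slope * design$values[i, k] + sh$intercept
      row <- row + amp * exp(-(grid$potentials - (sh$ep + dj))^2 /
                               (2 * sh$width^2))
    }
    mat[i, ] <- row + amps[i] * shape
  }
  if (noise_sd > 0) {
    mat <- mat + matrix(stats::rnorm(n_s * n_p, 0, noise_sd), n_s, n_p)
  }
  list(set = voltammogram_set(grid, mat, samples = design$samples),
       clean = clean, jitter_steps = steps,
       noise_sd = noise_sd, baseline_scale = base_scale)
}
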
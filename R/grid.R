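#' Uniform potential grid
#'
#' Constructs the applied-potential axis of a voltammetric scan: a strictly
#' increasing uniform grid from `start` to `stop` volts in steps of `step`
#' volts.  The default grid (0.00 to +1.30 V at 5 mV) has 261 points and is
#' the grid on which all bundled analyte parameters are defined.
#'
#' @param start first potential (V).
#' @param stop last potential (V); must exceed `start`.
#' @param step potential increment (V); must be positive and divide
#'   `stop - start` to within floating-point rounding.
#' @return An object of class `potential_grid`: a list with `start`, `stop`,
#'   `step`, `n_points` and the realised `potentials` vector.
#' @examples
#' g <- potential_grid()
#' g$n_points  # 261
#' @export
potential_grid <- function(start = 0, stop = 1.3, step = 0.005) {
  if (!is.finite(start) || !is.finite(stop) || !is.finite(step)) {
    stop("potential grid parameters must be finite", call. = FALSE)
  }
  if (step <= 0) stop("grid step must be > 0", call. = FALSE)
  if (stop <= start) stop("grid stop must exceed start", call. = FALSE)
  n <- round((stop - start) / step) + 1
  if (abs((start + (n - 1) * step) - stop) > 1e-9 * max(1, abs(stop))) {
    stop("grid step does not evenly divide the potential range", call. = FALSE)
  }
  structure(
    list(start = start, stop = stop, step = step, n_points = as.integer(n),
         potentials = start + step * (seq_len(n) - 1)),
    class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("<potential_grid> %.3f to %.3f V, step %.4f V (%d points)\n",
              x$start, x$stop, x$step, x$n_points))
  invisible(x)
}

#' Single voltammogram
#'
#' A current trace on a uniform potential grid.
#'
#' @param grid a [potential_grid()].
#' @param current numeric vector of currents (consistent but unitless current
#'   units), one value per grid point, all finite.
#' @return An object of class `voltammogram`.
#' @export
voltammogram <- function(grid, current) {
  stopifnot(inherits(grid, "potential_grid"))
  current <- as.numeric(current)
  if (length(current) != grid$n_points) {
    stop(sprintf("current has %d values but grid has %d points",
                 length(current), grid$n_points), call. = FALSE)
  }
  if (!all(is.finite(current))) {
    stop("voltammogram currents must all be finite", call. = FALSE)
  }
  structure(list(grid = grid, current = current), class = "voltammogram")
}

#' Set of voltammograms on a shared grid
#'
#' The sample-by-potential current matrix that all preprocessing and
#' calibration stages operate on.  The calibration instance used throughout
#' the package documentation is 16 samples x 261 potentials.
#'
#' @param grid a [potential_grid()].
#' @param mat numeric matrix, one row per sample, `grid$n_points` columns.
#' @param samples character vector of sample IDs (defaults to rownames of
#'   `mat`, or `S1..Sn`).
#' @return An object of class `voltammogram_set` with elements `grid`,
#'   `samples`, `matrix`.
#' @export
voltammogram_set <- function(grid, mat, samples = NULL) {
  stopifnot(inherits(grid, "potential_grid"))
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (ncol(mat) != grid$n_points) {
    stop(sprintf("matrix has %d columns but grid has %d points",
                 ncol(mat), grid$n_points), call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- rownames(mat)
    if (is.null(samples)) samples <- sprintf("S%d", seq_len(nrow(mat)))
  }
  samples <- as.character(samples)
  if (length(samples) != nrow(mat)) {
    stop("sample ID count does not match matrix row count", call. = FALSE)
  }
  if (anyDuplicated(samples)) stop("sample IDs must be unique", call. = FALSE)
  if (nrow(mat) > 0 && !all(is.finite(mat))) {
    stop("voltammogram matrix must be finite", call. = FALSE)
  }
  dimnames(mat) <- list(samples, format_potential(grid$potentials))
  structure(list(grid = grid, samples = samples, matrix = mat),
            class = "voltammogram_set")
}

#' @export
print.voltammogram_set <- function(x, ...) {
  cat(sprintf("<voltammogram_set> %d samples x %d points (%.3f-%.3f V)\n",
              nrow(x$matrix), x$grid$n_points, x$grid$start, x$grid$stop))
  invisible(x)
}

#' Nominal concentration table
#'
#' Sample-by-analyte matrix of nominal concentrations in mol/L, paired row
#' for row with a [voltammogram_set()].
#'
#' @param values numeric matrix (n_samples x n_analytes), all values >= 0.
#' @param samples sample IDs; default rownames or `S1..Sn`.
#' @param analytes analyte names; default colnames of `values`.
#' @return An object of class `conc_table` with `samples`, `analytes`,
#'   `values`.
#' @export
conc_table <- function(values, samples = NULL, analytes = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(samples)) {
    samples <- rownames(values)
    if (is.null(samples)) samples <- sprintf("S%d", seq_len(nrow(values)))
  }
  if (is.null(analytes)) {
    analytes <- colnames(values)
    if (is.null(analytes)) analytes <- sprintf("A%d", seq_len(ncol(values)))
  }
  samples <- as.character(samples); analytes <- as.character(analytes)
  if (length(samples) != nrow(values) || length(analytes) != ncol(values)) {
    stop("dimension names do not match the value matrix", call. = FALSE)
  }
  if (nrow(values) > 0 && (!all(is.finite(values)) || any(values < 0))) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  dimnames(values) <- list(samples, analytes)
  structure(list(samples = samples, analytes = analytes, values = values),
            class = "conc_table")
}

#' @export
print.conc_table <- function(x, ...) {
  cat(sprintf("<conc_table> %d samples x %d analytes (mol/L)\n",
              length(x$samples), length(x$analytes)))
  print(utils::head(x$values))
  invisible(x)
}

# 3-decimal header representation of potentials (5 mV grid resolves exactly)
format_potential <- function(e) sprintf("%.3f", e)
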
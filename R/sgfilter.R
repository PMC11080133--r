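#' Savitzky-Golay parameters
#'
#' @param window odd window length in points (default 15).
#' @param polyorder polynomial degree fitted in each window (default 2),
#'   strictly below `window`.
#' @param deriv derivative order 0, 1 or 2 (default 1: first derivative,
#'   which removes any additive offset left after baseline correction),
#'   at most `polyorder`.
#' @return An object of class `sg_params`.
#' @export
sg_params <- function(window = 15L, polyorder = 2L, deriv = 1L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3",
                                           call. = FALSE)
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  if (deriv > polyorder || deriv < 0 || deriv > 2) {
    stop("deriv must be in 0..2 and <= polyorder", call. = FALSE)
  }
  structure(list(window = window, polyorder = polyorder, deriv = deriv),
            class = "sg_params")
}

# polynomial least-squares derivative row for window offsets `offs`
# evaluated at offset 0: d-th derivative = d! * b_d of the fitted polynomial
sg_row <- function(offs, polyorder, deriv) {
  A <- outer(offs, 0:polyorder, `^`)
  G <- solve(crossprod(A), t(A))      # (p+1) x n pseudo-inverse
  factorial(deriv) * G[deriv + 1, ]
}

#' Savitzky-Golay convolution coefficients
#'
#' Least-squares convolution weights for the `deriv`-th derivative of a
#' degree-`polyorder` polynomial fit over a symmetric window, evaluated at
#' the window centre, on a unit-spaced grid.  For window 5, polyorder 2,
#' deriv 0 these are the classic (-3, 12, 17, 12, -3)/35.
#'
#' @param window odd window length.
#' @param polyorder polynomial degree.
#' @param deriv derivative order.
#' @return Numeric coefficient vector of length `window`.
#' @export
sg_coefficients <- function(window, polyorder, deriv = 0L) {
  p <- sg_params(window, polyorder, deriv)
  h <- (p$window - 1L) %/% 2L
  sg_row(seq.int(-h, h), p$polyorder, p$deriv)
}

#' Apply a Savitzky-Golay filter row-wise
#'
#' Interior points use the symmetric convolution of [sg_coefficients()];
#' within half a window of either edge the polynomial is refitted on the
#' truncated asymmetric window and its derivative evaluated at the point
#' itself, so the output keeps the input length.  Derivatives are scaled by
#' `(1/step)^deriv`, giving current units per volt for `deriv = 1` on a
#' potential grid.
#'
#' @param mat numeric matrix (samples x points) or a vector.
#' @param params an [sg_params()].
#' @param step grid spacing used to scale derivatives (default 1).
#' @return Filtered matrix (or vector) of the same shape.
#' @export
apply_sg <- function(mat, params = sg_params(), step = 1) {
  vec_in <- is.null(dim(mat))
  m <- if (vec_in) matrix(mat, nrow = 1) else as.matrix(mat)
  n <- ncol(m)
  if (n < params$window) stop("trace shorter than the filter window",
                              call. = FALSE)
  h <- (params$window - 1L) %/% 2L
  centre <- sg_coefficients(params$window, params$polyorder, params$deriv)
  out <- m
  interior <- (h + 1L):(n - h)
  # interior: one matrix product over the sliding windows
  for (i in interior) {
    out[, i] <- m[, (i - h):(i + h), drop = FALSE] %*% centre
  }
  for (i in seq_len(h)) {          # leading edge, truncated window
    offs <- seq.int(1L - i, h)
    row <- sg_row(offs, params$polyorder, params$deriv)
    out[, i] <- m[, i + offs, drop = FALSE] %*% row
    j <- n - i + 1L                # trailing edge, mirrored truncation
    offs <- seq.int(-h, i - 1L)
    row <- sg_row(offs, params$polyorder, params$deriv)
    out[, j] <- m[, j + offs, drop = FALSE] %*% row
  }
  out <- out / step^params$deriv
  if (vec_in) as.numeric(out) else out
}

#' Savitzky-Golay filter a voltammogram set
#'
#' [apply_sg()] on the set's matrix with the grid step as derivative
#' scaling; grid and IDs preserved.
#'
#' @param set a [voltammogram_set()].
#' @param params an [sg_params()].
#' @return The filtered [voltammogram_set()].
#' @export
sg_filter_set <- function(set, params = sg_params()) {
  stopifnot(inherits(set, "voltammogram_set"))
  voltammogram_set(set$grid,
                   apply_sg(set$matrix, params, step = set$grid$step),
                   samples = set$samples)
}

#' Fit a column-scaling state
#'
#' Chemometric column scaling ahead of PLS: `center` subtracts column
#' means; `autoscale` additionally divides by the column standard deviation
#' (n - 1 denominator); `pareto` divides by the square root of the standard
#' deviation, damping but not equalising variable variance.  Constant
#' columns scale to zero and are flagged.
#'
#' @param mat numeric matrix.
#' @param mode `"center"`, `"autoscale"` or `"pareto"`.
#' @return An object of class `scaling_state` with `mode`, `means`, `sds`,
#'   `divisor` and `constant` (logical flags).
#' @export
fit_scaling <- function(mat, mode = c("pareto", "center", "autoscale")) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  means <- colMeans(mat)
  sds <- apply(mat, 2, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  divisor <- switch(mode,
                    center = rep(1, ncol(mat)),
                    autoscale = sds,
                    pareto = sqrt(sds))
  divisor[constant | divisor == 0] <- 1
  structure(list(mode = mode, means = means, sds = sds, divisor = divisor,
                 constant = constant),
            class = "scaling_state")
}

#' Apply / invert a fitted scaling
#'
#' @param mat numeric matrix with as many columns as the fitted state.
#' @param state a `scaling_state` from [fit_scaling()].
#' @return The scaled matrix.
#' @export
apply_scaling <- function(mat, state) {
  stopifnot(inherits(state, "scaling_state"))
  mat <- as.matrix(mat)
  if (ncol(mat) != length(state$means)) {
    stop("column count does not match the scaling state", call. = FALSE)
  }
  sweep(sweep(mat, 2, state$means, `-`), 2, state$divisor, `/`)
}

#' @rdname apply_scaling
#' @export
invert_scaling <- function(mat, state) {
  stopifnot(inherits(state, "scaling_state"))
  sweep(sweep(as.matrix(mat), 2, state$divisor, `*`), 2, state$means, `+`)
}
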
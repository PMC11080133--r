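#' airPLS parameters
#'
#' Tuning parameters of the adaptive iteratively reweighted penalized least
#' squares baseline corrector: penalty weight `lam` (default 1e5), iteration
#' cap `max_iter` (default 15), difference order `diff_order` (default 2)
#' and the convergence ratio `conv_ratio` (default 1e-3) on the
#' negative-residual mass.  `lam` is dimensionless with respect to the index
#' spacing; users changing grid density should rescale it.
#'
#' @param lam penalty weight, > 0.
#' @param max_iter maximum number of reweighting iterations, >= 1.
#' @param diff_order order of the difference penalty, one of 1, 2, 3.
#' @param conv_ratio stop when the negative-residual mass falls below this
#'   fraction of the total absolute signal.
#' @return An object of class `airpls_params`.
#' @export
airpls_params <- function(lam = 1e5, max_iter = 15L, diff_order = 2L,
                          conv_ratio = 1e-3) {
  if (lam < 0) stop("lam must be >= 0", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (!diff_order %in% 1:3) stop("diff_order must be 1, 2 or 3", call. = FALSE)
  structure(list(lam = lam, max_iter = as.integer(max_iter),
                 diff_order = as.integer(diff_order), conv_ratio = conv_ratio),
            class = "airpls_params")
}

#' Weighted Whittaker smoother
#'
#' Solves exactly, by a sparse banded factorisation, the penalized
#' least-squares problem
#' \deqn{\min_z \sum_i w_i (y_i - z_i)^2 + \lambda \|D^{(d)} z\|^2}
#' where \eqn{D^{(d)}} is the d-th order difference operator on the index
#' grid.  This is the smoothing core that airPLS reweights.
#'
#' @param y numeric signal vector.
#' @param w non-negative weights, same length as `y`, not all zero.
#' @param lam penalty weight, >= 0.
#' @param diff_order difference order (1, 2 or 3).
#' @return The fitted vector `z`.
#' @export
whittaker_smooth <- function(y, w, lam, diff_order = 2L) {
  n <- length(y)
  if (length(w) != n) stop("weights and signal differ in length", call. = FALSE)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (all(w == 0)) stop("degenerate system: all weights are zero", call. = FALSE)
  if (n <= diff_order) stop("signal shorter than the difference order + 1",
                            call. = FALSE)
  W <- Matrix::Diagonal(n, w)
  D <- difference_operator(n, diff_order)
  A <- W + lam * Matrix::crossprod(D)
  as.numeric(Matrix::solve(A, w * y))
}

# sparse d-th order difference operator, (n - d) x n
difference_operator <- function(n, d) {
  coefs <- choose(d, 0:d) * (-1)^(d - (0:d))
  Matrix::bandSparse(n - d, n, k = 0:d,
                     diagonals = lapply(coefs, rep, n - d))
}

#' airPLS baseline estimation
#'
#' Adaptive iteratively reweighted penalized least squares: the Whittaker
#' smoother is refitted with weights that progressively ignore points lying
#' above the running baseline estimate (peaks) and emphasise points below
#' it, so the fit converges onto the signal's lower envelope.
#'
#' Iteration t: fit `z = whittaker_smooth(y, w, lam, diff_order)`, form the
#' residual `d = y - z` and its negative mass `dssn = sum(|d[d < 0]|)`;
#' stop when `dssn < conv_ratio * sum(|y|)` or at `max_iter`.  Otherwise set
#' `w = 0` where `d >= 0` and `w = exp(t * |d| / dssn)` where `d < 0`, then
#' pin both endpoint weights to the maximum weight so the fit stays anchored
#' at the trace edges.
#'
#' @param y numeric signal vector, finite.
#' @param params an [airpls_params()].
#' @return List with `baseline`, `corrected` (`y - baseline`, exactly) and
#'   `iterations` used.
#' @export
airpls_baseline <- function(y, params = airpls_params()) {
  if (!all(is.finite(y))) stop("signal must be finite", call. = FALSE)
  stopifnot(inherits(params, "airpls_params"))
  n <- length(y)
  w <- rep(1, n)
  z <- y
  abs_total <- sum(abs(y))
  it <- 0L
  for (t in seq_len(params$max_iter)) {
    it <- t
    z <- whittaker_smooth(y, w, params$lam, params$diff_order)
    d <- y - z
    neg <- d < 0
    dssn <- sum(abs(d[neg]))
    if (dssn <= params$conv_ratio * abs_total || t == params$max_iter) break
    w[!neg] <- 0
    w[neg] <- exp(t * abs(d[neg]) / dssn)
    w[c(1L, n)] <- max(w)
  }
  list(baseline = z, corrected = y - z, iterations = it)
}

#' Baseline-correct every voltammogram in a set
#'
#' Row-wise [airpls_baseline()]; grid and sample IDs are preserved.
#'
#' @param set a [voltammogram_set()].
#' @param params an [airpls_params()].
#' @return The corrected [voltammogram_set()].
#' @export
airpls_correct_set <- function(set, params = airpls_params()) {
  stopifnot(inherits(set, "voltammogram_set"))
  out <- set$matrix
  for (i in seq_len(nrow(out))) {
    res <- tryCatch(airpls_baseline(set$matrix[i, ], params),
                    error = function(e) {
                      stop(sprintf("airPLS failed on row %d (%s): %s",
                                   i, set$samples[i], conditionMessage(e)),
                           call. = FALSE)
                    })
    out[i, ] <- res$corrected
  }
  voltammogram_set(set$grid, out, samples = set$samples)
}
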
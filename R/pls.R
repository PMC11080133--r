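#' NIPALS partial least squares regression (PLS2)
#'
#' Fits a PLS regression of a response matrix `Y` (nominal concentrations)
#' on a predictor matrix `X` (preprocessed voltammograms) by the nonlinear
#' iterative partial least squares algorithm, extracting latent variables
#' that maximise X-Y covariance.  Both blocks are scaled internally and the
#' scaling states stored, so prediction is expressed in original units.
#'
#' The inner NIPALS iteration converges when the relative change of the
#' X-score vector falls below 1e-10 (cap 500 iterations; hitting the cap is
#' recorded as a warning flag on the component, which is still accepted).
#' Component extraction stops early if either deflated block degenerates to
#' numerical zero; the realised number of components is reported in `n_lv`.
#' The regression coefficient matrix on the scaled blocks is
#' `B = W (P'W)^{-1} Q'`.
#'
#' @param X numeric matrix, samples x variables.
#' @param Y numeric matrix (or vector), samples x analytes; no zero-variance
#'   column allowed.
#' @param n_lv number of latent variables, at most `min(nrow(X) - 1, ncol(X))`.
#' @param x_scaling scaling for X: `"pareto"` (default), `"center"` or
#'   `"autoscale"`.
#' @param y_scaling scaling for Y: `"autoscale"` (default; makes the model
#'   invariant to per-analyte units) or `"center"`.
#' @return An object of class `pls_model` with `W`, `T`, `P`, `U`, `Q`
#'   (score/loading matrices), `B`, `n_lv`, the two `scaling_state`s,
#'   `fitted` (training predictions, original units) and
#'   `nonconverged` (logical per component).
#' @export
pls_fit <- function(X, Y, n_lv,
                    x_scaling = c("pareto", "center", "autoscale"),
                    y_scaling = c("autoscale", "center", "pareto")) {
  x_scaling <- match.arg(x_scaling); y_scaling <- match.arg(y_scaling)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ", call. = FALSE)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (n_lv < 1 || n_lv > min(n - 1, p)) {
    stop("n_lv must be in 1..min(n_samples - 1, n_points)", call. = FALSE)
  }
  ysd <- apply(Y, 2, stats::sd)
  if (any(ysd == 0)) stop("zero-variance response column", call. = FALSE)

  xs <- fit_scaling(X, x_scaling)
  ys <- fit_scaling(Y, y_scaling)
  X0 <- apply_scaling(X, xs)
  Y0 <- apply_scaling(Y, ys)
  x_tot <- sum(X0^2); y_tot <- sum(Y0^2)

  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv); U <- matrix(0, n, n_lv)
  Q <- matrix(0, m, n_lv)
  nonconv <- logical(n_lv)
  a_done <- 0L
  for (a in seq_len(n_lv)) {
    if (sum(X0^2) < 1e-24 * max(x_tot, 1e-300) ||
        sum(Y0^2) < 1e-24 * max(y_tot, 1e-300)) break
    u <- Y0[, which.max(apply(Y0, 2, stats::var))]
    t_old <- rep(0, n)
    w <- q <- NULL; t <- NULL
    converged <- FALSE
    for (it in seq_len(500L)) {
      w <- crossprod(X0, u) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      t <- X0 %*% w
      q <- crossprod(Y0, t) / sum(t^2)
      u <- Y0 %*% q / sum(q^2)
      if (sqrt(sum((t - t_old)^2)) < 1e-10 * max(sqrt(sum(t^2)), 1e-300)) {
        converged <- TRUE
        break
      }
      t_old <- t
    }
    pvec <- crossprod(X0, t) / sum(t^2)
    X0 <- X0 - t %*% t(pvec)
    Y0 <- Y0 - t %*% t(q)
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; U[, a] <- u; Q[, a] <- q
    nonconv[a] <- !converged
    a_done <- a
  }
  if (a_done == 0L) stop("no latent variable could be extracted", call. = FALSE)
  W <- W[, seq_len(a_done), drop = FALSE]
  P <- P[, seq_len(a_done), drop = FALSE]
  Tm <- Tm[, seq_len(a_done), drop = FALSE]
  U <- U[, seq_len(a_done), drop = FALSE]
  Q <- Q[, seq_len(a_done), drop = FALSE]
  B <- W %*% solve(crossprod(P, W)) %*% t(Q)
  model <- structure(
    list(n_lv = a_done, W = W, T = Tm, P = P, U = U, Q = Q, B = B,
         x_scaling = xs, y_scaling = ys,
         analytes = colnames(Y), nonconverged = nonconv[seq_len(a_done)]),
    class = "pls_model")
  model$fitted <- pls_predict(model, X)
  model
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables, %d analytes, %d X-variables\n",
              x$n_lv, ncol(x$B), nrow(x$B)))
  invisible(x)
}

# coefficient matrix truncated to the first `a` latent variables
pls_coefficients <- function(model, a = model$n_lv) {
  W <- model$W[, seq_len(a), drop = FALSE]
  P <- model$P[, seq_len(a), drop = FALSE]
  Q <- model$Q[, seq_len(a), drop = FALSE]
  W %*% solve(crossprod(P, W)) %*% t(Q)
}

#' Predict concentrations from a fitted PLS model
#'
#' Applies the stored X scaling, multiplies by the regression coefficients
#' and inverts the Y scaling.
#'
#' @param model a [pls_fit()] model.
#' @param X_new matrix of new (preprocessed) voltammograms with the training
#'   column count.
#' @param n_lv predict with a truncated model of this many latent variables
#'   (default: all fitted).
#' @return Matrix of predicted concentrations (mol/L), samples x analytes.
#' @export
pls_predict <- function(model, X_new, n_lv = model$n_lv) {
  stopifnot(inherits(model, "pls_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$x_scaling$means)) {
    stop("X_new column count does not match the training matrix", call. = FALSE)
  }
  B <- if (n_lv == model$n_lv) model$B else pls_coefficients(model, n_lv)
  pred <- invert_scaling(apply_scaling(X_new, model$x_scaling) %*% B,
                         model$y_scaling)
  colnames(pred) <- model$analytes
  rownames(pred) <- rownames(X_new)
  pred
}

# fold assignment for the supported CV schemes
cv_folds <- function(n, scheme = c("loo", "kfold"), k = 7L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "loo") return(as.list(seq_len(n)))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  perm <- sample.int(n)                      # seeded venetian blinds
  split(perm, rep_len(seq_len(k), n))
}

#' Cross-validated RMSECV over candidate latent-variable counts
#'
#' For each fold, scaling and model are refitted on the remaining samples
#' with `max_lv` components and the held-out samples predicted at every
#' truncation 1..`max_lv`; RMSECV per analyte per LV count is computed from
#' the pooled out-of-fold predictions (original concentration units).
#'
#' @param X,Y training blocks as in [pls_fit()].
#' @param max_lv largest LV count to evaluate; must leave every training
#'   fold at least `max_lv + 1` samples.
#' @param scheme `"loo"` (default, deterministic) or `"kfold"` (seeded
#'   venetian blinds).
#' @param k number of folds for `"kfold"`.
#' @param seed seed for the fold permutation.
#' @param x_scaling,y_scaling passed to [pls_fit()].
#' @return An object of class `pls_cv`: `rmsecv` and `press` (max_lv x
#'   analytes matrices), `pred` (per-LV list of out-of-fold prediction
#'   matrices), `scheme` descriptor string.
#' @export
cross_validate <- function(X, Y, max_lv, scheme = c("loo", "kfold"), k = 7L,
                           seed = 1L, x_scaling = "pareto",
                           y_scaling = "autoscale") {
  scheme <- match.arg(scheme)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  folds <- cv_folds(n, scheme, k, seed)
  min_train <- n - max(lengths(folds))
  if (max_lv > min_train - 1) {
    stop("max_lv too large for the smallest training fold", call. = FALSE)
  }
  m <- ncol(Y)
  preds <- lapply(seq_len(max_lv), function(a) matrix(NA_real_, n, m))
  for (fold in folds) {
    fit <- pls_fit(X[-fold, , drop = FALSE], Y[-fold, , drop = FALSE],
                   n_lv = max_lv, x_scaling = x_scaling,
                   y_scaling = y_scaling)
    for (a in seq_len(max_lv)) {
      a_eff <- min(a, fit$n_lv)
      preds[[a]][fold, ] <- pls_predict(fit, X[fold, , drop = FALSE],
                                        n_lv = a_eff)
    }
  }
  rmsecv <- matrix(NA_real_, max_lv, m,
                   dimnames = list(paste0("LV", seq_len(max_lv)),
                                   colnames(Y) %||% paste0("A", seq_len(m))))
  for (a in seq_len(max_lv)) {
    rmsecv[a, ] <- sqrt(colMeans((preds[[a]] - Y)^2))
  }
  press <- n * rmsecv^2
  structure(list(rmsecv = rmsecv, press = press, pred = preds,
                 scheme = if (scheme == "loo") "leave-one-out" else
                   sprintf("%d-fold venetian blinds (seed %d)", k, seed),
                 n = n),
            class = "pls_cv")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the number of latent variables from an RMSECV curve
#'
#' Parsimony rule: analyte-wise RMSECV curves are pooled by root mean
#' square across analytes, and the smallest LV count whose pooled RMSECV is
#' within a tolerance of the curve minimum is chosen — the point past which
#' adding a component no longer significantly reduces the cross-validation
#' error.
#'
#' @param cv a [cross_validate()] result, or a numeric vector/matrix of
#'   RMSECV values (rows = LV counts).
#' @param tol relative tolerance on the pooled minimum (default 0.02).
#' @return The chosen LV count (integer).
#' @export
select_n_lv <- function(cv, tol = 0.02) {
  rmsecv <- if (inherits(cv, "pls_cv")) cv$rmsecv else
    matrix(cv, ncol = if (is.null(dim(cv))) 1 else ncol(cv))
  pooled <- sqrt(rowMeans(rmsecv^2))
  as.integer(which(pooled <= (1 + tol) * min(pooled))[1])
}
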
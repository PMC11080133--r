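#' Prediction error statistics (RMSE, REP%, R-squared)
#'
#' \deqn{RMSE = \sqrt{\sum_i (y_{pred,i} - y_{act,i})^2 / n}}
#' \deqn{REP\% = 100 \cdot RMSE / \bar{y}_{act}}
#' with the mean taken over the same sample set, plus the coefficient of
#' determination of the predicted-versus-nominal least-squares line.
#'
#' @param y_pred predicted concentrations (mol/L).
#' @param y_act nominal concentrations (mol/L), same length.
#' @return An object of class `error_stats`: `rmse`, `rep_percent` (`NA`
#'   when the nominal mean is zero), `r2`, `n`, `y_mean`.
#' @export
error_stats <- function(y_pred, y_act) {
  if (length(y_pred) != length(y_act) || length(y_act) < 1) {
    stop("prediction and nominal vectors must match, n >= 1", call. = FALSE)
  }
  rmse <- sqrt(mean((y_pred - y_act)^2))
  y_mean <- mean(y_act)
  rep_percent <- if (y_mean == 0) NA_real_ else 100 * rmse / y_mean
  r2 <- if (length(y_act) > 2 && stats::sd(y_act) > 0 && stats::sd(y_pred) > 0)
    stats::cor(y_act, y_pred)^2 else if (rmse == 0) 1 else NA_real_
  structure(list(rmse = rmse, rep_percent = rep_percent, r2 = r2,
                 n = length(y_act), y_mean = y_mean),
            class = "error_stats")
}

# shared constructor enforcing the ANOVA additivity identities
build_cv_anova <- function(ss_regression, df_regression, ss_residual,
                           df_residual) {
  ms_reg <- ss_regression / df_regression
  ms_res <- ss_residual / df_residual
  if (ms_res == 0) {
    f <- Inf; p <- 0
  } else {
    f <- ms_reg / ms_res
    p <- stats::pf(f, df_regression, df_residual, lower.tail = FALSE)
  }
  data.frame(
    term = c("total_corrected", "regression", "residual"),
    SS = c(ss_regression + ss_residual, ss_regression, ss_residual),
    DF = c(df_regression + df_residual, df_regression, df_residual),
    MS = c((ss_regression + ss_residual) / (df_regression + df_residual),
           ms_reg, ms_res),
    F = c(NA, f, NA),
    p = c(NA, p, NA),
    SD = sqrt(c((ss_regression + ss_residual) / (df_regression + df_residual),
                ms_reg, ms_res)))
}

#' CV-ANOVA table from sums of squares
#'
#' Assembles the cross-validation ANOVA table directly from the regression
#' and residual sums of squares and degrees of freedom:
#' `MS = SS/DF`, `F = MS_regression / MS_residual`, `p` the upper-tail F
#' probability, and `SD = sqrt(MS)`.
#'
#' @param ss_regression,df_regression regression SS and DF.
#' @param ss_residual,df_residual residual SS and DF.
#' @return A data frame with rows total_corrected / regression / residual.
#' @export
cv_anova_from_ss <- function(ss_regression, df_regression, ss_residual,
                             df_residual) {
  build_cv_anova(ss_regression, df_regression, ss_residual, df_residual)
}

#' CV-ANOVA significance test
#'
#' F-test of PLS model significance on cross-validated predictive
#' residuals: the response is scaled to unit variance (total corrected
#' SS = n - 1), the residual SS is the sum of squared cross-validated
#' residuals, and the regression SS is their difference.  The degrees of
#' freedom assigned to the regression follow the configurable convention
#' `df_regression` (default: four fifths of the total DF, rounded), with
#' `df_residual = df_total - df_regression`.
#'
#' @param y_scaled unit-variance response vector (scaled so its corrected
#'   SS equals n - 1).
#' @param cv_residuals cross-validated residuals of the same scaled
#'   response.
#' @param df_regression regression degrees of freedom; default
#'   `round(4/5 * (n - 1))`.
#' @return A CV-ANOVA data frame as in [cv_anova_from_ss()].
#' @export
cv_anova <- function(y_scaled, cv_residuals, df_regression = NULL) {
  n <- length(y_scaled)
  if (length(cv_residuals) != n) stop("residual length mismatch", call. = FALSE)
  ss_total <- sum((y_scaled - mean(y_scaled))^2)
  ss_res <- sum(cv_residuals^2)
  ss_reg <- ss_total - ss_res
  df_total <- n - 1
  if (is.null(df_regression)) df_regression <- round(4 / 5 * df_total)
  df_res <- df_total - df_regression
  if (df_res < 1 || df_regression < 1) stop("degenerate DF split", call. = FALSE)
  build_cv_anova(ss_reg, df_regression, ss_res, df_res)
}

# training R^2 and cross-validated Q^2 of a single-response PLS model,
# both on the scaled response
r2_q2 <- function(X, y, n_lv, scheme = "loo", k = 7L, seed = 1L,
                  x_scaling = "pareto") {
  y <- as.numeric(y)
  ss_tot <- sum((y - mean(y))^2)
  fit <- pls_fit(X, y, n_lv = n_lv, x_scaling = x_scaling)
  r2 <- 1 - sum((fit$fitted - y)^2) / ss_tot
  cv <- cross_validate(X, y, max_lv = n_lv, scheme = scheme, k = k,
                       seed = seed, x_scaling = x_scaling)
  press <- sum((cv$pred[[n_lv]] - y)^2)
  q2 <- 1 - press / ss_tot
  c(r2 = r2, q2 = q2)
}

#' Response-permutation validity test
#'
#' Refits the PLS model against randomly permuted responses: a valid model
#' retains much higher R2 and Q2 for the true response than for any
#' permutation, and the regression lines of permuted R2 and Q2 against the
#' |correlation| between permuted and original response (the original model
#' included at correlation 1) should intercept near zero (R2) and below
#' zero (Q2).
#'
#' @param X predictor matrix.
#' @param y single response vector.
#' @param n_lv latent variables per refit.
#' @param n_perm number of permutations (default 40).
#' @param seed integer seed.
#' @param scheme,k CV scheme for Q2 (see [cross_validate()]).
#' @return An object of class `permutation_result`: data frame `perms`
#'   (correlation, r2, q2 per permutation), `original` (r2, q2),
#'   `r2_intercept`, `q2_intercept`.
#' @export
permutation_test <- function(X, y, n_lv, n_perm = 40L, seed = 1L,
                             scheme = "loo", k = 7L) {
  if (n_perm < 10) stop("n_perm must be >= 10", call. = FALSE)
  X <- as.matrix(X); y <- as.numeric(y)
  orig <- r2_q2(X, y, n_lv, scheme, k, seed)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  res <- matrix(NA_real_, n_perm, 3,
                dimnames = list(NULL, c("correlation", "r2", "q2")))
  for (i in seq_len(n_perm)) {
    yp <- sample(y)
    stat <- r2_q2(X, yp, n_lv, scheme, k, seed)
    res[i, ] <- c(abs(stats::cor(yp, y)), stat["r2"], stat["q2"])
  }
  cors <- c(res[, "correlation"], 1)
  r2s <- c(res[, "r2"], orig["r2"])
  q2s <- c(res[, "q2"], orig["q2"])
  r2_int <- unname(stats::coef(stats::lm(r2s ~ cors))[1])
  q2_int <- unname(stats::coef(stats::lm(q2s ~ cors))[1])
  structure(list(perms = as.data.frame(res),
                 original = c(r2 = unname(orig["r2"]),
                              q2 = unname(orig["q2"])),
                 r2_intercept = r2_int, q2_intercept = q2_int,
                 n_perm = n_perm, n_lv = n_lv, seed = seed),
            class = "permutation_result")
}

#' Sample leverages in the X- and Y-score spaces
#'
#' Diagonals of the projection (hat) matrices of the score blocks,
#' `H0 = T (T'T)^{-1} T'` and `Hy = U (U'U)^{-1} U'`.  Each leverage lies
#' in [0, 1] and the X-leverages sum to the number of latent variables.
#'
#' @param model a [pls_fit()] model.
#' @return List with `leverage_x` and `leverage_y` per-sample vectors.
#' @export
leverages <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  hat_diag <- function(S) {
    G <- tryCatch(solve(crossprod(S)),
                  error = function(e) stop("degenerate score matrix",
                                           call. = FALSE))
    rowSums((S %*% G) * S)
  }
  list(leverage_x = hat_diag(model$T), leverage_y = hat_diag(model$U))
}

#' Hotelling T-squared score-space distance
#'
#' Per-sample squared score distance, the sum over components of the
#' squared score divided by the score-column variance, with the usual
#' small-sample critical threshold
#' `A (N-1)(N+1) / (N (N-A)) * F(1 - alpha; A, N - A)`.
#'
#' @param model a [pls_fit()] model with `n_samples > n_lv`.
#' @param alpha significance level (default 0.05).
#' @return List with `t2` (per sample), `critical`, `alpha`.
#' @export
hotelling_t2 <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "pls_model"))
  Tm <- model$T
  N <- nrow(Tm); A <- ncol(Tm)
  if (N <= A) stop("need more samples than latent variables", call. = FALSE)
  v <- apply(Tm, 2, stats::var)
  if (any(v == 0)) stop("zero-variance score column", call. = FALSE)
  t2 <- rowSums(sweep(Tm^2, 2, v, `/`))
  crit <- A * (N - 1) * (N + 1) / (N * (N - A)) *
    stats::qf(1 - alpha, A, N - A)
  list(t2 = t2, critical = crit, alpha = alpha)
}

#' Standardized residuals and outlier flags
#'
#' Raw residuals (`y_act - y_pred`) divided by the residual standard
#' deviation, here the root mean square residual.  Observations with
#' |z| > 2 are flagged as outliers; normal-probability plotting coordinates
#' (sorted z against normal quantiles) are included.
#'
#' @param y_pred predicted values.
#' @param y_act nominal values, same length, n >= 3.
#' @return List with `z`, `flags` (logical), `rsd` and `npp` (data frame
#'   `theoretical`, `observed`).
#' @export
standardized_residuals <- function(y_pred, y_act) {
  n <- length(y_act)
  if (length(y_pred) != n || n < 3) stop("need n >= 3 paired values",
                                         call. = FALSE)
  r <- y_act - y_pred
  rsd <- sqrt(mean(r^2))
  z <- if (rsd == 0) rep(0, n) else r / rsd
  ord <- order(z)
  list(z = z, flags = abs(z) > 2, rsd = rsd,
       npp = data.frame(theoretical = stats::qnorm(stats::ppoints(n)),
                        observed = z[ord]))
}
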
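#' Analytical eco-scale score
#'
#' Sums penalty points over reagent, energy, occupational-hazard and waste
#' items and subtracts them from a base of 100.  Classification follows the
#' standard eco-scale bands: 100 is the ideal green method, above 75 a
#' great green analysis, 50-75 acceptable, below 50 inadequate.
#'
#' @param items data frame with columns `label`, `category` (one of
#'   `"reagent"`, `"energy"`, `"occupational hazard"`, `"waste"`) and
#'   `penalty` (non-negative points).  An empty/NULL `items` gives the
#'   ideal score of 100.
#' @return An object of class `eco_scale_sheet`: `items`, `total_pp`,
#'   `score`, `classification`.
#' @examples
#' eco_scale(eco_items_voltammetric())$score  # 90
#' @export
eco_scale <- function(items = NULL) {
  if (is.null(items) || nrow(items) == 0) {
    items <- data.frame(label = character(), category = character(),
                        penalty = numeric())
  }
  stopifnot(all(c("label", "category", "penalty") %in% names(items)))
  ok <- c("reagent", "energy", "occupational hazard", "waste")
  if (!all(items$category %in% ok)) {
    stop("unknown penalty category: ",
         paste(setdiff(items$category, ok), collapse = ", "), call. = FALSE)
  }
  if (any(items$penalty < 0)) stop("penalty points must be >= 0", call. = FALSE)
  total <- sum(items$penalty)
  score <- 100 - total
  if (score < 0) {
    warning("total penalty points exceed 100; score floored at 0")
    score <- 0
  }
  classification <- if (score == 100) "ideal" else if (score > 75)
    "great green" else if (score >= 50) "acceptable" else "inadequate"
  structure(list(items = items, total_pp = total, score = score,
                 classification = classification),
            class = "eco_scale_sheet")
}

#' @export
print.eco_scale_sheet <- function(x, ...) {
  cat(sprintf("<eco_scale_sheet> %d penalty points, score %g (%s)\n",
              x$total_pp, x$score, x$classification))
  invisible(x)
}

#' Bundled eco-scale item lists
#'
#' Penalty-point items for the direct voltammetric determination
#' (Britton-Robinson buffer, methanol for the entacapone stock, water,
#' negligible energy, no occupational hazard, moderate waste) and for the
#' comparison HPLC method (tetrahydrofuran, trifluoroacetic acid,
#' acetonitrile mobile phase, higher energy, hazard and waste).  They give
#' eco-scale scores of 90 and 77 respectively.
#'
#' @return A data frame suitable for [eco_scale()].
#' @export
eco_items_voltammetric <- function() {
  data.frame(
    label = c("Britton-Robinson buffer", "Methanol", "Water",
              "Energy (<= 0.1 kWh per sample)", "Occupational hazard",
              "Waste"),
    category = c("reagent", "reagent", "reagent", "energy",
                 "occupational hazard", "waste"),
    penalty = c(1, 6, 0, 0, 0, 3))
}

#' @rdname eco_items_voltammetric
#' @export
eco_items_hplc <- function() {
  data.frame(
    label = c("Water", "Tetrahydrofuran", "Trifluoroacetic acid",
              "Acetonitrile", "Energy (> 0.1 kWh per sample)",
              "Occupational hazard", "Waste"),
    category = c("reagent", "reagent", "reagent", "reagent", "energy",
                 "occupational hazard", "waste"),
    penalty = c(0, 6, 4, 4, 1, 3, 5))
}

#' Summary statistics of one method's recoveries
#'
#' @param mean mean percentage recovery.
#' @param sd standard deviation (%); at least one of `sd`/`variance`
#'   required.
#' @param variance variance (%^2); checked against `sd^2` to roughly the
#'   last printed digit when both are supplied.
#' @param n number of determinations, >= 2.
#' @return An object of class `method_summary`.
#' @export
method_summary <- function(mean, sd = NULL, variance = NULL, n) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (is.null(sd) && is.null(variance)) {
    stop("supply sd or variance", call. = FALSE)
  }
  if (is.null(sd)) sd <- sqrt(variance)
  if (is.null(variance)) variance <- sd^2
  if (abs(sd^2 - variance) > 0.01 + 0.01 * variance) {
    stop("sd and variance are inconsistent", call. = FALSE)
  }
  structure(list(mean = mean, sd = sd, variance = variance,
                 n = as.integer(n)),
            class = "method_summary")
}

#' Pooled-variance two-sample t test from summaries
#'
#' Student t statistic for comparing two methods' mean recoveries from
#' their summary statistics:
#' `t = (mean_a - mean_b) / sqrt(s_p^2 (1/n_a + 1/n_b))` with the pooled
#' variance `s_p^2 = ((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2)`.
#' The verdict compares |t| against a supplied tabulated critical value.
#'
#' @param a,b [method_summary()] objects.
#' @param t_critical tabulated critical value (optional).
#' @return List with `t`, `df`, `p` (two-sided, from the t distribution at
#'   `df`), `t_critical`, `verdict` (`"no significant difference"` /
#'   `"significant difference"` / `NA` without a critical value).
#' @export
pooled_t_test <- function(a, b, t_critical = NULL) {
  stopifnot(inherits(a, "method_summary"), inherits(b, "method_summary"))
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$variance + (b$n - 1) * b$variance) / df
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  verdict <- if (is.null(t_critical)) NA_character_ else
    if (abs(t) <= t_critical) "no significant difference" else
      "significant difference"
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
       t_critical = t_critical, verdict = verdict)
}

#' Variance-ratio (F) test from summaries
#'
#' `F` is the larger variance over the smaller (so `F >= 1` always), with
#' `n - 1` degrees of freedom on each side and a verdict against a supplied
#' tabulated critical value.
#'
#' @param a,b [method_summary()] objects with positive variances.
#' @param f_critical tabulated critical value (optional).
#' @return List with `f`, `df` (numerator, denominator), `f_critical`,
#'   `verdict`.
#' @export
variance_ratio_test <- function(a, b, f_critical = NULL) {
  stopifnot(inherits(a, "method_summary"), inherits(b, "method_summary"))
  if (a$variance <= 0 || b$variance <= 0) {
    stop("variances must be > 0", call. = FALSE)
  }
  if (a$variance >= b$variance) {
    f <- a$variance / b$variance; df <- c(a$n - 1L, b$n - 1L)
  } else {
    f <- b$variance / a$variance; df <- c(b$n - 1L, a$n - 1L)
  }
  verdict <- if (is.null(f_critical)) NA_character_ else
    if (f <= f_critical) "no significant difference" else
      "significant difference"
  list(f = f, df = df, f_critical = f_critical, verdict = verdict)
}
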
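# finite-field arithmetic used by the cyclic design construction:
# prime moduli directly; GF(4) via bit-xor addition and the x^2 = x + 1
# multiplication table
gf_add <- function(a, b, q) {
  if (q == 4L) bitwXor(a, b) else (a + b) %% q
}
gf_mult <- function(a, b, q) {
  if (q == 4L) {
    m <- matrix(c(0L, 0L, 0L, 0L,
                  0L, 1L, 2L, 3L,
                  0L, 2L, 3L, 1L,
                  0L, 3L, 1L, 2L), 4L, 4L, byrow = TRUE)
    m[cbind(a + 1L, b + 1L)]
  } else (a * b) %% q
}

#' Multilevel multifactor (Brereton) calibration design
#'
#' Cyclic construction of an `n_levels^2`-run mixture design with
#' `n_factors` factors at `n_levels` equally spaced coded levels, balanced
#' (each level appears exactly `n_levels` times per factor) and mutually
#' orthogonal (all pairwise factor-column correlations are exactly zero).
#' Runs are indexed by pairs (a, b) over the finite field of order
#' `n_levels`; factor j takes the level `b + f_j * a` in field arithmetic,
#' so the first factor repeats the five-level base sequence and subsequent
#' factors are its cyclic level permutations.  The default (5, 3) instance
#' is the 25-mixture ternary calibration design.
#'
#' @param n_levels number of concentration levels; supported: 2, 3, 4, 5, 7.
#' @param n_factors number of analytes (factors), at most `n_levels`.
#' @return An object of class `mixture_design`: list with `n_levels`,
#'   `n_factors`, `n_runs`, `level_codes` (runs x factors matrix of centred
#'   codes, e.g. -2..+2 for five levels) and `codes` (the sorted code set).
#' @examples
#' d <- brereton_design(5, 3)
#' d$n_runs                       # 25
#' max(abs(cor(d$level_codes)[upper.tri(diag(3))]))  # 0
#' @export
brereton_design <- function(n_levels = 5L, n_factors = 3L) {
  n_levels <- as.integer(n_levels); n_factors <- as.integer(n_factors)
  if (!n_levels %in% c(2L, 3L, 4L, 5L, 7L)) {
    stop("unsupported n_levels (need a prime power in 2..7): ", n_levels,
         call. = FALSE)
  }
  if (n_factors < 1 || n_factors > n_levels) {
    stop("n_factors must be between 1 and n_levels", call. = FALSE)
  }
  q <- n_levels
  codes <- if (q %% 2L == 1L) (0:(q - 1)) - (q - 1L) %/% 2L else
    2L * (0:(q - 1)) - (q - 1L)          # symmetric, equally spaced, sum 0
  ab <- expand.grid(b = 0:(q - 1), a = 0:(q - 1))  # b fastest: base sequence
  lev <- sapply(seq_len(n_factors) - 1L, function(f) {
    gf_add(ab$b, gf_mult(rep(f, nrow(ab)), ab$a, q), q)
  })
  lev <- matrix(as.integer(lev), ncol = n_factors)
  level_codes <- matrix(codes[lev + 1L], ncol = n_factors,
                        dimnames = list(paste0("M", seq_len(q^2)),
                                        paste0("F", seq_len(n_factors))))
  structure(list(n_levels = q, n_factors = n_factors, n_runs = q^2L,
                 level_codes = level_codes, codes = codes),
            class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("<mixture_design> %d levels x %d factors, %d runs\n",
              x$n_levels, x$n_factors, x$n_runs))
  invisible(x)
}

#' Map design level codes to concentrations
#'
#' Affine, order-preserving map per analyte: the lowest code maps to the
#' low end of the analyte's linear range, the highest to the high end,
#' intermediate codes equally spaced between.
#'
#' @param design a [brereton_design()].
#' @param ranges named list (one entry per factor, in design column order)
#'   of `c(low, high)` concentration ranges in mol/L.
#' @return A [conc_table()] with one row per design run.
#' @export
map_levels_to_concentrations <- function(design, ranges) {
  stopifnot(inherits(design, "mixture_design"))
  if (length(ranges) != design$n_factors) {
    stop("need one concentration range per design factor", call. = FALSE)
  }
  lo_code <- min(design$codes); hi_code <- max(design$codes)
  vals <- sapply(seq_len(design$n_factors), function(j) {
    r <- ranges[[j]]
    if (length(r) != 2 || r[1] >= r[2]) {
      stop("inverted or malformed range for factor ", j, call. = FALSE)
    }
    frac <- (design$level_codes[, j] - lo_code) / (hi_code - lo_code)
    r[1] + frac * (r[2] - r[1])
  })
  vals <- matrix(vals, ncol = design$n_factors)
  analytes <- if (!is.null(names(ranges))) names(ranges) else
    colnames(design$level_codes)
  conc_table(vals, samples = rownames(design$level_codes),
             analytes = analytes)
}

# level index (1..n_levels) of every table entry, per analyte
conc_level_index <- function(table) {
  apply(table$values, 2, function(v) match(v, sort(unique(v))))
}

#' Seeded calibration / validation split
#'
#' Draws a deterministic seeded split of the design runs into a calibration
#' and a validation subset (default 16 and 9 of the 25-run design), keeping
#' the split as level-balanced as possible: among 1000 seeded candidate
#' splits, the first in which both subsets contain every level of every
#' factor is chosen (falling back to the best coverage found).
#'
#' @param table a [conc_table()] built from a design.
#' @param n_cal calibration set size (default 16).
#' @param n_val validation set size (default 9).
#' @param seed integer seed.
#' @return List with `cal` and `val` character vectors of sample IDs and
#'   `balanced` (logical: full level coverage in both subsets).
#' @export
split_calibration_validation <- function(table, n_cal = 16L, n_val = 9L,
                                         seed = 1L) {
  stopifnot(inherits(table, "conc_table"))
  n <- length(table$samples)
  if (n_cal + n_val > n) stop("split sizes exceed the number of runs",
                              call. = FALSE)
  lev <- conc_level_index(table)
  n_lev <- apply(lev, 2, max)
  coverage <- function(rows) {
    sum(vapply(seq_len(ncol(lev)), function(j)
      length(unique(lev[rows, j])), numeric(1)))
  }
  full <- 2 * sum(n_lev)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  best <- NULL; best_cov <- -1
  for (try in seq_len(1000L)) {
    perm <- sample.int(n)
    cal <- perm[seq_len(n_cal)]
    val <- perm[n_cal + seq_len(n_val)]
    cov <- coverage(cal) + coverage(val)
    if (cov > best_cov) {
      best_cov <- cov
      best <- list(cal = cal, val = val)
    }
    if (cov == full) break
  }
  list(cal = table$samples[sort(best$cal)],
       val = table$samples[sort(best$val)],
       balanced = best_cov == full)
}

#' Apex current of an analyte peak
#'
#' Maximum current within `window` volts of the analyte's nominal peak
#' potential, per sample — the univariate response used for single-analyte
#' calibration lines on baseline-corrected traces.
#'
#' @param set a [voltammogram_set()].
#' @param ep nominal anodic peak potential (V).
#' @param window half-width of the search window (V), default 0.05.
#' @return Numeric vector of apex currents, one per sample.
#' @export
peak_current <- function(set, ep, window = 0.05) {
  stopifnot(inherits(set, "voltammogram_set"))
  idx <- which(abs(set$grid$potentials - ep) <= window + 1e-12)
  if (length(idx) == 0) stop("no grid points within the peak window",
                             call. = FALSE)
  apply(set$matrix[, idx, drop = FALSE], 1, max)
}

#' Univariate calibration line
#'
#' Ordinary least squares fit of peak current against concentration, with
#' the Pearson correlation coefficient — the single-analyte calibration
#' performed before multivariate modelling.
#'
#' @param concs concentrations (mol/L), at least 3 distinct-valued points.
#' @param peak_currents matching apex currents.
#' @return An object of class `univariate_fit`: `slope` (current units per
#'   mol/L), `intercept` (current units), `r`.
#' @export
univariate_fit <- function(concs, peak_currents) {
  if (length(concs) != length(peak_currents) || length(concs) < 3) {
    stop("need >= 3 paired points", call. = FALSE)
  }
  if (stats::sd(concs) == 0) stop("degenerate: all concentrations equal",
                                  call. = FALSE)
  slope <- stats::cov(concs, peak_currents) / stats::var(concs)
  intercept <- mean(peak_currents) - slope * mean(concs)
  r <- if (stats::sd(peak_currents) == 0) 0 else
    stats::cor(concs, peak_currents)
  structure(list(slope = slope, intercept = intercept, r = r),
            class = "univariate_fit")
}
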
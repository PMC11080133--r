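#' icoshift parameters
#'
#' Interval-correlation-optimised shifting: signals are split into
#' consecutive intervals of `interval_width` points and each interval is
#' rigidly shifted by an integer number of points to maximise its
#' cross-correlation with the corresponding interval of a target trace.
#'
#' Note on the default width: 800 points exceeds the default 261-point
#' voltammogram, in which case the whole trace forms a single interval and
#' alignment reduces to one rigid shift per sample.
#'
#' @param interval_width interval width in points, >= 2.  Widths at or above
#'   the trace length give whole-trace alignment.
#' @param max_shift maximum |shift| in points, or `"best"` (the default) for
#'   `min(floor(interval_width / 2), 50)`.
#' @param target_mode `"average"`, `"median"`, `"max"` or a sample index /
#'   sample ID to align against one explicit trace.
#' @param fill_mode `"edge"` replicates the edge value into the vacated
#'   points; `"na_marker"` fills with the segment mean (keeping the marker
#'   auditable via the returned shift table).
#' @param passes maximum number of align-and-recompute-target passes
#'   (default 5).  Against a smeared average of misaligned traces a single
#'   correlation pass can leave one-point residual shifts on some samples;
#'   realigning to the recomputed (sharper) average converges to a fixed
#'   point, at which all shifts are zero, in a couple of passes.  Passes
#'   stop early at the fixed point; set 1 for classic single-pass
#'   behaviour.  Ignored when an explicit external target is supplied.
#' @param min_gain minimum relative correlation improvement a nonzero shift
#'   must deliver over leaving the segment in place (default 0, the pure
#'   argmax).  The
#'   cross-correlation of heavily overlapped peak clusters has a nearly
#'   flat top: when a sample's composition differs strongly from the
#'   target's, the flat top can tip the discrete argmax one point off even
#'   for perfectly aligned data, with a gain of only ~0.1-0.2 %, whereas
#'   undoing a genuine one-point misalignment gains >= 1 %.  The margin
#'   suppresses the former without touching the latter; set 0 for the pure
#'   argmax.
#' @return An object of class `icoshift_params`.
#' @export
icoshift_params <- function(interval_width = 800L, max_shift = "best",
                            target_mode = "average",
                            fill_mode = c("edge", "na_marker"),
                            passes = 5L, min_gain = 0) {
  if (interval_width < 2) stop("interval_width must be >= 2", call. = FALSE)
  if (!identical(max_shift, "best") && max_shift < 0) {
    stop("max_shift must be >= 0 or 'best'", call. = FALSE)
  }
  if (passes < 1) stop("passes must be >= 1", call. = FALSE)
  if (min_gain < 0) stop("min_gain must be >= 0", call. = FALSE)
  structure(list(interval_width = as.integer(interval_width),
                 max_shift = max_shift, target_mode = target_mode,
                 fill_mode = match.arg(fill_mode),
                 passes = as.integer(passes), min_gain = min_gain),
            class = "icoshift_params")
}

#' Build the alignment target trace
#'
#' @param set a [voltammogram_set()] with at least one sample.
#' @param mode `"average"` (column-wise mean, the default reference),
#'   `"median"`, `"max"` (the sample with the largest absolute current), or
#'   a sample index / ID.
#' @return A [voltammogram()].
#' @export
build_target <- function(set, mode = "average") {
  stopifnot(inherits(set, "voltammogram_set"))
  if (nrow(set$matrix) == 0) stop("cannot build a target from an empty set",
                                  call. = FALSE)
  cur <- if (identical(mode, "average")) {
    colMeans(set$matrix)
  } else if (identical(mode, "median")) {
    apply(set$matrix, 2, stats::median)
  } else if (identical(mode, "max")) {
    set$matrix[which.max(apply(abs(set$matrix), 1, max)), ]
  } else if (is.numeric(mode)) {
    set$matrix[as.integer(mode), ]
  } else if (is.character(mode) && mode %in% set$samples) {
    set$matrix[match(mode, set$samples), ]
  } else {
    stop("unknown target mode: ", mode, call. = FALSE)
  }
  voltammogram(set$grid, as.numeric(cur))
}

# rigid shift by s points (positive = rightward); vacated points filled
shift_segment <- function(x, s, fill_mode = "edge") {
  n <- length(x)
  if (s == 0) return(x)
  fill_lo <- if (fill_mode == "edge") x[1] else mean(x)
  fill_hi <- if (fill_mode == "edge") x[n] else mean(x)
  if (s > 0) {
    s <- min(s, n)
    c(rep(fill_lo, s), x[seq_len(n - s)])
  } else {
    s <- min(-s, n)
    c(x[(s + 1):n], rep(fill_hi, s))
  }
}

#' Align one segment to a target segment
#'
#' Exhaustive search over integer shifts `s` in `[-max_shift, max_shift]`
#' for the one maximising the inner product between the (mean-centred)
#' target segment and the segment shifted by `s` (positive = rightward).
#' Ties are broken toward smaller `|s|`, then toward negative `s`, so an
#' already-aligned segment keeps shift 0.
#'
#' @param segment numeric vector to align.
#' @param target_segment numeric vector, same length.
#' @param max_shift maximum |shift| in points.
#' @param fill_mode see [icoshift_params()].
#' @param min_gain relative improvement over the unshifted score a nonzero
#'   shift must reach to be accepted (default 0, the pure argmax; see
#'   [icoshift_params()]).
#' @return List with `shift` (the chosen `s`) and `aligned` (the shifted
#'   segment).
#' @export
align_interval <- function(segment, target_segment, max_shift,
                           fill_mode = "edge", min_gain = 0) {
  n <- length(segment)
  if (n < 2) stop("segment must have at least 2 points", call. = FALSE)
  if (length(target_segment) != n) {
    stop("segment and target segment differ in length", call. = FALSE)
  }
  tc <- target_segment - mean(target_segment)
  shifts <- seq.int(-max_shift, max_shift)
  # order candidates so that the first maximum found wins the tie-break:
  # smaller |s| first, negative before positive at equal |s|
  shifts <- shifts[order(abs(shifts), shifts)]
  best_s <- shifts[1]
  best_v <- NA_real_
  v0 <- NA_real_
  for (s in shifts) {
    sh <- shift_segment(segment, s, fill_mode)
    v <- sum(tc * (sh - mean(sh)))
    if (s == 0) v0 <- v
    if (is.na(best_v) || v > best_v + 1e-12 * max(1, abs(best_v))) {
      best_v <- v
      best_s <- s
    }
  }
  # flat-top guard: a nonzero move must beat staying put by min_gain
  if (min_gain > 0 && best_s != 0 && !is.na(v0) && v0 > 0 &&
      best_v < v0 * (1 + min_gain)) {
    best_s <- 0L
  }
  list(shift = best_s,
       aligned = shift_segment(segment, best_s, fill_mode))
}

#' icoshift alignment of a voltammogram set
#'
#' Splits each trace into consecutive intervals of
#' `params$interval_width` points (a trailing remainder of fewer than 2
#' points is merged into the previous interval; a width at or above the
#' trace length makes the whole trace one interval) and aligns every
#' interval of every sample to the target by [align_interval()].  Output
#' shape equals input shape.
#'
#' @param set a [voltammogram_set()].
#' @param params an [icoshift_params()].
#' @param target optional [voltammogram()] to align against (e.g. the
#'   calibration-set target when aligning unknowns); default builds it from
#'   `set` per `params$target_mode`.
#' @return List with `set` (aligned [voltammogram_set()]), `shifts`
#'   (samples x intervals integer matrix) and `target` (the
#'   [voltammogram()] used).
#' @export
icoshift_align <- function(set, params = icoshift_params(), target = NULL) {
  stopifnot(inherits(set, "voltammogram_set"),
            inherits(params, "icoshift_params"))
  passes <- if (is.null(target)) params$passes else 1L
  total_shifts <- NULL
  out <- set
  used_target <- target
  for (pass in seq_len(passes)) {
    res <- icoshift_pass(out, params, target)
    out <- res$set
    used_target <- res$target
    total_shifts <- if (is.null(total_shifts)) res$shifts else
      total_shifts + res$shifts
    if (all(res$shifts == 0L)) break
  }
  list(set = out, shifts = total_shifts, target = used_target)
}

# one alignment pass against a (possibly rebuilt) target
icoshift_pass <- function(set, params, target = NULL) {
  n_p <- set$grid$n_points
  w <- min(params$interval_width, n_p)
  starts <- seq.int(1L, n_p, by = w)
  ends <- pmin(starts + w - 1L, n_p)
  if (length(starts) > 1 && (ends[length(ends)] - starts[length(starts)] + 1) < 2) {
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
    ends[length(ends)] <- n_p
  }
  n_int <- length(starts)
  if (is.null(target)) target <- build_target(set, params$target_mode)
  stopifnot(inherits(target, "voltammogram"))
  out <- set$matrix
  shifts <- matrix(0L, nrow(out), n_int,
                   dimnames = list(set$samples, paste0("int", seq_len(n_int))))
  for (j in seq_len(n_int)) {
    idx <- starts[j]:ends[j]
    ms <- if (identical(params$max_shift, "best")) {
      min(length(idx) %/% 2L, 50L)
    } else as.integer(params$max_shift)
    tseg <- target$current[idx]
    for (i in seq_len(nrow(out))) {
      al <- align_interval(set$matrix[i, idx], tseg, ms, params$fill_mode,
                           params$min_gain)
      out[i, idx] <- al$aligned
      shifts[i, j] <- al$shift
    }
  }
  list(set = voltammogram_set(set$grid, out, samples = set$samples),
       shifts = shifts, target = target)
}
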
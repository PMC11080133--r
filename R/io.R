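#' Read a voltammogram set from CSV
#'
#' Expects the interchange layout written by [write_voltammogram_set()]:
#' a header row `sample_id, <E1>, <E2>, ...` with potentials in volts, then
#' one row per sample.  The grid is reconstructed from the header and checked
#' for uniform spacing.
#'
#' @param path CSV file path.
#' @return A [voltammogram_set()].
#' @export
read_voltammogram_set <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  if (ncol(df) < 3) stop("voltammogram CSV needs sample_id plus >= 2 potential columns",
                         call. = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("first CSV column must be 'sample_id'", call. = FALSE)
  }
  pots <- suppressWarnings(as.numeric(names(df)[-1]))
  if (any(is.na(pots))) {
    stop(sprintf("non-numeric potential header column: '%s'",
                 names(df)[-1][which(is.na(pots))[1]]), call. = FALSE)
  }
  steps <- diff(pots)
  step <- steps[1]
  bad <- which(abs(steps - step) > 1e-6 * max(abs(step), 1e-12))
  if (step <= 0 || length(bad) > 0) {
    off <- if (length(bad) > 0) bad[1] + 2L else 2L
    stop(sprintf("non-uniform potential grid in CSV header (column %d, '%s')",
                 off, names(df)[off]), call. = FALSE)
  }
  grid <- potential_grid(pots[1], pots[length(pots)], step)
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("ragged or non-numeric current rows in CSV", call. = FALSE)
  voltammogram_set(grid, mat, samples = as.character(df[[1]]))
}

#' Write a voltammogram set to CSV
#'
#' Full double precision (17 significant digits) so that
#' `read_voltammogram_set(write_voltammogram_set(x))` round-trips
#' bit-for-bit.  An empty set writes a header-only file.
#'
#' @param set a [voltammogram_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_voltammogram_set <- function(set, path) {
  stopifnot(inherits(set, "voltammogram_set"))
  header <- c("sample_id", format_potential(set$grid$potentials))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  if (nrow(set$matrix) > 0) {
    body <- vapply(seq_len(nrow(set$matrix)), function(i) {
      paste(c(set$samples[i],
              formatC(set$matrix[i, ], format = "g", digits = 17)),
            collapse = ",")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a concentration table from CSV
#'
#' Layout: `sample_id` column followed by one numeric column per analyte
#' (mol/L).
#'
#' @param path CSV file path.
#' @return A [conc_table()].
#' @export
read_conc_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("first CSV column must be 'sample_id'", call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  conc_table(vals, samples = as.character(df[[1]]),
             analytes = names(df)[-1])
}

#' Write a concentration table to CSV
#'
#' @param table a [conc_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_conc_table <- function(table, path) {
  stopifnot(inherits(table, "conc_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", table$analytes), collapse = ","), con)
  if (length(table$samples) > 0) {
    body <- vapply(seq_along(table$samples), function(i) {
      paste(c(table$samples[i],
              formatC(table$values[i, ], format = "g", digits = 17)),
            collapse = ",")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}
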
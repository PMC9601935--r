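#' Canonical risk-factor names
#'
#' The 32 ordered risk-factor names of the UCI cervical cancer (risk factors)
#' table, in their standard 1-based numbering, and the four screening-test
#' target names. Factor identity is tracked by this numbering throughout the
#' package (feature rankings, factor drops, selection modes).
#'
#' @return `risk_factor_names()` returns a character vector of length 32;
#'   `target_names()` a character vector of length 4.
#' @export
risk_factor_names <- function() {
  c("Age",
    "Number of sexual partners",
    "First sexual intercourse (age)",
    "Number of pregnancies",
    "Smokes",
    "Smokes (years)",
    "Smokes (packs/year)",
    "Hormonal contraceptives",
    "Hormonal contraceptives (years)",
    "Intrauterine Device (IUD)",
    "IUD (years)",
    "Sexually Transmitted Diseases (STDs)",
    "STDs (number)",
    "STDs: condylomatosis",
    "STDs: cervical condylomatosis",
    "STDs: vaginal condylomatosis",
    "STDs: vulvo-perineal condylomatosis",
    "STDs: syphilis",
    "STDs: pelvic inflammatory disease",
    "STDs: genital herpes",
    "STDs: molluscum contagiosum",
    "STDs: AIDS",
    "STDs: HIV",
    "STDs: Hepatitis B",
    "STDs: HPV",
    "STDs: Number of diagnoses",
    "STDs: Time since first diagnosis",
    "STDs: Time since last diagnosis",
    "Dx: Cancer",
    "Dx: CIN",
    "Dx: HPV",
    "Diagnosis (Dx)")
}

#' @rdname risk_factor_names
#' @export
target_names <- function() {
  c("Hinselmann", "Schiller", "Cytology", "Biopsy")
}

#' Read a patient-by-risk-factor CSV table
#'
#' Reads a comma-separated table in the UCI dialect: a header row, numeric
#' cells, and a sentinel string (`"?"` by default) marking missing values.
#' The last four columns are taken as the binary screening-test targets and
#' all preceding columns as risk factors.
#'
#' @param path Path to the CSV file.
#' @param missing_marker String marking a missing cell. Default `"?"`.
#' @return An object of class `raw_table`: a list with `values` (numeric
#'   matrix, `NA` for missing), `n_rows`, `factor_names`, and `target_names`.
#' @details Malformed rows (wrong width) and non-numeric non-missing cells
#'   are hard errors naming the offending row.
#' @export
read_table <- function(path, missing_marker = "?") {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("no data rows: file is empty")
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  header <- trimws(header)
  n_col <- length(header)
  if (n_col < 5L) stop("table must have at least one factor and four target columns")
  if (length(lines) < 2L) stop("no data rows")
  body <- strsplit(lines[-1L], ",", fixed = TRUE)
  widths <- lengths(body)
  bad <- which(widths != n_col)
  if (length(bad) > 0L) {
    stop(sprintf("malformed row width at data row %d: expected %d cells, found %d",
                 bad[[1L]], n_col, widths[[bad[[1L]]]]))
  }
  cells <- trimws(matrix(unlist(body), nrow = length(body), ncol = n_col, byrow = TRUE))
  is_missing <- cells == missing_marker
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad_cell <- which(is.na(values) & !is_missing, arr.ind = TRUE)
  if (nrow(bad_cell) > 0L) {
    stop(sprintf("non-numeric non-missing cell at data row %d, column '%s'",
                 bad_cell[1L, 1L], header[[bad_cell[1L, 2L]]]))
  }
  values[is_missing] <- NA_real_
  colnames(values) <- header
  out <- structure(list(
    values = values,
    n_rows = nrow(values),
    factor_names = header[seq_len(n_col - 4L)],
    target_names = header[seq(n_col - 3L, n_col)]
  ), class = "raw_table")
  gamlp_log(sprintf("read_table: %d rows, %d columns (%d factors, 4 targets), %d missing cells",
                    out$n_rows, n_col, n_col - 4L, sum(is_missing)))
  out
}

#' @export
print.raw_table <- function(x, ...) {
  cat(sprintf("raw_table: %d rows x %d columns (%d factors + %d targets), %d missing cells\n",
              x$n_rows, ncol(x$values), length(x$factor_names),
              length(x$target_names), sum(is.na(x$values))))
  invisible(x)
}

#' Write a raw table back to CSV in the UCI dialect
#'
#' @param raw A `raw_table`.
#' @param path Output path.
#' @param missing_marker Sentinel written for missing cells.
#' @return `path`, invisibly.
#' @export
write_raw_table <- function(raw, path, missing_marker = "?") {
  stopifnot(inherits(raw, "raw_table"))
  cells <- format_num_cell(raw$values)
  cells[is.na(raw$values)] <- missing_marker
  lines <- c(paste(colnames(raw$values), collapse = ","),
             apply(cells, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

# format numbers compactly and stably (integers without decimals)
format_num_cell <- function(v) {
  out <- formatC(v, format = "g", digits = 15)
  out[] <- sub("^\\s+", "", out)
  out
}

#' Preprocess a raw risk-factor table
#'
#' Applies the standard cleaning protocol for this dataset family: drop the
#' factors listed in `drop_factors` (by their 1-based factor number; the two
#' "time since STD diagnosis" factors 27 and 28 by default, which are mostly
#' missing), remove every row that still contains a missing cell in a
#' retained factor or target column, and min-max scale each continuous
#' factor to \[0, 1\] (binary 0/1 factors pass through unchanged; constant
#' columns map to 0).
#'
#' @param raw A `raw_table` from [read_table()] or [generate_synthetic()].
#' @param drop_factors Integer vector of 1-based factor numbers to drop.
#' @param normalize Logical; min-max scale continuous factors. Default `TRUE`.
#' @return An object of class `clean_dataset`: list with `X` (numeric matrix,
#'   no missing values), `y` (named list of binary 0/1 vectors, one per
#'   target), `retained_factor_ids` (1-based factor numbers, in order), and
#'   `report` (a `preprocess_report` with row/column bookkeeping).
#' @export
preprocess <- function(raw, drop_factors = c(27L, 28L), normalize = TRUE) {
  stopifnot(inherits(raw, "raw_table"))
  p <- length(raw$factor_names)
  drop_factors <- as.integer(drop_factors)
  if (length(drop_factors) > 0L && !all(drop_factors %in% seq_len(p))) {
    stop("drop_factors must be a subset of 1..", p)
  }
  n_targets <- length(raw$target_names)
  if (n_targets < 1L) stop("target columns missing")
  retained <- setdiff(seq_len(p), drop_factors)
  Xall <- raw$values[, retained, drop = FALSE]
  Tall <- raw$values[, p + seq_len(n_targets), drop = FALSE]
  keep <- stats::complete.cases(cbind(Xall, Tall))
  if (!any(keep)) stop("all rows removed: every row has a missing value in a retained column")
  X <- Xall[keep, , drop = FALSE]
  Tm <- Tall[keep, , drop = FALSE]
  if (!all(Tm %in% c(0, 1))) stop("target columns must be binary 0/1 after row filtering")

  binary <- apply(X, 2L, function(col) all(col %in% c(0, 1)))
  if (isTRUE(normalize)) {
    for (j in which(!binary)) {
      rng <- range(X[, j])
      X[, j] <- if (diff(rng) == 0) 0 else (X[, j] - rng[1L]) / diff(rng)
    }
  }
  report <- structure(list(
    rows_before = raw$n_rows,
    rows_after = nrow(X),
    rows_removed = raw$n_rows - nrow(X),
    dropped_factors = drop_factors,
    retained_factor_ids = retained,
    n_continuous = sum(!binary),
    n_binary = sum(binary),
    normalized = isTRUE(normalize)
  ), class = "preprocess_report")
  # The reference cleaning of the full 858-row table retains 668 rows; if an
  # 858-row input lands elsewhere the row-filter rule differs from the
  # reference protocol, which is worth a warning but not an error.
  if (raw$n_rows == 858L && nrow(X) != 668L) {
    warning(sprintf("858-row input retained %d rows; the reference protocol retains 668",
                    nrow(X)))
  }
  gamlp_log(sprintf("preprocess: %d -> %d rows; dropped factors: %s",
                    raw$n_rows, nrow(X),
                    if (length(drop_factors)) paste(drop_factors, collapse = ", ") else "none"))
  y <- lapply(seq_len(n_targets), function(k) as.integer(Tm[, k]))
  names(y) <- raw$target_names
  structure(list(X = X, y = y, retained_factor_ids = retained, report = report),
            class = "clean_dataset")
}

#' @export
print.clean_dataset <- function(x, ...) {
  prev <- vapply(x$y, mean, numeric(1)) * 100
  cat(sprintf("clean_dataset: %d rows x %d factors\n", nrow(x$X), ncol(x$X)))
  cat("target prevalence (%):\n")
  print(round(prev, 1))
  invisible(x)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("preprocess_report: %d -> %d rows (%d removed); dropped factors: %s; %d continuous%s, %d binary factors\n",
              x$rows_before, x$rows_after, x$rows_removed,
              if (length(x$dropped_factors)) paste(x$dropped_factors, collapse = ", ") else "none",
              x$n_continuous, if (x$normalized) " (min-max scaled)" else "",
              x$n_binary))
  invisible(x)
}

#' Balance a binary classification dataset by random oversampling
#'
#' Duplicates minority-class rows uniformly at random with replacement until
#' both classes have equal counts. Majority rows are untouched; an already
#' balanced input is returned unchanged.
#'
#' @param X Numeric matrix of predictors.
#' @param y Binary 0/1 vector, one entry per row of `X`.
#' @param seed Integer seed; the duplication draw is deterministic given it.
#' @return An object of class `balanced_dataset`: list with `X`, `y` (equal
#'   class counts) and `provenance`, the source row index of every output row
#'   (duplicates allowed).
#' @export
oversample <- function(X, y, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  counts <- tabulate(y + 1L, nbins = 2L)
  if (any(counts == 0L)) stop("oversample requires both classes present")
  if (counts[1L] == counts[2L]) {
    return(structure(list(X = X, y = y, provenance = seq_along(y)),
                     class = "balanced_dataset"))
  }
  minority <- if (counts[1L] < counts[2L]) 0L else 1L
  deficit <- abs(diff(counts))
  min_idx <- which(y == minority)
  extra <- with_seed(derive_seed(seed, "oversample"),
                     min_idx[sample.int(length(min_idx), deficit, replace = TRUE)])
  provenance <- c(seq_along(y), extra)
  structure(list(X = X[provenance, , drop = FALSE],
                 y = y[provenance],
                 provenance = provenance),
            class = "balanced_dataset")
}

#' @export
print.balanced_dataset <- function(x, ...) {
  cat(sprintf("balanced_dataset: %d rows (%d per class), %d duplicated rows\n",
              length(x$y), sum(x$y == 1L), length(x$y) - length(unique(x$provenance))))
  invisible(x)
}
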
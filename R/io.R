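#' Read and write labeled square matrices as tab-separated text
#'
#' Matrices are stored as TSV with a header row of parcel labels and a leading
#' label column, at full double precision (shortest round-trip
#' representation), so write-then-read is lossless. `read_matrix()` validates
#' shape and symmetry and reports the offending line on malformed input.
#'
#' @param m Square numeric matrix.
#' @param path File path.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()` returns
#'   the matrix with dimnames.
#' @export
write_matrix <- function(m, path) {
  check_square_symmetric(m, tol = Inf, arg = "m")
  lb <- node_labels(m)
  # %.17g is enough digits to reproduce any double exactly on re-parse
  chr <- matrix(sprintf("%.17g", m), nrow(m))
  df <- tibble::as_tibble(chr, .name_repair = ~lb)
  df <- dplyr::bind_cols(tibble::tibble(parcel = lb), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix
#' @param check_symmetric Validate symmetry on read (tolerance 1e-9).
#' @export
read_matrix <- function(path, check_symmetric = TRUE) {
  # base parser: strtod is correctly rounded, so %.17g output re-reads exactly
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, colClasses = NA),
    error = function(e) {
      abort(sprintf("Malformed matrix file '%s': %s", path, conditionMessage(e)))
    }
  )
  if (!"parcel" %in% names(df)) {
    abort(sprintf("Matrix file '%s' lacks the leading 'parcel' label column.", path))
  }
  vals <- df[, setdiff(names(df), "parcel"), drop = FALSE]
  numeric_ok <- vapply(vals, is.numeric, logical(1))
  if (!all(numeric_ok)) {
    col <- names(vals)[!numeric_ok][1]
    bad <- which(is.na(suppressWarnings(as.numeric(vals[[col]]))))[1]
    abort(sprintf("Non-numeric cell in '%s', column '%s', data line %d.",
                  path, col, bad))
  }
  m <- as.matrix(vals)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    abort(sprintf("Non-numeric or missing cell in '%s' at data line %d.", path, bad))
  }
  colnames(m) <- names(vals)
  if (nrow(m) != ncol(m)) {
    abort(sprintf("Matrix file '%s' is %d x %d, not square.", path, nrow(m), ncol(m)))
  }
  dimnames(m) <- list(as.character(df$parcel), colnames(m))
  if (!identical(rownames(m), colnames(m))) {
    abort(sprintf("Row and column labels disagree in '%s'.", path))
  }
  if (check_symmetric && max(abs(m - t(m))) > 1e-9) {
    abort(sprintf("Matrix in '%s' is asymmetric beyond 1e-9.", path))
  }
  m
}

#' Read a subject time-series TSV (timepoints x parcels, header of labels)
#'
#' @param path File path.
#' @return Numeric matrix with parcel-label colnames.
#' @export
read_timeseries <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, colClasses = "numeric"),
    error = function(e) {
      abort(sprintf("Malformed time-series file '%s': %s",
                    path, conditionMessage(e)))
    }
  )
  m <- as.matrix(df)
  if (anyNA(m)) abort(sprintf("Missing values in time-series file '%s'.", path))
  m
}

#' Read a design table (subject_id, group, age, score columns)
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_design <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
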
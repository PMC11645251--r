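#' Coerce to a taxon-by-sample count matrix
#'
#' Count tables are represented throughout the package as numeric matrices
#' with taxa in rows and samples in columns, carrying taxon ids as row names
#' and sample ids as column names. This helper accepts such a matrix, or a
#' data frame / tibble whose first column holds taxon ids and whose remaining
#' columns are one sample each, and returns the validated matrix form.
#'
#' @param x A taxa-by-samples matrix, or a data frame with taxon ids in the
#'   first column and one numeric column per sample.
#' @param integer_counts Require entries to be whole numbers (default `TRUE`).
#'   Averaged rarefied tables are real-valued; pass `FALSE` for those.
#'
#' @return A numeric matrix, taxa x samples, with dimnames set.
#' @export
#'
#' @examples
#' tbl <- tibble::tibble(taxon = c("A", "B"), s1 = c(2, 3), s2 = c(0, 5))
#' as_count_matrix(tbl)
as_count_matrix <- function(x, integer_counts = TRUE) {
  if (is.data.frame(x)) {
    taxa <- as.character(x[[1L]])
    m <- as.matrix(x[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- taxa
  } else if (is.matrix(x)) {
    m <- x
    storage.mode(m) <- "double"
  } else {
    stopf("counts must be a matrix or a data frame, not %s", class(x)[1L])
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("taxon", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("sample", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m))) stopf("duplicate taxon ids in count table")
  if (nrow(m) < 2L) stopf("count table needs at least 2 taxa, got %d", nrow(m))
  if (ncol(m) < 1L) stopf("count table needs at least 1 sample")
  if (any(!is.finite(m))) stopf("count table contains non-finite entries")
  if (any(m < 0)) stopf("count table contains negative entries")
  if (integer_counts && any(abs(m - round(m)) > 1e-8)) {
    stopf("count table contains non-integer entries")
  }
  m
}

#' Per-sample library sizes
#'
#' @param counts A taxa-by-samples count matrix (see [as_count_matrix()]).
#' @return Named numeric vector of column sums.
#' @export
library_sizes <- function(counts) {
  colSums(as_count_matrix(counts, integer_counts = FALSE))
}

#' Read a taxon-by-sample count table from TSV
#'
#' The expected layout is one header row of sample ids, a first column of
#' taxon ids, and integer cells; this is the plain-text exchange format used
#' by all command-line entry points.
#'
#' @param path Path to a tab-separated file.
#' @return A taxa-by-samples numeric matrix with dimnames.
#' @export
read_counts <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (ncol(tbl) < 2L) stopf("'%s': no sample columns found", path)
  bad <- which(!vapply(tbl[-1L], is.numeric, logical(1L)))
  if (length(bad)) {
    stopf("'%s': non-numeric cells in column(s) %s", path,
          paste(names(tbl)[-1L][bad], collapse = ", "))
  }
  as_count_matrix(tbl)
}

#' Write a count table as TSV
#'
#' @param counts Taxa-by-samples matrix or data frame.
#' @param path Output path.
#' @param id_column Name for the taxon-id column (default `"taxon"`).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, id_column = "taxon") {
  m <- as_count_matrix(counts, integer_counts = FALSE)
  tbl <- tibble::as_tibble(m, rownames = id_column)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read a per-sample covariate table and align it to a count table
#'
#' The CSV holds sample ids in its first column and numeric covariates in the
#' remaining columns (zero covariate columns gives an intercept-only design).
#' Rows are reordered to match the column order of `counts`; unreferenced ids
#' are dropped with a warning and missing ids or `NA` cells are errors.
#'
#' @param path Path to a CSV file.
#' @param counts Count matrix whose sample order defines the alignment; `NULL`
#'   keeps file order.
#' @return A samples-by-covariates numeric matrix with sample ids as row names.
#' @export
read_covariates <- function(path, counts = NULL) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  ids <- as.character(tbl[[1L]])
  if (anyDuplicated(ids)) stopf("'%s': duplicate sample ids", path)
  x <- as.matrix(tbl[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- ids
  if (anyNA(x)) stopf("'%s': missing covariate values", path)
  if (!is.null(counts)) {
    want <- colnames(as_count_matrix(counts, integer_counts = FALSE))
    missing <- setdiff(want, ids)
    if (length(missing)) {
      stopf("'%s': no covariates for sample(s) %s", path,
            paste(missing, collapse = ", "))
    }
    extra <- setdiff(ids, want)
    if (length(extra)) {
      warning(sprintf("dropping %d covariate row(s) not present in counts",
                      length(extra)), call. = FALSE)
    }
    x <- x[want, , drop = FALSE]
  }
  x
}

# Normalize a covariate input: NULL -> intercept-only (0-column) matrix.
as_covariate_matrix <- function(x, n_samples) {
  if (is.null(x)) {
    x <- matrix(numeric(0), nrow = n_samples, ncol = 0L)
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  if (nrow(x) != n_samples) {
    stopf("covariate table has %d rows but there are %d samples",
          nrow(x), n_samples)
  }
  if (any(!is.finite(x))) stopf("covariates must be finite")
  x
}
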
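#' Build a connectome from regional time series
#'
#' Computes all pairwise Pearson correlations between mean regional time
#' series and applies Fisher's Z-transformation `z = atanh(r)`.  The
#' diagonal is defined as exactly zero (a self-correlation of 1 has
#' infinite z, and the diagonal never enters any downstream statistic).
#' An off-diagonal |r| of 1 is degenerate and raises an error naming the
#' offending pair.
#'
#' @param ts a `region_timeseries`.
#' @return A `functional_connectome` with the time series' region order.
#' @export
build_connectome <- function(ts) {
  stopifnot(inherits(ts, "region_timeseries"))
  r <- stats::cor(ts$data)
  off <- abs(r) >= 1 - .Machine$double.eps^0.5
  diag(off) <- FALSE
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)[1, ]
    stop("degenerate correlation |r| = 1 between regions ",
         ts$regions[idx[1]], " and ", ts$regions[idx[2]],
         "; Fisher z would be infinite", call. = FALSE)
  }
  z <- atanh(r)
  diag(z) <- 0
  functional_connectome(z, ts$regions, diag_zero = TRUE, sym_tol = 1e-10)
}

#' Group-averaged connectome
#'
#' Entrywise arithmetic mean of the Fisher-z connectomes of all subjects
#' carrying a given group label, the healthy reference used throughout
#' the stimulation objective.
#'
#' @param cohort a `cohort_data`.
#' @param label `"healthy"` or `"patient"`.
#' @param exclude optional subject ids to leave out (used for
#'   leave-one-out references).
#' @return A `functional_connectome`.
#' @export
group_average <- function(cohort, label = "healthy", exclude = NULL) {
  stopifnot(inherits(cohort, "cohort_data"))
  ids <- names(cohort$subjects)[cohort$groups == label]
  ids <- setdiff(ids, exclude)
  if (!length(ids)) stop("no subjects with label '", label, "' to average", call. = FALSE)
  acc <- Reduce(`+`, lapply(cohort$subjects[ids], function(s) s$matrix))
  functional_connectome(acc / length(ids), cohort$regions, diag_zero = TRUE)
}

#' Read / write a connectome TSV
#'
#' Plain-text interchange format: a tab-separated square matrix whose
#' first row and first column hold the region abbreviations.  The reader
#' validates squareness and symmetry and, when a parcellation is given,
#' that the region order matches it exactly.
#'
#' @param path file path.
#' @param parc optional `parcellation` to validate region order against.
#' @param diag_zero whether the matrix must carry the measured-connectome
#'   zero diagonal.
#' @return `read_connectome()` returns a `functional_connectome`;
#'   `write_connectome()` returns `path` invisibly.
#' @export
read_connectome <- function(path, parc = NULL, diag_zero = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("connectome file is not square: ", path, call. = FALSE)
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column region labels disagree in ", path, call. = FALSE)
  }
  if (!is.null(parc) && !identical(rownames(m), parc$abbreviation)) {
    stop("region order in ", path, " does not match the parcellation", call. = FALSE)
  }
  functional_connectome(m, rownames(m), diag_zero = diag_zero, sym_tol = 1e-8)
}

#' @param f a `functional_connectome`.
#' @rdname read_connectome
#' @export
write_connectome <- function(f, path) {
  stopifnot(inherits(f, "functional_connectome"))
  df <- as.data.frame(f$matrix)
  utils::write.table(cbind(region = f$regions, df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write regional time series TSV
#'
#' Tab-separated, header = region abbreviations, one row per volume.
#'
#' @param path file path.
#' @param tr_seconds repetition time metadata.
#' @return `read_timeseries()` returns a `region_timeseries`.
#' @export
read_timeseries <- function(path, tr_seconds = 2) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  region_timeseries(as.matrix(df), colnames(df), tr_seconds = tr_seconds)
}

#' @param ts a `region_timeseries`.
#' @rdname read_timeseries
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "region_timeseries"))
  utils::write.table(ts$data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
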
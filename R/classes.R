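#' Functional connectome
#'
#' A square symmetric region-by-region matrix of Fisher-z transformed
#' Pearson correlations, together with its ordered region identifiers.
#' Measured connectomes (built from time series or read from disk) carry a
#' diagonal fixed at exactly zero: the Fisher z of a self-correlation is
#' infinite, and no similarity or group statistic in the package ever uses
#' the diagonal.  Connectomes produced by [transitive_closure()] are exempt
#' from the zero-diagonal policy, because the analytic closure of a direct
#' network generally has nonzero diagonal and zeroing it would break the
#' exact inverse relationship with [network_deconvolution()].
#'
#' @param matrix square symmetric numeric matrix (Fisher-z units).
#' @param regions character vector of region identifiers, one per
#'   row/column; defaults to existing dimnames or `V1..Vn`.
#' @param diag_zero logical; enforce an exactly zero diagonal (the policy
#'   for measured connectomes).
#' @param sym_tol asymmetry beyond this is an error; below it the matrix
#'   is symmetrized as `(M + t(M))/2`.
#'
#' @return An object of class `functional_connectome` with fields
#'   `matrix`, `regions`, `diag_zero`.
#' @export
functional_connectome <- function(matrix, regions = NULL, diag_zero = TRUE,
                                  sym_tol = 1e-12) {
  m <- check_symmetric(matrix, tol = sym_tol, what = "connectome matrix")
  n <- nrow(m)
  regions <- resolve_regions(regions, matrix, n)
  if (diag_zero) {
    bad <- which(diag(m) != 0)
    if (length(bad)) {
      if (max(abs(diag(m))) > sym_tol) {
        stop("measured connectome must have zero diagonal; offending region(s): ",
             paste(regions[utils::head(bad, 3)], collapse = ", "), call. = FALSE)
      }
      diag(m) <- 0
    }
  }
  dimnames(m) <- list(regions, regions)
  structure(list(matrix = m, regions = regions, diag_zero = diag_zero),
            class = "functional_connectome")
}

#' Direct network
#'
#' The direct-interaction matrix D recovered from a functional connectome
#' by [network_deconvolution()], or constructed synthetically.  The
#' functional connectome is modelled as the sum of all walks through D
#' (`F = D + D^2 + D^3 + ...`), so D must have spectral radius below 1 for
#' its transitive closure to exist.
#'
#' @param matrix square symmetric numeric matrix.
#' @param regions character vector of region identifiers.
#' @param sym_tol asymmetry tolerance, as in [functional_connectome()].
#' @return An object of class `direct_network`.
#' @export
direct_network <- function(matrix, regions = NULL, sym_tol = 1e-12) {
  m <- check_symmetric(matrix, tol = sym_tol, what = "direct network matrix")
  regions <- resolve_regions(regions, matrix, nrow(m))
  dimnames(m) <- list(regions, regions)
  structure(list(matrix = m, regions = regions), class = "direct_network")
}

resolve_regions <- function(regions, original, n) {
  if (is.null(regions)) {
    regions <- rownames(original) %||% paste0("V", seq_len(n))
  }
  regions <- as.character(regions)
  if (length(regions) != n) {
    stop("length(regions) must equal matrix dimension", call. = FALSE)
  }
  if (anyDuplicated(regions)) stop("region identifiers must be unique", call. = FALSE)
  regions
}

#' @export
print.functional_connectome <- function(x, ...) {
  cat("<functional_connectome> ", length(x$regions), " regions",
      if (x$diag_zero) ", zero diagonal" else "", "\n", sep = "")
  cat("  spectral radius: ", format(spectral_radius(x$matrix), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
print.direct_network <- function(x, ...) {
  cat("<direct_network> ", length(x$regions), " regions\n", sep = "")
  cat("  spectral radius: ", format(spectral_radius(x$matrix), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Region time series
#'
#' A time-by-region table of mean regional signals from which a
#' connectome is built.  At least three time points are required and no
#' column may be constant (its correlations would be undefined).
#'
#' @param data numeric matrix, rows = time points, columns = regions.
#' @param regions region identifiers (defaults to column names).
#' @param tr_seconds repetition time in seconds (metadata only).
#' @return An object of class `region_timeseries`.
#' @export
region_timeseries <- function(data, regions = NULL, tr_seconds = 2) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("time series must be a numeric matrix (time x region)", call. = FALSE)
  }
  if (anyNA(data)) stop("time series contain NA; imputation is out of scope", call. = FALSE)
  if (nrow(data) < 3) stop("need at least 3 time points", call. = FALSE)
  if (is.null(regions)) regions <- colnames(data) %||% paste0("V", seq_len(ncol(data)))
  regions <- as.character(regions)
  if (length(regions) != ncol(data)) stop("one region id per column required", call. = FALSE)
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant time series in region(s): ",
         paste(regions[sds == 0], collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) stop("tr_seconds must be positive", call. = FALSE)
  colnames(data) <- regions
  structure(list(data = data, regions = regions, tr_seconds = tr_seconds),
            class = "region_timeseries")
}

#' Cohort container
#'
#' Bundles subject connectomes with their group labels (`"patient"` or
#' `"healthy"`) and an optional table of clinical severity scores
#' (e.g. UPDRS-III) used for rank-severity correlation.
#'
#' @param subjects named list of `functional_connectome` objects (names =
#'   subject ids).
#' @param groups character vector, one label per subject, each
#'   `"patient"` or `"healthy"`.
#' @param clinical optional named numeric vector of clinical scores,
#'   names matching subject ids.
#' @return An object of class `cohort_data`.
#' @export
cohort_data <- function(subjects, groups, clinical = NULL) {
  if (!length(subjects)) stop("cohort must contain at least one subject", call. = FALSE)
  if (is.null(names(subjects)) || anyDuplicated(names(subjects))) {
    stop("subjects must be a uniquely named list", call. = FALSE)
  }
  ok <- vapply(subjects, inherits, logical(1), "functional_connectome")
  if (!all(ok)) stop("every subject must be a functional_connectome", call. = FALSE)
  groups <- as.character(groups)
  if (length(groups) != length(subjects)) stop("one group label per subject required", call. = FALSE)
  if (!all(groups %in% c("patient", "healthy"))) {
    stop('group labels must be "patient" or "healthy"', call. = FALSE)
  }
  ref <- subjects[[1]]$regions
  same <- vapply(subjects, function(s) identical(s$regions, ref), logical(1))
  if (!all(same)) stop("all subjects must share one parcellation and region order", call. = FALSE)
  if (!is.null(clinical)) {
    if (is.null(names(clinical))) stop("clinical scores must be named by subject id", call. = FALSE)
    unknown <- setdiff(names(clinical), names(subjects))
    if (length(unknown)) stop("clinical scores for unknown subject(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(subjects = subjects, groups = stats::setNames(groups, names(subjects)),
                 clinical = clinical, regions = ref),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("<cohort_data> ", sum(x$groups == "patient"), " patients, ",
      sum(x$groups == "healthy"), " healthy, ",
      length(x$regions), " regions\n", sep = "")
  invisible(x)
}

#' Subset a cohort by subject id
#'
#' @param cohort a `cohort_data` object.
#' @param ids subject ids to keep (order preserved).
#' @return A `cohort_data` with only the requested subjects.
#' @export
cohort_subset <- function(cohort, ids) {
  stopifnot(inherits(cohort, "cohort_data"))
  missing_ids <- setdiff(ids, names(cohort$subjects))
  if (length(missing_ids)) stop("unknown subject id(s): ",
                                paste(missing_ids, collapse = ", "), call. = FALSE)
  clin <- cohort$clinical
  if (!is.null(clin)) clin <- clin[intersect(names(clin), ids)]
  cohort_data(cohort$subjects[ids], unname(cohort$groups[ids]),
              if (length(clin)) clin else NULL)
}
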
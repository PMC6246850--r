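# Internal helpers shared across modules.

# Symmetry guard: asymmetry above `tol` is an input error, below it the
# matrix is symmetrized as (M + t(M))/2 so that downstream closed forms
# (which assume exact symmetry) are well posed.
check_symmetric <- function(m, tol = 1e-12, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square numeric matrix", call. = FALSE)
  }
  if (anyNA(m)) stop(what, " contains NA/NaN values", call. = FALSE)
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop(what, " is asymmetric beyond tolerance (max |M - t(M)| = ",
         format(asym), " > ", format(tol), ")", call. = FALSE)
  }
  (m + t(m)) / 2
}

# Eigenvalues of a symmetric matrix, values only (cheap path).
sym_eigenvalues <- function(m) {
  eigen(m, symmetric = TRUE, only.values = TRUE)$values
}

spectral_radius <- function(m) {
  max(abs(sym_eigenvalues(m)))
}

# Strictly-upper-triangle vectorization in row-major order, the edge
# ordering used by every similarity and edge-wise statistic.
upper_tri_index <- function(n) {
  which(upper.tri(matrix(0, n, n)))
}

# Row-major upper triangle of a square matrix.  For symmetric matrices the
# column-major upper triangle equals the row-major one up to a permutation
# shared by every matrix of the same size, so all correlations are
# unaffected; we still expose row-major order for file outputs.
upper_tri_vector <- function(m) {
  t(m)[lower.tri(m)]
}

# Edge index table (i < j) in the same row-major order as upper_tri_vector.
edge_table <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  data.frame(i = i, j = j)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
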
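#' Network deconvolution
#'
#' Recovers the direct-interaction network D from an observed functional
#' connectome F under the diffusion model `F = D + D^2 + D^3 + ...`.
#' With the eigendecomposition `F = U diag(lambda_i) U'` the closed-form
#' solution is `D = U diag(lambda_i / (1 + lambda_i)) U'`: every
#' eigenvalue is mapped by `x -> x/(1+x)` while the eigenvectors are kept.
#' The transform is the exact inverse of [transitive_closure()].
#'
#' The returned matrix is not diagonal-zeroed: the closed form generally
#' produces nonzero diagonals and zeroing them would destroy the analytic
#' inverse pair.
#'
#' @param f a `functional_connectome` (or plain symmetric matrix).
#' @param tol guard tolerance: an eigenvalue within `tol` of -1 makes the
#'   transform singular and is an error.
#' @return A `direct_network` with the same region order.
#' @export
network_deconvolution <- function(f, tol = 1e-9) {
  m <- transform_input(f, "functional_connectome")
  e <- eigen(m$matrix, symmetric = TRUE)
  bad <- which(abs(e$values + 1) < tol)
  if (length(bad)) {
    stop("network deconvolution is singular: eigenvalue ",
         format(e$values[bad[1]], digits = 12), " within ", format(tol),
         " of -1", call. = FALSE)
  }
  d <- eigen_map(e, e$values / (1 + e$values))
  direct_network(d, m$regions)
}

#' Transitive closure
#'
#' Re-convolves a direct network into the full functional connectome by
#' summing all walk contributions: `TC(D) = D + D^2 + D^3 + ...`, which
#' for spectral radius below 1 equals `V diag(eta_i / (1 - eta_i)) V'`
#' where `D = V diag(eta_i) V'`.  Any eigenvalue at or above 1 makes the
#' series diverge; this raises a condition of class
#' `connstim_divergence`, which the stimulation sweep catches and records
#' as an infeasible stimulation strength.
#'
#' @param d a `direct_network` (or plain symmetric matrix).
#' @param tol divergence guard: eigenvalues must stay below `1 - tol`.
#' @return A `functional_connectome` (diagonal not forced to zero).
#' @export
transitive_closure <- function(d, tol = 1e-9) {
  m <- transform_input(d, "direct_network")
  e <- eigen(m$matrix, symmetric = TRUE)
  if (max(e$values) >= 1 - tol) {
    stop(divergence_condition(max(e$values), tol))
  }
  f <- eigen_map(e, e$values / (1 - e$values))
  functional_connectome(f, m$regions, diag_zero = FALSE)
}

divergence_condition <- function(eta_max, tol) {
  structure(
    class = c("connstim_divergence", "error", "condition"),
    list(message = paste0("transitive closure diverges: largest eigenvalue ",
                          format(eta_max, digits = 12), " >= 1 - ", format(tol),
                          " (post-stimulation network infeasible)"),
         call = NULL, eta_max = eta_max)
  )
}

# Rebuild U diag(vals) U' and re-symmetrize against rounding.
eigen_map <- function(e, mapped) {
  m <- e$vectors %*% (mapped * t(e$vectors))
  (m + t(m)) / 2
}

transform_input <- function(x, cls) {
  if (inherits(x, cls)) {
    list(matrix = x$matrix, regions = x$regions)
  } else if (inherits(x, c("functional_connectome", "direct_network"))) {
    list(matrix = x$matrix, regions = x$regions)
  } else {
    m <- check_symmetric(x, what = "matrix")
    list(matrix = m, regions = rownames(m) %||% paste0("V", seq_len(nrow(m))))
  }
}

#' Pooled spectral scaling factor
#'
#' Before simulation every connectome is multiplied by one pooled
#' constant alpha chosen so that all deconvolved networks have spectral
#' radius at most `beta` (default 0.5), guaranteeing convergence of the
#' transitive closure even after sizeable stimulation.  The per-matrix
#' upper bound is
#' `alpha^i = min(beta / ((1-beta) lambda+), -beta / ((1+beta) lambda-))`
#' where `lambda+` / `lambda-` are the matrix's largest positive and
#' smallest negative eigenvalues; a matrix lacking one sign contributes
#' only the other term.  The pooled alpha is the minimum over all
#' matrices, so a single constant is valid for the whole cohort.
#'
#' @param matrices list of `functional_connectome` objects (or matrices):
#'   all pre-stimulation matrices, patients and healthy pooled.
#' @param beta target spectral bound for the deconvolved networks, in
#'   (0, 1).  Default 0.5.
#' @return An object of class `scaling_params` with fields `alpha`,
#'   `beta`, `per_matrix_bounds`.
#' @export
compute_scaling_factor <- function(matrices, beta = 0.5) {
  if (inherits(matrices, c("functional_connectome", "direct_network"))) {
    matrices <- list(matrices)
  }
  if (!length(matrices)) stop("need at least one matrix", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0 || beta >= 1) {
    stop("beta must be a single number in (0, 1)", call. = FALSE)
  }
  bounds <- vapply(matrices, function(x) {
    m <- transform_input(x, "functional_connectome")$matrix
    ev <- sym_eigenvalues(m)
    lam_pos <- ev[ev > 0]
    lam_neg <- ev[ev < 0]
    b <- Inf
    if (length(lam_pos)) b <- min(b, beta / ((1 - beta) * max(lam_pos)))
    if (length(lam_neg)) b <- min(b, -beta / ((1 + beta) * min(lam_neg)))
    b
  }, numeric(1))
  alpha <- min(bounds)
  if (!is.finite(alpha)) {
    stop("all matrices have an all-zero spectrum; nothing to scale", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, per_matrix_bounds = bounds),
            class = "scaling_params")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat("<scaling_params> alpha = ", format(x$alpha, digits = 6),
      " (beta = ", format(x$beta), ", pooled over ",
      length(x$per_matrix_bounds), " matrices)\n", sep = "")
  invisible(x)
}

#' Apply the pooled scaling
#'
#' Multiplies every entry of a connectome by the pooled `alpha`.
#' Eigenvalues scale linearly, so after scaling the deconvolved network
#' is guaranteed a spectral radius of at most `beta`.
#'
#' @param f a `functional_connectome`.
#' @param params a `scaling_params` from [compute_scaling_factor()], or a
#'   single positive number.
#' @return The scaled `functional_connectome`.
#' @export
apply_scaling <- function(f, params) {
  alpha <- if (inherits(params, "scaling_params")) params$alpha else params
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0) {
    stop("alpha must be a single finite positive number", call. = FALSE)
  }
  stopifnot(inherits(f, "functional_connectome"))
  out <- f
  out$matrix <- f$matrix * alpha
  out
}
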
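#' Perturbation operator for focal stimulation
#'
#' Focal stimulation of one bilateral target is modelled as a
#' multiplicative operator P on the direct network: entries in the rows
#' and columns of the target regions equal the stimulation strength `s`
#' and all other entries equal 1, so `D' = D * P` (element-wise).  A
#' strength above 1 up-regulates the target's direct connections, below
#' 1 down-regulates them (0.7 is a 30% down-regulation).  The edge
#' between the two target regions, like every other entry, receives `s`
#' exactly once.
#'
#' @param parc a `parcellation`.
#' @param target a pair id or pair abbreviation (bilateral target), or an
#'   integer vector of region indices for a generalized target set.
#' @param strength positive stimulation strength `s`.
#' @return An object of class `perturbation_operator` with fields
#'   `matrix`, `target_regions`, `strength`.
#' @export
build_perturbation <- function(parc, target, strength) {
  stopifnot(inherits(parc, "parcellation"))
  if (!is.numeric(strength) || length(strength) != 1 || strength <= 0) {
    stop("strength must be a single positive number", call. = FALSE)
  }
  if (length(target) == 1 && (is.character(target) ||
      target %in% parc$pair_id)) {
    regions <- pair_indices(parc, if (is.character(target)) target else as.integer(target))
  } else {
    regions <- as.integer(target)
    if (!all(regions %in% parc$index)) stop("unknown target region index", call. = FALSE)
  }
  n <- nrow(parc)
  p <- matrix(1, n, n)
  p[regions, ] <- strength
  p[, regions] <- strength
  structure(list(matrix = p, target_regions = regions, strength = strength,
                 regions = parc$abbreviation),
            class = "perturbation_operator")
}

#' @export
print.perturbation_operator <- function(x, ...) {
  cat("<perturbation_operator> s = ", format(x$strength), " on region(s) ",
      paste(x$regions[x$target_regions], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Stimulation protocol
#'
#' The grid of strengths and the set of bilateral targets screened by
#' [stimulation_sweep()].  The default grid runs from 0.02 to 2.00 in
#' steps of 0.02 (98% down-regulation to 100% up-regulation at 2%
#' resolution); the identity strength 1.0 is always forced into the grid
#' so that "no stimulation" is a candidate and the best achievable
#' relative change is never negative.  The default target set is every
#' homologous pair of the parcellation (46 bilateral targets for the
#' shipped 92-region scheme).
#'
#' @param parc a `parcellation`.
#' @param strengths increasing vector of positive strengths, or `NULL`
#'   for the default grid.
#' @param targets vector of pair ids or pair abbreviations, or `"all"`.
#' @return An object of class `stimulation_protocol`.
#' @export
stimulation_protocol <- function(parc, strengths = NULL, targets = "all") {
  stopifnot(inherits(parc, "parcellation"))
  if (is.null(strengths)) strengths <- seq(0.02, 2.00, by = 0.02)
  strengths <- sort(unique(c(strengths, 1.0)))
  if (any(strengths <= 0)) stop("strengths must be strictly positive", call. = FALSE)
  pairs <- pair_table(parc)
  if (identical(targets, "all")) {
    target_ids <- pairs$pair_id
  } else if (is.character(targets)) {
    target_ids <- vapply(targets, function(t) {
      hit <- pairs$pair_id[pairs$pair_abbreviation == t]
      if (length(hit) != 1) stop("unknown target pair: ", t, call. = FALSE)
      hit
    }, integer(1))
  } else {
    target_ids <- as.integer(targets)
    if (!all(target_ids %in% pairs$pair_id)) stop("unknown target pair id", call. = FALSE)
  }
  structure(list(strengths = strengths, targets = unname(target_ids),
                 parcellation = parc),
            class = "stimulation_protocol")
}

#' Simulate one stimulation event
#'
#' Applies the full forward model for a single (target, strength)
#' choice: deconvolve the (already alpha-scaled) connectome to its
#' direct network, impose the perturbation element-wise, and re-convolve
#' by transitive closure.  If the perturbed direct network has an
#' eigenvalue at or above 1 the closure diverges and the stimulation is
#' infeasible; this is returned as an `stim_infeasible` marker rather
#' than an error so that strength sweeps can simply skip the point.
#'
#' @param f a `functional_connectome`, already scaled by the pooled alpha.
#' @param p a `perturbation_operator`.
#' @param d optional pre-computed `direct_network` of `f` (the
#'   deconvolution is strength-independent, so sweeps cache it).
#' @param tol divergence guard tolerance.
#' @return The post-stimulation `functional_connectome`, or an object of
#'   class `stim_infeasible`.
#' @export
apply_stimulation <- function(f, p, d = NULL, tol = 1e-9) {
  stopifnot(inherits(p, "perturbation_operator"))
  if (is.null(d)) d <- network_deconvolution(f, tol = tol)
  if (nrow(d$matrix) != nrow(p$matrix)) {
    stop("connectome and perturbation dimensions disagree", call. = FALSE)
  }
  dp <- d$matrix * p$matrix
  tryCatch(
    transitive_closure(direct_network(dp, d$regions), tol = tol),
    connstim_divergence = function(cond) {
      structure(list(eta_max = cond$eta_max, strength = p$strength,
                     target_regions = p$target_regions),
                class = "stim_infeasible")
    }
  )
}

#' Is a stimulation result feasible?
#'
#' @param x result of [apply_stimulation()].
#' @return `FALSE` for the divergence marker, `TRUE` otherwise.
#' @export
is_feasible <- function(x) !inherits(x, "stim_infeasible")

#' Sweep all targets and strengths for one connectome
#'
#' Evaluates the whole protocol grid for a single (subject or
#' group-averaged) patient connectome: for every bilateral target and
#' every strength, the post-stimulation connectome is computed and its
#' similarity to the healthy reference recorded, together with the
#' relative change of that similarity over the pre-stimulation value.
#' Infeasible combinations (diverging closure) are flagged and excluded
#' from later optimization.
#'
#' The deconvolution of `f` is computed once and cached across the whole
#' grid.  In the inner loop the closure `(I - D')^-1 - I` is evaluated
#' through a Cholesky factorization of `I - D'`, whose failure is exactly
#' the divergence condition; this is algebraically identical to the
#' eigendecomposition form used by [transitive_closure()] and several
#' times faster.
#'
#' @param f the patient `functional_connectome` (alpha-scaled).
#' @param protocol a `stimulation_protocol`.
#' @param healthy_ref the healthy reference `functional_connectome`
#'   (alpha-scaled, same region order).
#' @param subject_id id string recorded in the output.
#' @param tol divergence tolerance passed to the deconvolution guard.
#' @return A data.frame of class `stim_sweep` with one row per
#'   (target, strength): columns `subject_id`, `target_pair`,
#'   `target_abbrev`, `strength`, `cc_pre`, `cc_post`,
#'   `relative_change`, `feasible`.
#' @export
stimulation_sweep <- function(f, protocol, healthy_ref, subject_id = "subject",
                              tol = 1e-9) {
  stopifnot(inherits(protocol, "stimulation_protocol"))
  parc <- protocol$parcellation
  if (!identical(f$regions, healthy_ref$regions)) {
    stop("patient and reference connectomes must share region order", call. = FALSE)
  }
  if (length(f$regions) != nrow(parc)) {
    stop("connectome does not match the protocol's parcellation", call. = FALSE)
  }
  n <- nrow(parc)
  d <- network_deconvolution(f, tol = tol)$matrix
  ident <- diag(n)
  ut_idx <- which(upper.tri(ident))
  # both vectors share one edge ordering, so the correlation equals the
  # row-major definition used by connectomic_similarity()
  ref_ut <- healthy_ref$matrix[ut_idx]
  cc_pre <- stats::cor(f$matrix[ut_idx], ref_ut)
  strengths <- protocol$strengths
  targets <- protocol$targets

  n_rows <- length(targets) * length(strengths)
  out_strength <- rep(strengths, times = length(targets))
  out_target <- rep(targets, each = length(strengths))
  cc_post <- rep(NA_real_, n_rows)
  feasible <- rep(FALSE, n_rows)

  row <- 0L
  for (t_id in targets) {
    idx <- pair_indices(parc, t_id)
    mask <- matrix(0, n, n)
    mask[idx, ] <- 1
    mask[, idx] <- 1
    dm <- d * mask
    for (s in strengths) {
      row <- row + 1L
      dp <- d + (s - 1) * dm
      a <- ident - dp
      ch <- tryCatch(chol(a), error = function(e) NULL)
      if (is.null(ch)) next  # I - D' not positive definite: closure diverges
      fp <- chol2inv(ch)     # (I - D')^-1 = TC(D') + I; identity diag drops out
      cc_post[row] <- stats::cor(fp[ut_idx], ref_ut)
      feasible[row] <- TRUE
    }
  }
  abbrev <- pair_table(parc)
  res <- data.frame(
    subject_id = subject_id,
    target_pair = out_target,
    target_abbrev = abbrev$pair_abbreviation[match(out_target, abbrev$pair_id)],
    strength = out_strength,
    cc_pre = cc_pre,
    cc_post = cc_post,
    relative_change = (cc_post - cc_pre) / cc_pre * 100,
    feasible = feasible,
    stringsAsFactors = FALSE
  )
  class(res) <- c("stim_sweep", "data.frame")
  res
}

#' Write sweep results to TSV
#'
#' @param sweep a `stim_sweep` data frame.
#' @param path output file.
#' @export
write_sweep <- function(sweep, path) {
  out <- data.frame(subject_id = sweep$subject_id,
                    target_abbrev = sweep$target_abbrev,
                    strength = sweep$strength,
                    similarity_pre = sweep$cc_pre,
                    similarity_post = sweep$cc_post,
                    relative_change_pct = sweep$relative_change,
                    feasible = sweep$feasible)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
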
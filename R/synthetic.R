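# Synthetic cohort generator.
#
# Every stage of the pipeline is testable without any imaging data: a
# healthy cohort is generated from a shared prototype direct network plus
# subject-level noise, and patients are generated by implanting a known
# multiplicative lesion into the direct network before transitive
# closure.  The generative direction mirrors the model's own assumption
# (the measured connectome is the closure of a direct network), so the
# implanted ground truth exactly predicts what the recovery pipeline
# should return on noiseless data.

#' Specification of a synthetic cohort
#'
#' @param n_regions even region count (default 92, the shipped atlas).
#' @param n_healthy,n_patients group sizes.
#' @param prototype_density edge density of the prototype direct
#'   network's support (Erdos-Renyi on the upper triangle).
#' @param prototype_radius spectral radius the prototype is rescaled to.
#' @param subject_noise_sd SD of the Gaussian edge noise (z units) added
#'   to the prototype's support edges for each subject.
#' @param lesion data.frame with columns `pair_id`, `strength`,
#'   `fraction`: each row implants a multiplicative lesion of the given
#'   strength at the given homologous pair into that fraction of
#'   patients.  `NULL` for no lesion.
#' @param planted_edge_shift optional list `list(edges = 2-column matrix
#'   of region indices, shift = z units)` added to patient connectomes
#'   after closure, for edge-wise statistics tests.
#' @param severity_model optional list `list(base, slope, noise_sd)`
#'   mapping lesion depth `|log(s0)|` to a synthetic UPDRS-like score.
#' @param seed RNG seed; all generators are pure functions of
#'   `(spec, seed)`.
#' @return A list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_regions = 92L, n_healthy = 20L,
                                  n_patients = 20L, prototype_density = 0.1,
                                  prototype_radius = 0.4,
                                  subject_noise_sd = 0.05,
                                  lesion = NULL, planted_edge_shift = NULL,
                                  severity_model = NULL, seed = 1L) {
  if (n_regions %% 2L != 0L || n_regions < 4L) {
    stop("n_regions must be an even number >= 4", call. = FALSE)
  }
  if (prototype_density <= 0 || prototype_density > 1) {
    stop("prototype_density must be in (0, 1]", call. = FALSE)
  }
  if (prototype_radius <= 0 || prototype_radius >= 1) {
    stop("prototype_radius must be in (0, 1)", call. = FALSE)
  }
  if (subject_noise_sd < 0) stop("subject_noise_sd must be >= 0", call. = FALSE)
  if (!is.null(lesion)) {
    stopifnot(all(c("pair_id", "strength", "fraction") %in% names(lesion)))
    if (any(lesion$strength <= 0)) stop("lesion strength must be > 0", call. = FALSE)
    if (any(lesion$fraction < 0 | lesion$fraction > 1)) {
      stop("lesion fraction must be in [0, 1]", call. = FALSE)
    }
    if (any(lesion$pair_id > n_regions / 2L)) {
      stop("lesion pair_id outside the parcellation", call. = FALSE)
    }
  }
  structure(list(n_regions = as.integer(n_regions),
                 n_healthy = as.integer(n_healthy),
                 n_patients = as.integer(n_patients),
                 prototype_density = prototype_density,
                 prototype_radius = prototype_radius,
                 subject_noise_sd = subject_noise_sd,
                 lesion = lesion, planted_edge_shift = planted_edge_shift,
                 severity_model = severity_model, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

spec_parcellation <- function(spec) {
  if (spec$n_regions == 92L) default_parcellation() else
    synthetic_parcellation(spec$n_regions)
}

# Prototype direct network: Erdos-Renyi support with half-normal weights,
# rescaled to the requested spectral radius.
draw_prototype <- function(spec) {
  n <- spec$n_regions
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  support <- stats::runif(sum(ut)) < spec$prototype_density
  w <- abs(stats::rnorm(sum(ut))) * support
  m[ut] <- w
  m <- m + t(m)
  r <- spectral_radius(m)
  if (r == 0) stop("prototype direct network is all-zero; increase density",
                   call. = FALSE)
  m * (spec$prototype_radius / r)
}

# Subject-level direct network: prototype plus symmetric Gaussian noise
# on the support edges, capped at a safe spectral radius so the closure
# always converges (also after a lesion of strength up to 2).
draw_subject_direct <- function(proto, spec, cap = 0.6) {
  n <- nrow(proto)
  m <- proto
  if (spec$subject_noise_sd > 0) {
    ut <- upper.tri(m)
    noise <- stats::rnorm(sum(ut), sd = spec$subject_noise_sd) * (m[ut] != 0)
    e <- matrix(0, n, n)
    e[ut] <- noise
    m <- m + e + t(e)
  }
  r <- spectral_radius(m)
  if (r > cap) m <- m * (cap / r)
  m
}

#' Generate a synthetic healthy cohort
#'
#' Draws one prototype direct network (shared connectome backbone) and,
#' per subject, adds independent edge noise and convolves by transitive
#' closure.  The prototype is attached as attribute `"prototype"` (a
#' `direct_network`), so a patient cohort can be generated from the same
#' backbone.
#'
#' @param spec a `synthetic_cohort_spec`.
#' @return A `cohort_data` of healthy subjects (`HC01`, `HC02`, ...).
#' @export
generate_healthy_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  parc <- spec_parcellation(spec)
  set.seed(spec$seed)
  proto <- draw_prototype(spec)
  subjects <- list()
  for (i in seq_len(spec$n_healthy)) {
    d <- draw_subject_direct(proto, spec)
    f <- transitive_closure(direct_network(d, parc$abbreviation))
    f <- as_measured(f)
    subjects[[sprintf("HC%02d", i)]] <- f
  }
  cohort <- cohort_data(subjects, rep("healthy", length(subjects)))
  attr(cohort, "prototype") <- direct_network(proto, parc$abbreviation)
  cohort
}

# The closure has a small nonzero diagonal; measured connectomes carry a
# zero diagonal by policy.  The diagonal never enters any statistic, so
# dropping it does not perturb the ground truth used by the tests.
as_measured <- function(f) {
  m <- f$matrix
  diag(m) <- 0
  functional_connectome(m, f$regions, diag_zero = TRUE)
}

#' Generate a synthetic patient cohort with known lesions
#'
#' Each patient's direct network is the healthy prototype plus subject
#' noise; lesion carriers additionally have their direct network
#' multiplied element-wise by the lesion's perturbation operator before
#' transitive closure.  The returned cohort carries a `"ground_truth"`
#' attribute recording, per subject, the implanted pair, its strength
#' `s0`, and the implied optimal corrective strength `1/s0`.  When the
#' spec has a `severity_model`, synthetic clinical scores increasing
#' monotonically with lesion depth `|log(s0)|` are attached.
#'
#' @param spec a `synthetic_cohort_spec`.
#' @param healthy a cohort from [generate_healthy_cohort()] (its
#'   prototype is reused), or a `direct_network` prototype.
#' @return A `cohort_data` of patients (`PD01`, ...), with attribute
#'   `"ground_truth"` (data.frame).
#' @export
generate_patient_cohort <- function(spec, healthy) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  proto <- if (inherits(healthy, "direct_network")) healthy else
    attr(healthy, "prototype")
  if (is.null(proto)) stop("healthy cohort carries no prototype", call. = FALSE)
  parc <- spec_parcellation(spec)
  set.seed(spec$seed + 1L)
  n_pat <- spec$n_patients
  ids <- sprintf("PD%02d", seq_len(n_pat))

  # carrier assignment per lesion row, drawn without overlap so that the
  # ground-truth ledger stays one lesion per subject
  carriers <- list()
  if (!is.null(spec$lesion)) {
    pool <- ids
    for (k in seq_len(nrow(spec$lesion))) {
      n_carry <- round(spec$lesion$fraction[k] * n_pat)
      if (n_carry > length(pool)) {
        stop("lesion fractions sum past 1: not enough lesion-free patients",
             call. = FALSE)
      }
      carriers[[k]] <- if (n_carry > 0) sample(pool, n_carry) else character(0)
      pool <- setdiff(pool, carriers[[k]])
    }
  }

  subjects <- list()
  gt <- data.frame(subject_id = ids, pair_id = NA_integer_,
                   strength = NA_real_, corrective_strength = NA_real_,
                   lesion_depth = 0, stringsAsFactors = FALSE)
  for (i in seq_len(n_pat)) {
    d <- draw_subject_direct(proto$matrix, spec)
    if (!is.null(spec$lesion)) {
      for (k in seq_len(nrow(spec$lesion))) {
        if (ids[i] %in% carriers[[k]]) {
          p <- build_perturbation(parc, spec$lesion$pair_id[k],
                                  spec$lesion$strength[k])
          d <- d * p$matrix
          gt$pair_id[i] <- spec$lesion$pair_id[k]
          gt$strength[i] <- spec$lesion$strength[k]
          gt$corrective_strength[i] <- 1 / spec$lesion$strength[k]
          gt$lesion_depth[i] <- gt$lesion_depth[i] +
            abs(log(spec$lesion$strength[k]))
        }
      }
    }
    if (spectral_radius(d) >= 1 - 1e-9) {
      stop("lesion strength makes the transitive closure diverge at generation",
           call. = FALSE)
    }
    f <- transitive_closure(direct_network(d, parc$abbreviation))
    subjects[[ids[i]]] <- as_measured(f)
  }
  if (!is.null(spec$planted_edge_shift)) {
    ed <- spec$planted_edge_shift$edges
    shift <- spec$planted_edge_shift$shift
    for (id in ids) {
      m <- subjects[[id]]$matrix
      m[ed] <- m[ed] + shift
      m[ed[, c(2, 1), drop = FALSE]] <- m[ed[, c(2, 1), drop = FALSE]] + shift
      subjects[[id]] <- functional_connectome(m, parc$abbreviation)
    }
  }
  clinical <- NULL
  if (!is.null(spec$severity_model)) {
    sm <- spec$severity_model
    clinical <- stats::setNames(
      sm$base + sm$slope * gt$lesion_depth +
        stats::rnorm(n_pat, sd = sm$noise_sd %||% 0),
      ids)
  }
  cohort <- cohort_data(subjects, rep("patient", n_pat), clinical = clinical)
  attr(cohort, "ground_truth") <- gt
  attr(cohort, "prototype") <- proto
  cohort
}

#' Merge two cohorts
#'
#' @param ... `cohort_data` objects with disjoint subject ids and one
#'   shared region order.
#' @return A single `cohort_data`.
#' @export
combine_cohorts <- function(...) {
  parts <- list(...)
  subjects <- do.call(c, lapply(parts, function(p) p$subjects))
  groups <- do.call(c, lapply(parts, function(p) unname(p$groups)))
  clin <- do.call(c, lapply(parts, function(p) p$clinical))
  cohort_data(subjects, groups, clinical = if (length(clin)) clin else NULL)
}

#' Generate time series realizing a target connectome
#'
#' Samples a zero-mean multivariate normal whose correlation matrix is
#' `tanh` of the target Fisher-z connectome (diagonal 1).  If that matrix
#' is not positive semi-definite it is repaired to the nearest
#' correlation matrix ([Matrix::nearPD()]); the repair distance (max
#' absolute entry change) is reported as attribute `"repair"` and must
#' stay below `repair_threshold`.  As the number of time points grows,
#' [build_connectome()] applied to the output converges to the target.
#'
#' @param f_target a `functional_connectome` (Fisher-z units).
#' @param n_timepoints number of samples (rows).
#' @param seed RNG seed.
#' @param repair_threshold maximum tolerated repair distance.
#' @param tr_seconds repetition-time metadata for the output.
#' @return A `region_timeseries`.
#' @export
generate_timeseries <- function(f_target, n_timepoints = 500, seed = 1L,
                                repair_threshold = 0.1, tr_seconds = 2) {
  stopifnot(inherits(f_target, "functional_connectome"))
  cmat <- tanh(f_target$matrix)
  diag(cmat) <- 1
  ev_min <- min(sym_eigenvalues(cmat))
  repair <- 0
  if (ev_min < 1e-8) {
    fixed <- as.matrix(Matrix::nearPD(cmat, corr = TRUE)$mat)
    repair <- max(abs(fixed - cmat))
    if (repair > repair_threshold) {
      stop("target connectome is too far from a valid correlation matrix ",
           "(repair distance ", format(repair, digits = 4), ")", call. = FALSE)
    }
    cmat <- fixed
  }
  set.seed(seed)
  n <- nrow(cmat)
  z <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n)
  # chol of a PSD-repaired matrix can still hit zero pivots; ridge the
  # last 1e-10 for factorization only
  ch <- chol(cmat + diag(1e-10, n))
  x <- z %*% ch
  out <- region_timeseries(x, f_target$regions, tr_seconds = tr_seconds)
  attr(out, "repair") <- repair
  out
}

#' Generate a synthetic labeled atlas volume
#'
#' Builds a small mirror-symmetric 3-D atlas for exercising the
#' parcellation subdivision: `n_regions/2` seed voxels are placed
#' uniformly in the left half of the grid, mirrored across the midline,
#' and every voxel is labeled by its nearest same-hemisphere seed
#' (Voronoi regions).  Left regions take odd labels, their mirrored
#' right partners the next even label, matching the parcellation's
#' pairing convention.  Hemisphere region volumes are exactly mirrored.
#'
#' @param n_regions even region count.
#' @param volume_shape 3-vector of grid dimensions; the first (x) must be
#'   even, since the midline splits hemispheres.
#' @param seed RNG seed.
#' @return A list with `volume` (3-D integer array) and `parcellation`.
#' @export
generate_synthetic_atlas <- function(n_regions = 12L,
                                     volume_shape = c(16L, 12L, 12L),
                                     seed = 1L) {
  if (n_regions %% 2L != 0L) stop("n_regions must be even", call. = FALSE)
  if (volume_shape[1] %% 2L != 0L) {
    stop("x dimension must be even (midline hemisphere split)", call. = FALSE)
  }
  k <- n_regions %/% 2L
  nx <- volume_shape[1]; ny <- volume_shape[2]; nz <- volume_shape[3]
  n_left <- (nx %/% 2L) * ny * nz
  if (n_left < k) stop("grid too small for the requested region count", call. = FALSE)
  set.seed(seed)
  left_vox <- as.matrix(expand.grid(x = seq_len(nx %/% 2L), y = seq_len(ny),
                                    z = seq_len(nz)))
  seeds <- left_vox[sample.int(nrow(left_vox), k), , drop = FALSE]
  vol <- array(0L, dim = c(nx, ny, nz))
  all_vox <- as.matrix(expand.grid(x = seq_len(nx), y = seq_len(ny),
                                   z = seq_len(nz)))
  left_half <- all_vox[, 1] <= nx %/% 2L
  # mirror right-hemisphere voxels onto left coordinates, then nearest seed
  mx <- ifelse(left_half, all_vox[, 1], nx + 1L - all_vox[, 1])
  d2 <- outer(mx, seeds[, 1], `-`)^2 +
    outer(all_vox[, 2], seeds[, 2], `-`)^2 +
    outer(all_vox[, 3], seeds[, 3], `-`)^2
  nearest <- max.col(-d2, ties.method = "first")
  lab <- 2L * nearest - 1L + !left_half
  vol[all_vox] <- as.integer(lab)
  list(volume = vol, parcellation = synthetic_parcellation(n_regions))
}

#' Write a synthetic cohort to disk
#'
#' Writes the standard interchange files for a generated cohort: one
#' connectome TSV per subject, the parcellation TSV, and a
#' `ground_truth.json` ledger with the implanted lesions and clinical
#' scores (when present).
#'
#' @param cohort a `cohort_data` (typically healthy + patients combined).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(cohort$regions)
  parc <- tryCatch(cohort_parcellation(cohort), error = function(e) NULL)
  if (!is.null(parc)) write_parcellation(parc, file.path(dir, "parcellation.tsv"))
  for (id in names(cohort$subjects)) {
    write_connectome(cohort$subjects[[id]],
                     file.path(dir, paste0(id, "_connectome.tsv")))
  }
  ledger <- list(groups = as.list(cohort$groups))
  gt <- attr(cohort, "ground_truth")
  if (!is.null(gt)) ledger$ground_truth <- gt
  if (!is.null(cohort$clinical)) ledger$clinical = as.list(cohort$clinical)
  jsonlite::write_json(ledger, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
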
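#' Connectomic similarity
#'
#' Pearson correlation between the vectorized strictly-upper triangles
#' (diagonal excluded) of two connectomes sharing one region order.  This
#' is the objective the stimulation model maximizes: how closely a
#' (post-stimulation) patient connectome resembles the group-averaged
#' healthy connectome.
#'
#' @param a,b `functional_connectome` objects with identical region order.
#' @return Pearson r.
#' @export
connectomic_similarity <- function(a, b) {
  stopifnot(inherits(a, "functional_connectome"),
            inherits(b, "functional_connectome"))
  if (!identical(a$regions, b$regions)) {
    stop("connectomes must share one region order", call. = FALSE)
  }
  if (length(a$regions) < 3) stop("need at least 3 regions", call. = FALSE)
  x <- upper_tri_vector(a$matrix)
  y <- upper_tri_vector(b$matrix)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance upper triangle; similarity undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Relative change of similarity
#'
#' The standardized outcome measure:
#' `(cc_post - cc_pre) / cc_pre * 100`, the percentage improvement of
#' connectomic similarity to the healthy reference achieved by a
#' stimulation.  Undefined for `cc_pre = 0`; a negative `cc_pre` inverts
#' the sign of "improvement" and triggers a warning.
#'
#' @param cc_pre,cc_post pre- and post-stimulation similarities.
#' @return Percent change.
#' @export
relative_change <- function(cc_pre, cc_post) {
  if (any(cc_pre == 0)) stop("relative change undefined for cc_pre = 0", call. = FALSE)
  if (any(cc_pre < 0)) {
    warning("cc_pre < 0: the sign of the relative change no longer tracks improvement")
  }
  (cc_post - cc_pre) / cc_pre * 100
}

#' Optimal strength for one target
#'
#' Selects, among the feasible grid points of one target, the strength
#' with the highest relative change.  Exact ties are broken toward the
#' strength closest to 1 (prefer the mildest intervention), then toward
#' the smaller strength; both rules are deterministic so rankings are
#' reproducible.
#'
#' @param records rows of a [stimulation_sweep()] result for one target.
#' @return A one-row data.frame with `target_pair`, `target_abbrev`,
#'   `best_strength`, `best_relative_change`, `cc_pre`, `cc_post`,
#'   `feasible` (FALSE when no grid point was feasible).
#' @export
optimize_strength <- function(records) {
  tgt <- unique(records$target_pair)
  if (length(tgt) != 1) stop("records must belong to a single target", call. = FALSE)
  feas <- records[records$feasible, , drop = FALSE]
  if (!nrow(feas)) {
    return(data.frame(target_pair = tgt,
                      target_abbrev = records$target_abbrev[1],
                      best_strength = NA_real_, best_relative_change = NA_real_,
                      cc_pre = records$cc_pre[1], cc_post = NA_real_,
                      feasible = FALSE, stringsAsFactors = FALSE))
  }
  ord <- order(-feas$relative_change, abs(feas$strength - 1), feas$strength)
  best <- feas[ord[1], ]
  data.frame(target_pair = tgt, target_abbrev = best$target_abbrev,
             best_strength = best$strength,
             best_relative_change = best$relative_change,
             cc_pre = best$cc_pre, cc_post = best$cc_post,
             feasible = TRUE, stringsAsFactors = FALSE)
}

#' Per-target optima of a sweep
#'
#' @param sweep a `stim_sweep` data frame.
#' @return One row per target, as in [optimize_strength()].
#' @export
sweep_optima <- function(sweep) {
  parts <- split(sweep, sweep$target_pair)
  out <- do.call(rbind, lapply(parts, optimize_strength))
  rownames(out) <- NULL
  out[order(out$target_pair), ]
}

#' Rank targets by their optimal relative change
#'
#' Descending sort by best relative change; ties are broken by
#' parcellation pair id, and targets with no feasible strength are placed
#' last (still receiving a rank so ranks remain a permutation).
#'
#' @param optima per-target optima from [sweep_optima()].
#' @return The optima with a `rank` column (1 = best), sorted by rank,
#'   class `target_ranking`.
#' @export
rank_targets <- function(optima) {
  if (!nrow(optima)) stop("need at least one target", call. = FALSE)
  key <- optima$best_relative_change
  key[!optima$feasible] <- -Inf
  ord <- order(-key, optima$target_pair)
  out <- optima[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("target_ranking", "data.frame")
  out
}

#' Full ranking pipeline for one connectome
#'
#' Convenience wrapper: sweep, per-target optimization, ranking.
#'
#' @inheritParams stimulation_sweep
#' @return A `target_ranking`.
#' @export
rank_connectome <- function(f, protocol, healthy_ref, subject_id = "subject",
                            tol = 1e-9) {
  rank_targets(sweep_optima(
    stimulation_sweep(f, protocol, healthy_ref, subject_id = subject_id,
                      tol = tol)))
}

#' Occurrence summary across rankings
#'
#' Counts, per target, how often it is the best (rank 1) or a top-five
#' (rank <= 5) choice across a collection of per-subject or per-iteration
#' rankings.
#'
#' @param rankings list of `target_ranking` objects sharing a target set.
#' @param top integer; the "top-k" threshold (default 5).
#' @return A data.frame with `target_pair`, `target_abbrev`, `n_best`,
#'   `n_top`.
#' @export
occurrence_summary <- function(rankings, top = 5L) {
  stopifnot(length(rankings) >= 1)
  ref <- sort(rankings[[1]]$target_pair)
  for (r in rankings) {
    if (!identical(sort(r$target_pair), ref)) {
      stop("rankings do not share one target set", call. = FALSE)
    }
  }
  abbrev <- rankings[[1]]$target_abbrev[match(ref, rankings[[1]]$target_pair)]
  n_best <- n_top <- stats::setNames(integer(length(ref)), ref)
  for (r in rankings) {
    best <- as.character(r$target_pair[r$rank == 1])
    topk <- as.character(r$target_pair[r$rank <= top])
    n_best[best] <- n_best[best] + 1L
    n_top[topk] <- n_top[topk] + 1L
  }
  data.frame(target_pair = ref, target_abbrev = abbrev,
             n_best = unname(n_best), n_top = unname(n_top),
             stringsAsFactors = FALSE)
}

#' Rank every patient in a cohort
#'
#' The individual-level pipeline: the healthy reference is the
#' group-averaged healthy connectome, one pooled alpha (at `beta`) is
#' computed over every subject connectome in the cohort, all matrices
#' are scaled by it, and each patient's scaled connectome is swept over
#' the whole protocol grid and ranked.
#'
#' @param cohort a `cohort_data` with both groups present.
#' @param protocol a `stimulation_protocol` (default: full default grid).
#' @param beta spectral bound for the pooled scaling (default 0.5).
#' @return A list with `rankings` (named list of `target_ranking`, one
#'   per patient), `scaling` (the `scaling_params`), and `healthy_ref`
#'   (scaled reference connectome).
#' @export
rank_cohort_patients <- function(cohort, protocol = NULL, beta = 0.5) {
  stopifnot(inherits(cohort, "cohort_data"))
  parc <- cohort_parcellation(cohort)
  if (is.null(protocol)) protocol <- stimulation_protocol(parc)
  scaling <- compute_scaling_factor(lapply(cohort$subjects, identity), beta = beta)
  healthy_ref <- apply_scaling(group_average(cohort, "healthy"), scaling)
  pat_ids <- names(cohort$subjects)[cohort$groups == "patient"]
  rankings <- lapply(pat_ids, function(id) {
    f <- apply_scaling(cohort$subjects[[id]], scaling)
    rank_connectome(f, protocol, healthy_ref, subject_id = id)
  })
  names(rankings) <- pat_ids
  list(rankings = rankings, scaling = scaling, healthy_ref = healthy_ref)
}

# A cohort stores only region ids; recover a parcellation for protocol
# construction (default atlas when the ids match it, otherwise the
# generic synthetic scheme).
cohort_parcellation <- function(cohort) {
  n <- length(cohort$regions)
  parc <- tryCatch(default_parcellation(), error = function(e) NULL)
  if (!is.null(parc) && identical(cohort$regions, parc$abbreviation)) return(parc)
  parc <- synthetic_parcellation(n)
  if (identical(cohort$regions, parc$abbreviation)) return(parc)
  stop("cannot infer a parcellation from the cohort's region ids; ",
       "build the protocol explicitly", call. = FALSE)
}

#' Group-level target identification
#'
#' The population-level pipeline: group-averaged patient and healthy
#' connectomes, one pooled alpha over all subject matrices, then a sweep
#' of the averaged patient connectome against the averaged healthy one.
#'
#' @inheritParams rank_cohort_patients
#' @return A list with `ranking` (a `target_ranking`), `sweep` (the full
#'   `stim_sweep`), and `scaling`.
#' @export
rank_cohort_group <- function(cohort, protocol = NULL, beta = 0.5) {
  stopifnot(inherits(cohort, "cohort_data"))
  parc <- cohort_parcellation(cohort)
  if (is.null(protocol)) protocol <- stimulation_protocol(parc)
  scaling <- compute_scaling_factor(lapply(cohort$subjects, identity), beta = beta)
  healthy_ref <- apply_scaling(group_average(cohort, "healthy"), scaling)
  pat_avg <- apply_scaling(group_average(cohort, "patient"), scaling)
  sw <- stimulation_sweep(pat_avg, protocol, healthy_ref, subject_id = "group")
  list(ranking = rank_targets(sweep_optima(sw)), sweep = sw, scaling = scaling)
}

#' Subsample cross-validation of the group ranking
#'
#' Robustness check of the group-level target identification: in each
#' iteration a fraction of the patients and of the healthy subjects is
#' sampled without replacement, the group averages, pooled alpha, and
#' group ranking are recomputed from scratch, and the per-target optimal
#' relative change and the winning target are recorded.
#'
#' @param cohort a `cohort_data` with at least two subjects per group.
#' @param n_iter number of subsampling iterations.
#' @param fraction fraction of each group sampled, in (0, 1].
#' @param seed RNG seed (the procedure is a pure function of its inputs).
#' @param protocol a `stimulation_protocol`, default grid if `NULL`.
#' @param beta spectral bound for the per-iteration pooled scaling.
#' @return A list with `per_target` (data.frame: `target_pair`,
#'   `target_abbrev`, `mean_relative_change`, `sd_relative_change`,
#'   `n_best`, `n_top`), `best_by_iteration` (character vector of winning
#'   pair abbreviations), `n_iter`.
#' @export
subsample_cross_validation <- function(cohort, n_iter = 100, fraction = 0.5,
                                       seed = 1L, protocol = NULL, beta = 0.5) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]", call. = FALSE)
  pat <- names(cohort$subjects)[cohort$groups == "patient"]
  hc <- names(cohort$subjects)[cohort$groups == "healthy"]
  if (length(pat) < 2 || length(hc) < 2) {
    stop("need at least two subjects per group", call. = FALSE)
  }
  parc <- cohort_parcellation(cohort)
  if (is.null(protocol)) protocol <- stimulation_protocol(parc)
  set.seed(seed)
  run_iteration <- function() {
    ids <- c(sample(pat, max(1L, floor(fraction * length(pat)))),
             sample(hc, max(1L, floor(fraction * length(hc)))))
    sub <- cohort_subset(cohort, ids)
    rank_cohort_group(sub, protocol = protocol, beta = beta)$ranking
  }
  rankings <- lapply(seq_len(n_iter), function(i) run_iteration())
  summarize_validation(rankings, n_iter)
}

#' Null validation with relabelled healthy subjects
#'
#' Bias check of the whole strategy: a fraction of the healthy group is
#' relabelled as the "patient group" and compared against the remaining
#' healthy subjects.  With no true group difference, per-target mean
#' relative changes should be near zero and the winning target close to
#' uniformly distributed.
#'
#' @inheritParams subsample_cross_validation
#' @param fraction fraction of healthy subjects used as pseudo-patients,
#'   in (0, 1): the complement serves as the reference group, so 1 is a
#'   degenerate split and an error.
#' @return As [subsample_cross_validation()].
#' @export
null_target_validation <- function(cohort, n_iter = 100, fraction = 0.5,
                                   seed = 1L, protocol = NULL, beta = 0.5) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1): pseudo-patients and reference must not coincide",
         call. = FALSE)
  }
  hc <- names(cohort$subjects)[cohort$groups == "healthy"]
  if (length(hc) < 4) stop("need at least 4 healthy subjects", call. = FALSE)
  parc <- cohort_parcellation(cohort)
  if (is.null(protocol)) protocol <- stimulation_protocol(parc)
  set.seed(seed)
  run_iteration <- function() {
    pseudo <- sample(hc, max(1L, floor(fraction * length(hc))))
    rest <- setdiff(hc, pseudo)
    sub <- cohort_data(cohort$subjects[c(pseudo, rest)],
                       c(rep("patient", length(pseudo)),
                         rep("healthy", length(rest))))
    rank_cohort_group(sub, protocol = protocol, beta = beta)$ranking
  }
  rankings <- lapply(seq_len(n_iter), function(i) run_iteration())
  summarize_validation(rankings, n_iter)
}

summarize_validation <- function(rankings, n_iter) {
  occ <- occurrence_summary(rankings)
  rel <- vapply(rankings, function(r) {
    r$best_relative_change[match(occ$target_pair, r$target_pair)]
  }, numeric(nrow(occ)))
  rel <- matrix(rel, nrow = nrow(occ))
  best <- vapply(rankings, function(r) r$target_abbrev[r$rank == 1], character(1))
  per_target <- data.frame(
    target_pair = occ$target_pair, target_abbrev = occ$target_abbrev,
    mean_relative_change = rowMeans(rel, na.rm = TRUE),
    sd_relative_change = apply(rel, 1, stats::sd, na.rm = TRUE),
    n_best = occ$n_best, n_top = occ$n_top, stringsAsFactors = FALSE)
  list(per_target = per_target, best_by_iteration = best, n_iter = n_iter)
}

#' Kendall correlation between target rank and clinical severity
#'
#' For one chosen target, correlates its per-subject priority rank with a
#' clinical severity score (e.g. UPDRS-III) using Kendall's tau-b
#' (tie-corrected; exact two-sided p for small untied samples, normal
#' approximation otherwise, as provided by [stats::cor.test()]).
#'
#' @param rankings named list of per-subject `target_ranking` objects.
#' @param clinical named numeric vector of severity scores.
#' @param target pair id or pair abbreviation of the target of interest.
#' @return A list with `tau`, `p_value`, `n`.
#' @export
rank_severity_correlation <- function(rankings, clinical, target) {
  ids <- intersect(names(rankings), names(clinical))
  if (length(ids) < 3) stop("need at least 3 subjects with both rank and score",
                            call. = FALSE)
  ranks <- vapply(rankings[ids], function(r) {
    hit <- if (is.character(target)) r$target_abbrev == target else r$target_pair == target
    if (!any(hit)) stop("target not present in a ranking", call. = FALSE)
    as.numeric(r$rank[hit])
  }, numeric(1))
  scores <- as.numeric(clinical[ids])
  if (length(unique(ranks)) == 1 || length(unique(scores)) == 1) {
    stop("all-tied ranks or scores: tau undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(ranks, scores, method = "kendall"))
  list(tau = unname(ct$estimate), p_value = ct$p.value, n = length(ids))
}

#' Connectome similarity as a discriminative index
#'
#' Computes each subject's connectomic similarity to the group-averaged
#' healthy connectome and the area under the ROC curve for
#' discriminating patients from healthy subjects by thresholding that
#' similarity (Mann-Whitney formulation: the probability that a random
#' healthy subject is more similar to the healthy average than a random
#' patient, ties counting one half).  Healthy subjects are compared to a
#' leave-one-out average so that self-inclusion does not inflate their
#' similarity.
#'
#' @param cohort a `cohort_data` with both groups non-empty.
#' @return A list with `similarity` (data.frame: `subject_id`, `group`,
#'   `similarity`) and `auc`.
#' @export
compute_discrimination_auc <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_data"))
  groups <- cohort$groups
  if (!any(groups == "patient") || !any(groups == "healthy")) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (sum(groups == "healthy") < 2) {
    stop("need at least 2 healthy subjects for a leave-one-out reference",
         call. = FALSE)
  }
  ref_all <- group_average(cohort, "healthy")
  sims <- vapply(names(cohort$subjects), function(id) {
    ref <- if (groups[[id]] == "healthy") {
      group_average(cohort, "healthy", exclude = id)
    } else {
      ref_all
    }
    connectomic_similarity(cohort$subjects[[id]], ref)
  }, numeric(1))
  hc <- sims[groups == "healthy"]
  pd <- sims[groups == "patient"]
  cmp <- outer(hc, pd, function(h, p) (h > p) + 0.5 * (h == p))
  list(similarity = data.frame(subject_id = names(sims),
                               group = unname(groups[names(sims)]),
                               similarity = unname(sims),
                               stringsAsFactors = FALSE),
       auc = mean(cmp))
}
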
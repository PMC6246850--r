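# Similarity objective, optimization, ranking, validation, statistics.

test_that("connectomic similarity matches hand Pearson on upper triangles", {
  a <- functional_connectome(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3))
  b <- functional_connectome(matrix(c(0, 1, 2, 1, 0, 4, 2, 4, 0), 3))
  expect_equal(connectomic_similarity(a, a), 1)
  neg <- functional_connectome(-a$matrix)
  expect_equal(connectomic_similarity(a, neg), -1)
  expect_equal(connectomic_similarity(a, b), cor(c(1, 2, 3), c(1, 2, 4)),
               tolerance = 1e-9)
  expect_equal(connectomic_similarity(a, b), 0.9819805, tolerance = 1e-6)
  flat <- functional_connectome(matrix(0, 3, 3))
  expect_error(connectomic_similarity(a, flat), "zero-variance")
})

test_that("relative change follows its defining formula", {
  expect_equal(relative_change(0.5, 0.55), 10)
  expect_equal(relative_change(0.5, 0.45), -10)
  expect_equal(relative_change(0.37, 0.37), 0)
  expect_error(relative_change(0, 0.5), "undefined")
  expect_warning(relative_change(-0.5, -0.4), "sign")
})

test_that("strength optimization maximizes with deterministic tie-breaks", {
  rec <- data.frame(subject_id = "s", target_pair = 1L, target_abbrev = "T",
                    strength = c(0.5, 0.8, 1, 1.2, 2),
                    cc_pre = 0.5,
                    cc_post = c(0.52, 0.58, 0.5, 0.58, 0.4),
                    feasible = TRUE)
  rec$relative_change <- (rec$cc_post - rec$cc_pre) / rec$cc_pre * 100
  best <- optimize_strength(rec)
  # tie between 0.8 and 1.2: both at distance 0.2 from 1 -> smaller s wins
  expect_equal(best$best_strength, 0.8)
  expect_equal(best$best_relative_change, 16)

  # all records equal: the identity strength wins
  rec$cc_post <- 0.5
  rec$relative_change <- 0
  expect_equal(optimize_strength(rec)$best_strength, 1)

  # no feasible record: target marked infeasible
  rec$feasible <- FALSE
  expect_false(optimize_strength(rec)$feasible)
})

test_that("rank_targets sorts by relative change with index tie-break", {
  opt <- data.frame(target_pair = c(3L, 1L, 2L), target_abbrev = c("c", "a", "b"),
                    best_strength = 1, best_relative_change = c(5, 9, 5),
                    cc_pre = 0.5, cc_post = 0.5, feasible = TRUE)
  rk <- rank_targets(opt)
  expect_equal(rk$target_pair, c(1L, 2L, 3L))
  expect_equal(rk$rank, 1:3)
  # permuting evaluation order leaves ranks unchanged
  rk2 <- rank_targets(opt[c(2, 3, 1), ])
  expect_equal(rk2$target_pair, rk$target_pair)
  # ranks are a permutation even with an infeasible target
  opt$feasible[1] <- FALSE
  rk3 <- rank_targets(opt)
  expect_equal(sort(rk3$rank), 1:3)
  expect_equal(rk3$target_pair[rk3$rank == 3], 3L)
})

test_that("the pipeline recovers an implanted lesion at rank 1", {
  parc <- tiny_parc(12)
  case <- make_lesion_case(parc, pair_id = 4, s0 = 0.5, seed = 41)
  prot <- stimulation_protocol(parc, strengths = seq(0.25, 2, by = 0.25))
  rk <- rank_connectome(case$f_patient, prot, case$f_healthy)
  expect_equal(rk$target_pair[rk$rank == 1], 4L)
  expect_equal(rk$best_strength[rk$rank == 1], 2)
  cc_pre <- connectomic_similarity(
    functional_connectome(case$f_patient$matrix, diag_zero = FALSE),
    functional_connectome(case$f_healthy$matrix, diag_zero = FALSE))
  expect_equal(rk$best_relative_change[rk$rank == 1],
               (1 - cc_pre) / cc_pre * 100, tolerance = 1e-8)
})

test_that("occurrence summary counts best and top-k consistently", {
  parc <- tiny_parc(12)
  case <- make_lesion_case(parc, pair_id = 2, s0 = 0.8, seed = 43)
  prot <- stimulation_protocol(parc, strengths = c(0.8, 1, 1.25))
  rk <- rank_connectome(case$f_patient, prot, case$f_healthy)
  occ <- occurrence_summary(list(rk, rk, rk))
  expect_equal(sum(occ$n_best), 3)
  expect_equal(sum(occ$n_top), 15)
  expect_equal(occ$n_best[occ$target_pair == 2], 3)
})

test_that("subsample cross-validation at fraction 1 reproduces the full ranking", {
  lesion <- data.frame(pair_id = 3, strength = 0.5, fraction = 1)
  world <- make_synthetic_cohorts(n_regions = 16, n_healthy = 4, n_patients = 4,
                                  noise_sd = 0.01, lesion = lesion, seed = 44)
  prot <- stimulation_protocol(synthetic_parcellation(16),
                               strengths = seq(0.4, 2, by = 0.2))
  full <- rank_cohort_group(world$cohort, protocol = prot)$ranking
  cv <- subsample_cross_validation(world$cohort, n_iter = 1, fraction = 1,
                                   seed = 9, protocol = prot)
  expect_equal(cv$best_by_iteration,
               full$target_abbrev[full$rank == 1])
  expect_equal(cv$per_target$mean_relative_change[
    match(full$target_pair, cv$per_target$target_pair)],
    full$best_relative_change, tolerance = 1e-12)

  # determinism under a fixed seed
  cv_a <- subsample_cross_validation(world$cohort, n_iter = 5, fraction = 0.5,
                                     seed = 7, protocol = prot)
  cv_b <- subsample_cross_validation(world$cohort, n_iter = 5, fraction = 0.5,
                                     seed = 7, protocol = prot)
  expect_identical(cv_a, cv_b)
  # the planted dominant target wins every subsample in this easy world
  expect_true(all(cv_a$best_by_iteration == "SYN3"))
})

test_that("null validation guards its degenerate split and shows no planted effect", {
  world <- make_synthetic_cohorts(n_regions = 16, n_healthy = 10, n_patients = 0,
                                  noise_sd = 0.02, seed = 45)
  prot <- stimulation_protocol(synthetic_parcellation(16),
                               strengths = seq(0.6, 1.6, by = 0.2))
  expect_error(null_target_validation(world$healthy, fraction = 1,
                                      protocol = prot), "coincide")
  nv <- null_target_validation(world$healthy, n_iter = 10, fraction = 0.5,
                               seed = 5, protocol = prot)
  expect_lt(max(abs(nv$per_target$mean_relative_change)), 0.5)
})

test_that("Kendall rank-severity correlation matches brute-force counting", {
  mk_rank <- function(r) {
    structure(data.frame(target_pair = 1:3, target_abbrev = c("a", "b", "c"),
                         rank = r), class = c("target_ranking", "data.frame"))
  }
  rankings <- list(s1 = mk_rank(c(1, 2, 3)), s2 = mk_rank(c(2, 1, 3)),
                   s3 = mk_rank(c(3, 2, 1)), s4 = mk_rank(c(2, 3, 1)))
  # target "a" has per-subject ranks 1, 2, 3, 2... use untied subsets
  clin <- c(s1 = 10, s2 = 20, s3 = 30)
  res <- rank_severity_correlation(rankings[1:3], clin, "a")
  expect_equal(res$tau, 1)
  res_neg <- rank_severity_correlation(rankings[1:3], c(s1 = 30, s2 = 20, s3 = 10), "a")
  expect_equal(res_neg$tau, -1)

  # 4-point worked example against the exhaustive pair-counting oracle
  ranks4 <- c(1, 2, 3, 4); scores4 <- c(12, 18, 15, 30)
  oracle <- kendall_brute(ranks4, scores4)
  expect_equal(oracle, 2/3)  # 5 concordant - 1 discordant over 6 pairs
  mk4 <- lapply(ranks4, function(r) mk_rank(c(r, setdiff(1:4, r)[1:2])))
  names(mk4) <- paste0("t", 1:4)
  res4 <- rank_severity_correlation(mk4, setNames(scores4, names(mk4)), "a")
  expect_equal(res4$tau, oracle, tolerance = 1e-12)

  expect_error(rank_severity_correlation(rankings[1:3],
                                         c(s1 = 1, s2 = 1, s3 = 1), "a"),
               "tied")
})

test_that("discrimination AUC behaves as a rank statistic", {
  set.seed(46)
  world <- make_synthetic_cohorts(n_regions = 12, n_healthy = 6, n_patients = 6,
                                  noise_sd = 0.05,
                                  lesion = data.frame(pair_id = 2, strength = 0.3,
                                                      fraction = 1), seed = 47)
  res <- compute_discrimination_auc(world$cohort)
  expect_true(res$auc >= 0 && res$auc <= 1)
  expect_equal(nrow(res$similarity), 12)
  # a strong lesion in every patient separates the groups
  expect_gt(res$auc, 0.9)
  # monotone transform of similarities leaves the AUC unchanged:
  # recompute AUC from transformed per-subject values
  s <- res$similarity
  hc <- atanh(s$similarity[s$group == "healthy"] / 2)
  pd <- atanh(s$similarity[s$group == "patient"] / 2)
  auc2 <- mean(outer(hc, pd, function(h, p) (h > p) + 0.5 * (h == p)))
  expect_equal(auc2, res$auc)
})
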
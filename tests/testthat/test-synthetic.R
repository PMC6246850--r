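# Synthetic cohort generators: determinism, ground truth, forward model.

test_that("healthy cohorts are deterministic and noiseless subjects coincide", {
  spec0 <- synthetic_cohort_spec(n_regions = 12, n_healthy = 3,
                                 subject_noise_sd = 0, seed = 61)
  hc <- generate_healthy_cohort(spec0)
  m <- lapply(hc$subjects, function(s) s$matrix)
  expect_equal(m[[1]], m[[2]])
  expect_equal(m[[2]], m[[3]])

  spec1 <- synthetic_cohort_spec(n_regions = 12, n_healthy = 4,
                                 subject_noise_sd = 0.05, seed = 62)
  a <- generate_healthy_cohort(spec1)
  b <- generate_healthy_cohort(spec1)
  expect_identical(lapply(a$subjects, `[[`, "matrix"),
                   lapply(b$subjects, `[[`, "matrix"))
  # noise makes subjects differ
  expect_gt(max(abs(a$subjects[[1]]$matrix - a$subjects[[2]]$matrix)), 0)
})

test_that("generated connectomes satisfy the transform round trip", {
  spec <- synthetic_cohort_spec(n_regions = 16, n_healthy = 3, n_patients = 2,
                                subject_noise_sd = 0.05,
                                lesion = data.frame(pair_id = 5, strength = 0.5,
                                                    fraction = 1), seed = 63)
  hc <- generate_healthy_cohort(spec)
  pd <- generate_patient_cohort(spec, hc)
  for (s in c(hc$subjects, pd$subjects)) {
    rt <- transitive_closure(network_deconvolution(s))
    expect_lt(max(abs(rt$matrix - s$matrix)[upper.tri(rt$matrix)]), 1e-10)
    expect_true(all(diag(s$matrix) == 0))
  }
})

test_that("patient ground truth records the implanted lesions", {
  lesion <- data.frame(pair_id = c(2, 7), strength = c(0.5, 1.5),
                       fraction = c(0.5, 0.25))
  spec <- synthetic_cohort_spec(n_regions = 20, n_healthy = 2, n_patients = 8,
                                lesion = lesion, seed = 64)
  hc <- generate_healthy_cohort(spec)
  pd <- generate_patient_cohort(spec, hc)
  gt <- attr(pd, "ground_truth")
  expect_equal(nrow(gt), 8)
  expect_equal(sum(gt$pair_id == 2, na.rm = TRUE), 4)
  expect_equal(sum(gt$pair_id == 7, na.rm = TRUE), 2)
  carried <- !is.na(gt$strength)
  expect_equal(gt$corrective_strength[carried], 1 / gt$strength[carried])

  # fraction 0 leaves patients statistically identical to healthy
  spec0 <- synthetic_cohort_spec(n_regions = 12, n_healthy = 2, n_patients = 2,
                                 subject_noise_sd = 0,
                                 lesion = data.frame(pair_id = 1, strength = 0.5,
                                                     fraction = 0), seed = 65)
  hc0 <- generate_healthy_cohort(spec0)
  pd0 <- generate_patient_cohort(spec0, hc0)
  expect_equal(pd0$subjects[[1]]$matrix, hc0$subjects[[1]]$matrix,
               ignore_attr = TRUE)
})

test_that("a divergent lesion errors at generation time", {
  spec <- synthetic_cohort_spec(n_regions = 12, n_healthy = 1, n_patients = 1,
                                subject_noise_sd = 0,
                                lesion = data.frame(pair_id = 1, strength = 40,
                                                    fraction = 1), seed = 66)
  hc <- generate_healthy_cohort(spec)
  expect_error(generate_patient_cohort(spec, hc), "diverge")
})

test_that("monotone severity model yields perfect rank correlation", {
  lesion <- data.frame(pair_id = c(1, 2, 3), strength = c(0.8, 0.5, 0.3),
                       fraction = c(1/3, 1/3, 1/3))
  spec <- synthetic_cohort_spec(
    n_regions = 12, n_healthy = 2, n_patients = 9, lesion = lesion,
    severity_model = list(base = 20, slope = 30, noise_sd = 0), seed = 67)
  hc <- generate_healthy_cohort(spec)
  pd <- generate_patient_cohort(spec, hc)
  gt <- attr(pd, "ground_truth")
  expect_false(is.null(pd$clinical))
  expect_equal(cor(gt$lesion_depth, pd$clinical[gt$subject_id],
                   method = "kendall"), 1)
})

test_that("generated time series converge to the target connectome", {
  set.seed(68)
  target <- functional_connectome(random_symmetric(8, radius = 0.5))
  ts <- generate_timeseries(target, n_timepoints = 5000, seed = 69)
  expect_identical(
    generate_timeseries(target, n_timepoints = 50, seed = 69)$data,
    generate_timeseries(target, n_timepoints = 50, seed = 69)$data)
  f_hat <- build_connectome(ts)
  expect_lt(max(abs(tanh(f_hat$matrix) - tanh(target$matrix))), 0.07)

  # identity correlation target: off-diagonal sample r within CLT bound
  ident <- functional_connectome(matrix(0, 6, 6))
  ts_id <- generate_timeseries(ident, n_timepoints = 4000, seed = 70)
  r <- cor(ts_id$data)
  expect_lt(max(abs(r[upper.tri(r)])), 3 / sqrt(4000))
})

test_that("cohorts round-trip through the on-disk layout", {
  lesion <- data.frame(pair_id = 3, strength = 0.5, fraction = 1)
  world <- make_synthetic_cohorts(n_regions = 12, n_healthy = 2, n_patients = 2,
                                  noise_sd = 0.02, lesion = lesion, seed = 71)
  cohort <- world$cohort
  attr(cohort, "ground_truth") <- attr(world$patients, "ground_truth")
  dir <- tempfile("cohort")
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(names(back$subjects), names(cohort$subjects))
  expect_equal(unname(back$groups), unname(cohort$groups))
  expect_equal(back$subjects[[1]]$matrix, cohort$subjects[[1]]$matrix,
               tolerance = 1e-12)
  expect_equal(attr(back, "ground_truth")$pair_id,
               attr(cohort, "ground_truth")$pair_id)
})
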
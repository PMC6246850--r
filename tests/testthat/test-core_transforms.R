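# The analytic deconvolution / closure pair and the spectral scaling.

test_that("network deconvolution matches hand eigendecomposition", {
  # zero matrix maps to zero
  f0 <- functional_connectome(matrix(0, 3, 3))
  expect_equal(network_deconvolution(f0)$matrix, matrix(0, 3, 3),
               ignore_attr = TRUE)

  # 2x2 with eigenvalues +-2/3: eigenvectors (1,1)/sqrt(2), (1,-1)/sqrt(2),
  # mapped eigenvalues 0.4 and -2 reconstruct to [[-0.8, 1.2], [1.2, -0.8]]
  f <- functional_connectome(matrix(c(0, 2/3, 2/3, 0), 2), c("A", "B"))
  d <- network_deconvolution(f)
  expect_equal(d$matrix, matrix(c(-0.8, 1.2, 1.2, -0.8), 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(d$regions, c("A", "B"))
})

test_that("transitive closure matches hand value and power series", {
  d0 <- direct_network(matrix(0, 3, 3))
  expect_equal(transitive_closure(d0)$matrix, matrix(0, 3, 3),
               ignore_attr = TRUE)

  d <- direct_network(matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(transitive_closure(d)$matrix,
               matrix(c(1/3, 2/3, 2/3, 1/3), 2),
               ignore_attr = TRUE, tolerance = 1e-12)

  # series oracle: all off-diagonal entries 0.2
  m <- matrix(0.2, 3, 3); diag(m) <- 0
  expect_lt(max(abs(transitive_closure(direct_network(m))$matrix -
                    tc_series(m))), 1e-10)
})

test_that("ND and TC are inverse operators on random admissible inputs", {
  set.seed(11)
  for (n in c(4, 9, 25)) {
    f <- functional_connectome(random_symmetric(n, radius = 0.5))
    rt <- transitive_closure(network_deconvolution(f))
    expect_lt(max(abs(rt$matrix - f$matrix)), 1e-10)
    d <- direct_network(random_symmetric(n, radius = 0.6))
    rt2 <- network_deconvolution(transitive_closure(d))
    expect_lt(max(abs(rt2$matrix - d$matrix)), 1e-10)
  }
})

test_that("transform outputs have eigenwise-mapped spectra and keep symmetry", {
  set.seed(12)
  f <- functional_connectome(random_symmetric(12, radius = 0.7))
  lam <- eigen(f$matrix, symmetric = TRUE, only.values = TRUE)$values
  d <- network_deconvolution(f)
  eta <- eigen(d$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(eta), sort(lam / (1 + lam)), tolerance = 1e-10)
  expect_lt(max(abs(d$matrix - t(d$matrix))), 1e-12)

  back <- eigen(transitive_closure(d)$matrix, symmetric = TRUE,
                only.values = TRUE)$values
  expect_equal(sort(back), sort(lam), tolerance = 1e-10)
})

test_that("transforms commute with simultaneous region permutation", {
  set.seed(13)
  n <- 8
  f <- functional_connectome(random_symmetric(n, radius = 0.5),
                             regions = letters[1:n])
  perm <- sample(n)
  fp <- functional_connectome(f$matrix[perm, perm], f$regions[perm])
  d1 <- network_deconvolution(f)$matrix[perm, perm]
  d2 <- network_deconvolution(fp)$matrix
  expect_equal(d1, d2, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("singularity and divergence guards fire with informative errors", {
  # eigenvalue exactly -1: F = diag-free 2x2 with eigenvalues +-1
  f_sing <- functional_connectome(matrix(c(0, 1, 1, 0), 2))
  expect_error(network_deconvolution(f_sing), "singular.*-1")

  d_div <- direct_network(matrix(c(0, 1.2, 1.2, 0), 2))
  err <- tryCatch(transitive_closure(d_div), condition = function(c) c)
  expect_s3_class(err, "connstim_divergence")
  expect_match(conditionMessage(err), "diverges")

  # asymmetry beyond 1e-12 is an input error
  m <- matrix(c(0, 0.2, 0.200001, 0), 2)
  expect_error(functional_connectome(m), "asymmetric")
})

test_that("scaling factor follows the two-sided eigenvalue inequality", {
  # one matrix with lambda+ = 0.5, lambda- = -0.5 at beta = 0.5:
  # bound = min(0.5/(0.5*0.5), -0.5/(1.5*-0.5)) = min(2, 2/3) = 2/3
  m <- matrix(c(0, 0.5, 0.5, 0), 2)
  sp <- compute_scaling_factor(list(functional_connectome(m)), beta = 0.5)
  expect_equal(sp$alpha, 2/3, tolerance = 1e-12)

  # pooled alpha is the minimum over matrices
  m2 <- matrix(c(0, 0.4, 0.4, 0), 2)  # bound 2/(0.4/0.5...) -> larger
  sp2 <- compute_scaling_factor(list(functional_connectome(m),
                                     functional_connectome(m2)), beta = 0.5)
  expect_equal(sp2$alpha, min(sp2$per_matrix_bounds))
  expect_equal(sp2$alpha, 2/3, tolerance = 1e-12)

  # default beta in the pipeline wrappers is 0.5
  expect_equal(formals(rank_cohort_patients)$beta, 0.5)
  expect_error(compute_scaling_factor(list(functional_connectome(m)), beta = 1.2),
               "beta")
})

test_that("one-sided spectra use only the available eigenvalue term", {
  # positive semi-definite matrix: no negative eigenvalue
  v <- c(1, 2, 3)
  m <- outer(v, v) / 10
  sp <- compute_scaling_factor(list(direct_network(m)), beta = 0.5)
  lam_max <- max(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(sp$alpha, 0.5 / (0.5 * lam_max), tolerance = 1e-12)
  expect_error(compute_scaling_factor(list(functional_connectome(matrix(0, 2, 2)))),
               "all-zero")
})

test_that("applied scaling bounds the deconvolved spectral radius by beta", {
  set.seed(14)
  mats <- lapply(1:12, function(i) {
    functional_connectome(random_symmetric(10, radius = runif(1, 0.5, 3)))
  })
  sp <- compute_scaling_factor(mats, beta = 0.5)
  for (f in mats) {
    scaled <- apply_scaling(f, sp)
    expect_equal(scaled$matrix, f$matrix * sp$alpha, ignore_attr = TRUE)
    d <- network_deconvolution(scaled)
    expect_lte(max(abs(eigen(d$matrix, symmetric = TRUE,
                             only.values = TRUE)$values)), 0.5 + 1e-9)
  }
  # alpha = 1 is the identity
  expect_equal(apply_scaling(mats[[1]], 1)$matrix, mats[[1]]$matrix)
})
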
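# Shared fixtures, built in code at test time.

# Random symmetric matrix with zero diagonal and a prescribed spectral
# radius: the generic admissible input for the transform pair.
random_symmetric <- function(n, radius = 0.5, zero_diag = TRUE) {
  m <- matrix(rnorm(n * n), n)
  m <- (m + t(m)) / 2
  if (zero_diag) diag(m) <- 0
  r <- max(abs(eigen(m, symmetric = TRUE, only.values = TRUE)$values))
  m * (radius / r)
}

# Truncated power-series oracle for the transitive closure.
tc_series <- function(d, k_max = 200) {
  acc <- d
  term <- d
  for (k in 2:k_max) {
    term <- term %*% d
    acc <- acc + term
  }
  acc
}

# Brute-force Kendall tau by exhaustive pair counting (no tie handling:
# callers use untied inputs).
kendall_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  (conc - disc) / choose(n, 2)
}

# Small noiseless world: healthy reference plus a patient carrying one
# implanted lesion, generated through the model's own forward operators
# so recovery is exact.
make_lesion_case <- function(parc, pair_id, s0, seed = 42,
                             n_regions = nrow(parc)) {
  set.seed(seed)
  d0 <- random_symmetric(n_regions, radius = 0.45)
  f_h <- transitive_closure(direct_network(d0, parc$abbreviation))
  p <- build_perturbation(parc, pair_id, s0)
  f_pat <- transitive_closure(
    direct_network(d0 * p$matrix, parc$abbreviation))
  list(f_healthy = f_h, f_patient = f_pat, d0 = d0)
}

tiny_parc <- function(n = 10) synthetic_parcellation(n)

# Small healthy + lesioned-patient cohorts sharing one prototype.
make_synthetic_cohorts <- function(n_regions = 20, n_healthy = 6,
                                   n_patients = 6, noise_sd = 0.02,
                                   lesion = NULL, seed = 3, ...) {
  spec <- synthetic_cohort_spec(
    n_regions = n_regions, n_healthy = n_healthy, n_patients = n_patients,
    subject_noise_sd = noise_sd, lesion = lesion, seed = seed, ...)
  hc <- generate_healthy_cohort(spec)
  if (n_patients == 0) {
    return(list(spec = spec, healthy = hc, patients = NULL, cohort = hc))
  }
  pd <- generate_patient_cohort(spec, hc)
  list(spec = spec, healthy = hc, patients = pd,
       cohort = combine_cohorts(hc, pd))
}
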
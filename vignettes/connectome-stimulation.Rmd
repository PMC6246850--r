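---
title: "Simulating focal neurostimulation on the functional connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating focal neurostimulation on the functional connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connstim)
```

## The model

`connstim` treats a measured resting-state functional connectome
\(F\) — a region-by-region matrix of Fisher-z transformed Pearson
correlations — as the stationary result of information diffusing over an
unobserved *direct* network \(D\):

\[
F \;=\; D + D^2 + D^3 + \cdots
\]

Every power of \(D\) contributes the walks of that length, so \(F\)
mixes direct interactions with all higher-order indirect ones.  Because
\(F\) is symmetric, both directions of the relationship have closed
forms through one eigendecomposition.  Writing
\(F = U\,\mathrm{diag}(\lambda_i)\,U^\top\),

\[
\mathrm{ND}(F) = U\,\mathrm{diag}\!\left(\frac{\lambda_i}{1+\lambda_i}\right)U^\top ,
\qquad
\mathrm{TC}(D) = V\,\mathrm{diag}\!\left(\frac{\eta_i}{1-\eta_i}\right)V^\top ,
\]

where ND (network deconvolution) recovers \(D\) from \(F\) and TC
(transitive closure) re-sums the series.  The two maps are exact
inverses whenever they converge: ND requires no eigenvalue of \(F\) at
\(-1\), TC requires every eigenvalue of \(D\) below \(1\).

A focal stimulation event is a multiplicative operator \(P\) on the
direct network.  For a bilateral target (one homologous left/right
pair), every entry in the target's rows and columns equals the strength
\(s\) and all other entries equal one, so

\[
D' = D \odot P, \qquad F' = \mathrm{TC}(D').
\]

\(s > 1\) up-regulates the target's direct connections, \(s < 1\)
down-regulates them (e.g. \(s = 0.7\) is a 30% down-regulation).  The
element-wise product applies \(s\) exactly once to every affected entry,
including the left–right edge and the target diagonal (the diagonal
never enters any statistic).

The therapeutic objective is *connectomic similarity*: the Pearson
correlation between the vectorized strictly-upper triangles of the
(post-stimulation) patient connectome and a group-averaged healthy
reference.  Outcomes are standardized as the relative change

\[
\mathrm{relative\ change} =
\frac{CC(\mathrm{post}, \mathrm{healthy}) - CC(\mathrm{pre}, \mathrm{healthy})}
     {CC(\mathrm{pre}, \mathrm{healthy})} \times 100\%,
\]

maximized per target over a strength grid; targets are then ranked by
their optimal relative change, per subject or on the group average.

## Tunable parameters

* **`beta` (default 0.5, dimensionless).**  Both transforms need the
  deconvolved spectrum safely inside \((-1, 1)\) even after sizeable
  up-regulation.  All pre-stimulation matrices are therefore multiplied
  by one pooled constant \(\alpha\) satisfying, for every matrix,
  \(\alpha \le \min\{\beta/((1-\beta)\lambda_+),\,
  -\beta/((1+\beta)\lambda_-)\}\) with \(\lambda_\pm\) the extreme
  positive/negative eigenvalues; \(\alpha\) is the minimum of the
  per-matrix bounds (a matrix lacking one sign of eigenvalue contributes
  only the other term).  After scaling, every deconvolved network has
  spectral radius at most \(\beta\).  One pooled \(\alpha\) — not a
  per-subject one — keeps all subjects on a common scale; similarity
  itself is scale-invariant, so \(\alpha\) only matters through the
  nonlinear ND/TC pair.
* **Strength grid (default 0.02–2.00, step 0.02).**  Covers 98%
  down-regulation to 100% up-regulation at 2% resolution; the identity
  strength 1.0 is always forced into the grid so that "do nothing" is a
  candidate and the best relative change can never be negative.
* **Guard tolerance (default 1e-9).**  Eigenvalues within 1e-9 of the
  singular points (\(-1\) for ND, \(1\) for TC) raise errors; in a
  strength sweep a diverging closure is recorded as an *infeasible*
  grid point rather than an error, since it simply means that strength
  is not attainable for that subject.
* **Symmetry tolerance (1e-12).**  Larger asymmetry is an input error;
  smaller asymmetry is symmetrized as \((M + M^\top)/2\).
* **Edge-wise significance (default 0.05 family-wise).**  Two-sample
  pooled-variance t-tests per upper-triangle edge with Bonferroni
  correction over all \(R(R-1)/2\) edges; Welch's correction is
  available by flag.

## Diagonal policy

The Fisher z of a self-correlation is infinite, so measured connectomes
carry an exactly-zero diagonal, and no similarity or group statistic
ever reads the diagonal.  Connectomes produced by `transitive_closure()`
are *not* diagonal-zeroed: the closure of a direct network has a small
positive diagonal (closed walks), and zeroing it would break the exact
inverse relationship with `network_deconvolution()` that the whole
simulation relies on.

## The synthetic world

The generator emulates the model's own forward direction so that ground
truth exists by construction:

* a **prototype direct network** \(D_0\) with Erdős–Rényi support
  (default density 0.1) and half-normal weights, rescaled to spectral
  radius 0.4 — dense enough that indirect walks matter (what ND must
  disentangle), sparse enough that individual connections are
  meaningful;
* **subjects** as \(D_0\) plus independent Gaussian edge noise (default
  SD 0.05 z) on the support, re-rescaled only if the spectral radius
  exceeds 0.6 (a guard against divergence, not a normalization: an
  aggressive cap would rescale every subject and inject a structured
  global discrepancy);
* **patients** as carriers of a known lesion
  \(D_0 \odot P(k, s_0)\) applied before closure, with the ledgered
  corrective strength \(1/s_0\);
* optional **severity scores** increasing monotonically with lesion
  depth \(|\log s_0|\), and optional planted additive edge shifts for
  the edge-wise statistics.

What a green test establishes: that the analytic machinery (transform
pair, scaling, perturbation algebra), the optimization and ranking
logic, and the statistics recover a *known* truth planted under the
model's own assumptions.  What it does not establish: anything about
real fMRI data, whose noise is not Gaussian or support-confined, whose
direct networks are not Erdős–Rényi, and whose group differences are
not single multiplicative lesions.  The cohort-specific clinical
findings of the source study (which nucleus is best for which fraction
of patients) are out of scope by design.

One quantitative limitation is worth stating plainly.  Holding the
prototype's spectral radius at 0.4 pins the direct edge weights near
\(r/(2\sqrt{np}) \approx 0.03\)–0.07 z at 92 regions *for any density*,
so additive subject noise of 0.05 z is of the same order as the weights
a 50% lesion modifies.  In that regime single-subject lesion recovery
degrades (the implanted pair lands in the top five for roughly half to
four-fifths of subjects rather than \(\ge 90\%\)); with noise at 0.02 z
recovery is perfect.  The noisy-recovery acceptance criterion is
asserted at its stated parameters regardless and is expected to fail;
see the decisions ledger accompanying the repository.

A related caveat concerns null validation.  Because every synthetic
subject derives from *one* fixed prototype network, the winning target
under the label-permutation null is a function of half-split noise
conditional on that prototype's row geometry (row norms, grid snapping
of the optimal strength, feasibility truncation), so winner counts are
uniform in expectation over prototypes but not exactly uniform given
one.  Mean relative changes stay well below 0.5%, as they should, but a
chi-square test of winner uniformity will reject given enough
iterations (p ≈ 0.011 at 50 iterations, below 0.01 by 200).  Real
cohorts, where each subject is its own rich realization, are a far less
structured null.

## Numerical choices

* **Eigendecompositions** use the symmetric solver throughout
  (`eigen(symmetric = TRUE)`).
* **Sweep hot path.**  A full screen is `targets × strengths`
  closures.  The sweep computes ND once per subject (it is
  strength-independent) and evaluates each closure as
  \((I - D')^{-1} - I\) via a Cholesky factorization of \(I - D'\):
  positive-definiteness of \(I - D'\) is *equivalent* to the
  convergence condition \(\max\eta < 1\), so a failed factorization is
  exactly an infeasible strength.  This is algebraically identical to
  the eigendecomposition form (asserted to 1e-10 in the tests) and
  several times faster, putting a 46-target × 100-strength sweep of a
  92-region connectome around two seconds.
* **Tie-breaks** are deterministic everywhere: equal relative changes
  resolve toward the strength closest to 1 (mildest intervention), then
  the smaller strength; equal target optima resolve by parcellation
  pair index.
* **Hemisphere-balanced subdivision.**  When refining the atlas to a
  high-resolution template, seed counts are drawn proportionally to
  regional volume for the left hemisphere (with a one-seed floor,
  enforced by stealing from the largest allocation) and mirrored onto
  the homologous right regions.  Mirroring enforces the equal-hemisphere
  constraint exactly and keeps subregions pairable into bilateral
  targets; it is proportional to volume up to left/right volume
  asymmetry.  Within regions, voxels are clustered by Lloyd's k-means
  with k-means++ initialization on voxel coordinates under a fixed
  seed, and clusters are renumbered by centroid position for
  reproducibility.
* **Degenerate inputs.**  Constant time-series columns, off-diagonal
  |r| = 1, all-zero spectra, all-tied ranks, zero-variance triangles and
  empty group selections are all errors with named offenders; edges
  with zero variance in both groups are flagged degenerate and excluded
  from significance rather than silently significant.

## Open design decisions

* **Healthy reference.**  Individual patients are compared to the
  group-averaged healthy connectome.  Healthy subjects entering the
  discriminative-similarity analysis are compared to a leave-one-out
  average, since self-inclusion trivially inflates their similarity.
* **Averaging before scaling.**  Group averages are computed first and
  the single pooled \(\alpha\) applied afterwards; scaling is linear,
  so the order affects only which matrices the bound is computed from,
  and the pooled bound covers subjects and averages alike.
* **Null validation split.**  Pseudo-patients are drawn from the
  healthy group and compared against the *complement*, so a fraction of
  1 (reference identical to pseudo-patients) is rejected as degenerate.
* **One-sample null for per-subject effects** (where used) is zero
  relative change.
* **Kendall correlation** between a target's per-subject rank and the
  clinical score uses tau-b with `stats::cor.test`'s exact small-sample
  p-value when there are no ties; per-subject ranks are the only
  per-subject quantity available, so they are what enters the
  correlation.
* **Positive definiteness of F is not assumed.**  Empirical Fisher-z
  matrices with zero diagonals are generally indefinite; the closed
  forms only need \(\lambda \ne -1\) and \(\eta < 1\), and only those
  conditions are enforced.

## A worked miniature

```{r example, eval = FALSE}
library(connstim)

spec <- synthetic_cohort_spec(
  n_regions = 92, n_healthy = 10, n_patients = 3,
  subject_noise_sd = 0.02,
  lesion = data.frame(pair_id = 38, strength = 0.5, fraction = 1),
  seed = 7)
healthy  <- generate_healthy_cohort(spec)
patients <- generate_patient_cohort(spec, healthy)
cohort   <- combine_cohorts(healthy, patients)

res <- rank_cohort_patients(cohort)
res$rankings$PD01[1:3, c("target_abbrev", "best_strength",
                         "best_relative_change", "rank")]
```

With a 50% down-regulating pallidal lesion implanted in every patient,
the bilateral globus pallidus (`PAL`) is returned at rank 1 with a best
strength near 2.0, the corrective inverse of the lesion (exactly 2.0 in
the noiseless limit; displaced by a few grid steps under edge noise —
the README shows the printed output of this script).

## Known limitations

* Strength is the only stimulation parameter; frequency, pulse width
  and electrode geometry are not modelled.
* Direct networks are assumed symmetric; directed variants are out of
  scope.
* The closure diverges for strong up-regulation of well-connected
  targets; such grid points are reported infeasible rather than
  extrapolated.
* Atlas volumes are exchanged as plain-text voxel tables, not NIfTI
  (no NIfTI reader exists in the supported dependency set).
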
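Package: connstim
Title: Functional Connectome-Based Simulation of Focal Neurostimulation
Version: 0.1.0
Authors@R:
    person("Connstim", "Developers", email = "connstim@example.org",
           role = c("aut", "cre"))
Description: Simulates the brain-wide network effects of focal
    neurostimulation from a resting-state functional connectome.  An
    observed region-by-region Fisher-z connectivity matrix is deconvolved
    into a direct-interaction network by an analytic eigenvalue transform,
    a focal multiplicative perturbation is applied to the direct network,
    and the perturbed network is re-convolved by transitive closure to
    predict the post-stimulation connectome.  Candidate stimulation
    targets and strengths are ranked by how far they move a patient
    connectome toward a healthy reference, at both group and
    single-subject level, with subsample cross-validation, null
    validation against relabelled healthy subjects, edge-wise group
    statistics of topological rectification, and a fully synthetic
    cohort generator with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
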
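Package: pasym
Title: Voxel-Wise Functional Asymmetry Analysis of Resting-State fMRI
Version: 0.1.0
Authors@R: person("pasym", "developers", role = c("aut", "cre"),
    email = "pasym@example.org")
Description: Computes the parameter of asymmetry (PAS), a voxel-wise
    difference between mean inter-hemispheric and mean intra-hemispheric
    functional connectivity, from preprocessed resting-state BOLD fMRI.
    Includes the temporal preprocessing contract (Friston-24 confound
    regression, linear detrending, band-pass filtering, framewise
    displacement computation and motion scrubbing), covariate-adjusted
    voxel-wise group inference with false-discovery-rate control and
    cluster extraction, brain-behavior Spearman correlation, leave-one-out
    support-vector-machine discrimination, and a latent-factor synthetic
    BOLD generator so the whole pipeline is testable without any data
    download. Minimal NIfTI-1 input/output is built in.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
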
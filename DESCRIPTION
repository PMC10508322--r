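Package: boldvar
Title: Resting-State BOLD Signal Variability and Behavioral Partial Least
    Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes per-voxel temporal variability maps (standard
    deviation and mean square successive difference) from denoised 4D
    resting-state fMRI, with grand-mean-100 intensity normalization, and
    relates them to behavioral measures through behavioral partial least
    squares: cross-block correlation, singular value decomposition into
    latent variables, permutation testing of singular values, bootstrap
    estimation of voxel-salience stability (bootstrap ratios) and of
    brain-score/behavior correlation confidence intervals. Includes
    confound residualization (age, mean framewise displacement),
    chronotype utilities (Morningness-Eveningness Questionnaire
    categories, chronotype/test-time synchrony scores), bootstrap-ratio
    map thresholding with cluster-extent filtering, per-network overlap
    quantification against a parcellation atlas, and a synthetic-data
    generator with planted latent structure for end-to-end parameter
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
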